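# The 37 model structures of the RY Lie Markov hierarchy and their
# structural properties (closure, nesting, equilibrium degrees of freedom,
# time reversibility, classical aliases).

# Structure catalogue: basis sets as printed, A1 convention.  Model 2.2a
# ({A1, D1}: transitions only, reducible chain) is registered but hidden.
.lmm_catalogue <- list(
  "1.1"   = c("A"),
  "2.2a"  = c("A1", "D1"),
  "2.2b"  = c("A", "A1"),
  "3.3a"  = c("A", "A1", "B"),
  "3.3b"  = c("A", "A1", "C"),
  "3.3c"  = c("A", "A1", "D1"),
  "3.4"   = c("A", "A1", "D"),
  "4.4a"  = c("A", "D", "E1", "E2"),
  "4.4b"  = c("A", "A1", "D", "D1"),
  "4.5a"  = c("A", "A1", "B", "D"),
  "4.5b"  = c("A", "A1", "C", "D"),
  "5.6a"  = c("A", "A1", "B", "C", "D1"),
  "5.6b"  = c("A", "A1", "D", "E1", "E2"),
  "5.7a"  = c("A", "A1", "B", "E1", "E2"),
  "5.7b"  = c("A", "A1", "B", "F1", "F2"),
  "5.7c"  = c("A", "A1", "B", "G1", "G2"),
  "5.11a" = c("A", "A1", "D1", "E1", "E2"),
  "5.11b" = c("A", "A1", "D1", "F1", "F2"),
  "5.11c" = c("A", "A1", "D1", "G1", "G2"),
  "5.16"  = c("A", "A1", "D", "G1", "G2"),
  "6.6"   = c("A", "A1", "B", "C", "D", "D1"),
  "6.7a"  = c("A", "A1", "B", "D", "E1", "E2"),
  "6.7b"  = c("A", "A1", "C", "D", "E1", "E2"),
  "6.8a"  = c("A", "A1", "D", "D1", "E1", "E2"),
  "6.8b"  = c("A", "A1", "D", "D1", "G1", "G2"),
  "6.17a" = c("A", "A1", "B", "D", "G1", "G2"),
  "6.17b" = c("A", "A1", "C", "D", "G1", "G2"),
  "8.8"   = c("A", "A1", "D", "D1", "E1", "E2", "F1", "F2"),
  "8.10a" = c("A", "A1", "B", "C", "D", "D1", "E1", "E2"),
  "8.10b" = c("A", "A1", "B", "C", "D", "D1", "G1", "G2"),
  "8.16"  = c("A", "A1", "D", "D1", "E1", "E2", "G1", "G2"),
  "8.17"  = c("A", "A1", "B", "D", "E1", "E2", "G1", "G2"),
  "8.18"  = c("A", "A1", "B", "D", "E1", "E2", "F1", "F2"),
  "9.20a" = c("A", "A1", "B", "C", "D1", "E1", "E2", "F1", "F2"),
  "9.20b" = c("A", "A1", "B", "C", "D1", "F1", "F2", "G1", "G2"),
  "10.12" = c("A", "A1", "B", "C", "D", "D1", "E1", "E2", "F1", "F2"),
  "10.34" = c("A", "A1", "B", "C", "D", "D1", "E1", "E2", "G1", "G2"),
  "12.12" = c("A", "A1", "B", "C", "D", "D1",
              "E1", "E2", "F1", "F2", "G1", "G2")
)

# Structures whose RY/WS/MK spans coincide; they never take a pairing prefix.
.lmm_symmetric <- c("1.1", "3.3a", "4.4a", "6.7a", "9.20b", "12.12")

# Classical aliases (within the RY family where the pairing matters).
.lmm_aliases <- c("1.1" = "JC", "2.2b" = "K2ST", "3.3a" = "K3ST",
                  "3.3c" = "TrNef", "4.4a" = "F81", "6.6" = "SSM",
                  "9.20b" = "DS", "12.12" = "GM")

.lmm_structures <- function(include_hidden = FALSE) {
  nm <- names(.lmm_catalogue)
  if (!include_hidden) nm <- setdiff(nm, "2.2a")
  nm
}

#' Build a Lie Markov model definition
#'
#' Assembles a model from its structure name (a row of the 37-entry catalogue)
#' and a base pairing.  For the six fully symmetric structures the pairing is
#' immaterial and is recorded as `"SYM"`.
#'
#' @param structure_name e.g. `"5.6b"`; `"RY5.6b"`-style prefixed names are
#'   also accepted (the prefix then overrides `pairing`).
#' @param pairing `"RY"`, `"WS"` or `"MK"`.
#' @param use_A2 substitute A2 = 3*A1 - A for A1 in the stored generator list
#'   (the convention used by the Cartesian parameterization).
#' @param allow_hidden permit the deprecated structure `"2.2a"`.
#' @return an object of class `lmm_model`: list with `structure`, `pairing`,
#'   `basis_names`, `basis` (named list of 4x4 generators), `dimension`,
#'   `ray_count`, `alias`, `name`, `use_A2`.
#' @examples
#' build_model("5.6b")
#' build_model("WS3.4")
#' @export
build_model <- function(structure_name, pairing = "RY", use_A2 = FALSE,
                        allow_hidden = FALSE) {
  m <- regmatches(structure_name,
                  regexec("^(RY|WS|MK)?([0-9]+\\.[0-9]+[abc]?)$", structure_name))[[1]]
  if (length(m) == 0) stop("unknown model name '", structure_name, "'")
  if (nzchar(m[2])) pairing <- m[2]
  structure_name <- m[3]
  if (identical(structure_name, "2.2a") && !allow_hidden) {
    stop("model 2.2a is omitted from the hierarchy: it forbids transversions ",
         "entirely and is of no phylogenetic interest ",
         "(use allow_hidden = TRUE to construct it anyway)")
  }
  if (!structure_name %in% names(.lmm_catalogue)) {
    stop("unknown model structure '", structure_name, "'; see list_models()")
  }
  if (is.character(pairing)) pairing <- lmm_pairing(pairing)
  symmetric <- structure_name %in% .lmm_symmetric
  basis_names <- .lmm_catalogue[[structure_name]]
  if (use_A2) basis_names[basis_names == "A1"] <- "A2"
  pr <- if (symmetric) lmm_pairing("RY") else pairing
  basis <- lapply(basis_names, get_basis_matrix, pairing = pr)
  names(basis) <- basis_names
  parts <- strsplit(structure_name, "[.]")[[1]]
  alias <- unname(.lmm_aliases[structure_name])
  if (!is.na(alias) && alias == "SSM" && pr$code != "WS") alias <- NA_character_
  obj <- list(
    structure   = structure_name,
    pairing     = if (symmetric) "SYM" else pr$code,
    basis_names = basis_names,
    basis       = basis,
    dimension   = length(basis_names),
    ray_count   = as.integer(gsub("[abc]$", "", parts[2])),
    alias       = if (is.na(alias)) NULL else alias,
    name        = if (symmetric) structure_name
                  else paste0(pr$code, structure_name),
    use_A2      = use_A2
  )
  stopifnot(obj$dimension == as.integer(parts[1]))
  class(obj) <- "lmm_model"
  obj
}

#' @export
print.lmm_model <- function(x, ...) {
  cat("Lie Markov model ", x$name,
      if (!is.null(x$alias)) paste0(" (", x$alias, ")"), "\n", sep = "")
  cat("  basis: ", paste(x$basis_names, collapse = ", "),
      "  (dimension ", x$dimension, ", ", x$ray_count, " rays)\n", sep = "")
  invisible(x)
}

# Stacked vectorized basis: dimension x 16 matrix spanning the model.
.lmm_span <- function(model) {
  t(vapply(model$basis, as.vector, numeric(16)))
}

.lmm_rank <- function(S, tol = 1e-9) {
  if (nrow(S) == 0) return(0L)
  d <- svd(S)$d
  sum(d > tol * max(d, 1))
}

# span(S1) subset of span(S2), by rank of the stacked vectorizations.
.lmm_span_contains <- function(S_outer, S_inner, tol = 1e-9) {
  .lmm_rank(rbind(S_outer, S_inner), tol) == .lmm_rank(S_outer, tol)
}

#' List the registered models
#'
#' @param pairing_variants expand the 31 asymmetric structures into their RY,
#'   WS and MK variants (99 models in total with the 6 symmetric ones).
#' @param modeltest append the nine reversible ModelTest models that are not
#'   Lie Markov models (108 in total).
#' @return data.frame with columns `name`, `structure`, `pairing`,
#'   `dimension`, `rays`, `lie_markov`.
#' @examples
#' nrow(list_models())                              # 37
#' nrow(list_models(pairing_variants = TRUE))       # 99
#' @export
list_models <- function(pairing_variants = FALSE, modeltest = FALSE) {
  structures <- .lmm_structures()
  rows <- list()
  for (s in structures) {
    dim <- as.integer(strsplit(s, "[.]")[[1]][1])
    rays <- as.integer(gsub("[abc]$", "", strsplit(s, "[.]")[[1]][2]))
    if (pairing_variants && !(s %in% .lmm_symmetric)) {
      for (p in c("RY", "WS", "MK")) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste0(p, s), structure = s, pairing = p,
          dimension = dim, rays = rays, lie_markov = TRUE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        name = s, structure = s,
        pairing = if (s %in% .lmm_symmetric) "SYM" else "RY",
        dimension = dim, rays = rays, lie_markov = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  if (modeltest) {
    extra <- reversible_panel_models()
    out <- rbind(out, data.frame(
      name = vapply(extra, function(m) m$name, character(1)),
      structure = NA_character_, pairing = NA_character_,
      dimension = vapply(extra, function(m) m$dimension, numeric(1)),
      rays = NA_integer_, lie_markov = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Verify Lie closure of a model's span
#'
#' Checks that the commutator of every pair of basis generators lies in the
#' span of the model basis (least-squares residual).  A failure would indicate
#' a mis-transcribed generator, not a property of the model.
#'
#' @param model an [build_model()] object.
#' @return list with `max_residual` and `worst_pair`.
#' @export
verify_lie_closure <- function(model) {
  S <- t(.lmm_span(model))            # 16 x n
  n <- length(model$basis)
  worst <- 0; pair <- c(NA, NA)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      Bi <- model$basis[[i]]; Bj <- model$basis[[j]]
      cm <- as.vector(Bi %*% Bj - Bj %*% Bi)
      res <- cm - S %*% qr.solve(S, cm)
      r <- sqrt(sum(res^2))
      if (r > worst) { worst <- r; pair <- model$basis_names[c(i, j)] }
    }
  }
  list(max_residual = worst, worst_pair = pair)
}

#' Is one model nested in another?
#'
#' TRUE iff every rate matrix of `inner` is a rate matrix of `outer`, i.e. the
#' basis span of `inner` is contained in that of `outer` (both expressed in
#' canonical coordinates, so the pairings may differ).
#'
#' @param inner,outer [build_model()] objects.
#' @param tol rank tolerance.
#' @export
is_nested <- function(inner, outer, tol = 1e-9) {
  .lmm_span_contains(.lmm_span(outer), .lmm_span(inner), tol)
}

#' Equilibrium base frequency degrees of freedom
#'
#' 0 for doubly stochastic models (flat frequencies); D contributes the
#' purine/pyrimidine split, E1+E2 the within-pair splits.
#'
#' @param model an [build_model()] object.
#' @return integer in 0:3.
#' @export
ebf_degrees_of_freedom <- function(model) {
  bn <- sub("^A2$", "A1", model$basis_names)
  has_d <- "D" %in% bn
  has_e <- "E1" %in% bn
  if (has_d && has_e) 3L else if (has_e) 2L else if (has_d) 1L else 0L
}

#' Test time reversibility of a model
#'
#' Samples random stochastic members and checks detailed balance
#' pi_i Q_ji = pi_j Q_ij against the equilibrium distribution.  With the
#' registered hierarchy this returns TRUE exactly for
#' 1.1, 2.2b, 3.3a, 3.3c, 3.4, 4.4a and 4.4b.
#'
#' @param model an [build_model()] object.
#' @param n number of random members to test.
#' @param tol detailed-balance tolerance.
#' @export
is_time_reversible <- function(model, n = 50, tol = 1e-8) {
  for (k in seq_len(n)) {
    Q <- sample_stochastic(model, trace = -4, n = 1)[[1]]
    pi <- equilibrium_frequencies(Q)
    for (i in 1:3) for (j in (i + 1):4) {
      if (abs(pi[i] * Q[j, i] - pi[j] * Q[i, j]) > tol) return(FALSE)
    }
  }
  TRUE
}

#' Tabulate the model catalogue with derived properties
#'
#' @param pairing_variants as in [list_models()].
#' @return data.frame: name, pairing, basis, dimension, rays, ebf_df,
#'   reversible, alias.
#' @export
model_catalogue <- function(pairing_variants = FALSE) {
  base <- list_models(pairing_variants = pairing_variants)
  rows <- lapply(seq_len(nrow(base)), function(i) {
    m <- build_model(base$structure[i],
                     if (base$pairing[i] == "SYM") "RY" else base$pairing[i])
    data.frame(name = base$name[i], pairing = base$pairing[i],
               basis = paste(m$basis_names, collapse = ","),
               dimension = m$dimension, rays = m$ray_count,
               ebf_df = ebf_degrees_of_freedom(m),
               reversible = m$structure %in%
                 c("1.1", "2.2b", "3.3a", "3.3c", "3.4", "4.4a", "4.4b"),
               alias = if (is.null(m$alias)) NA_character_ else m$alias)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export the nesting hierarchy as a DOT graph
#'
#' Edges are the covering relations of the nesting partial order over the 37
#' structures within one pairing (the topology of the published hierarchy
#' figure).
#'
#' @param pairing pairing within which to compute nesting.
#' @return character scalar: DOT source.
#' @export
nesting_graph_dot <- function(pairing = "RY") {
  structures <- .lmm_structures()
  models <- lapply(structures, build_model, pairing = pairing)
  names(models) <- structures
  n <- length(structures)
  nested <- matrix(FALSE, n, n, dimnames = list(structures, structures))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) nested[i, j] <- is_nested(models[[i]], models[[j]])
  }
  lines <- c("digraph lie_markov_nesting {", "  rankdir=BT;")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!nested[i, j]) next
    # covering edge: no k strictly between i and j
    via <- any(vapply(seq_len(n), function(k)
      k != i && k != j && nested[i, k] && nested[k, j], logical(1)))
    if (!via) {
      lines <- c(lines, sprintf('  "%s" -> "%s";', structures[i], structures[j]))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
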