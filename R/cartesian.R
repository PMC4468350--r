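# Cartesian parameterization of each model's stochastic cone, extreme-ray
# enumeration, and samplers built on them.
#
# The three-step construction: with the model written on basis {A, B_1..B_{n-1}}
# in the A2 convention (all non-A generators trace-orthogonal to A), a point
# b in [-1,1]^{n-1} maps to
#   P' = sum_i b_i B_i,   P = P' / (-min offdiag P'),   s = max_i |b_i|,
#   Q = A + s P.
# Q is stochastic, lies in the model, and has trace -12; s = 1 puts Q on the
# boundary of stochasticity (one off-diagonal zero).  The map is a continuous
# bijection onto the trace -12 section of the cone.

.lmm_cartesian_model <- function(model) {
  if (!model$use_A2 && "A1" %in% model$basis_names) {
    model <- build_model(model$structure,
                         if (model$pairing == "SYM") "RY" else model$pairing,
                         use_A2 = TRUE, allow_hidden = TRUE)
  }
  model
}

.lmm_offdiag <- function(Q) Q[row(Q) != col(Q)]

#' Map Cartesian parameters to a stochastic rate matrix
#'
#' @param model an [build_model()] object (converted internally to the A2
#'   basis convention).
#' @param b numeric vector in `[-1,1]^(dimension-1)`, the weights of the non-A
#'   generators; `b = 0` gives the Jukes-Cantor generator A.
#' @param trace optional target trace; the raw construction yields trace -12.
#' @return 4x4 stochastic rate matrix within the model.
#' @examples
#' cartesian_to_rate(build_model("3.4"), c(1, 0.5))
#' @export
cartesian_to_rate <- function(model, b, trace = NULL) {
  model <- .lmm_cartesian_model(model)
  if (length(b) != model$dimension - 1) {
    stop("model ", model$name, " takes ", model$dimension - 1,
         " Cartesian parameters, got ", length(b))
  }
  if (length(b) && max(abs(b)) > 1 + 1e-12) {
    stop("Cartesian parameters must lie in [-1, 1]")
  }
  A <- model$basis[["A"]]
  if (!length(b)) {
    return(.lmm_named4(if (is.null(trace)) A else normalize_rate(A, trace)))
  }
  others <- model$basis[model$basis_names != "A"]
  P1 <- matrix(0, 4, 4)
  for (i in seq_along(b)) P1 <- P1 + b[i] * others[[i]]
  mn <- min(.lmm_offdiag(P1))
  Q <- if (mn >= -1e-14) A else A - (max(abs(b)) / mn) * P1
  if (!is.null(trace)) Q <- normalize_rate(Q, trace)
  .lmm_named4(Q)
}

#' Invert the Cartesian parameterization
#'
#' Exact inverse of [cartesian_to_rate()] on the trace -12 section: with
#' R = Q - A written in the non-A basis as coordinates c, the saturation is
#' s = -min offdiag(R) and b = c * s / max|c|.
#'
#' @param Q stochastic rate matrix in the model; rescaled to trace -12 first
#'   if it is not already.
#' @param model an [build_model()] object.
#' @param tol membership tolerance.
#' @return numeric vector b in `[-1,1]^(dimension-1)`.
#' @export
rate_to_cartesian <- function(Q, model, tol = 1e-8) {
  model <- .lmm_cartesian_model(model)
  Q <- normalize_rate(Q, -12)
  mem <- in_model_span(Q, model, tol)
  if (!mem$member) {
    stop("rate matrix is not in model ", model$name,
         " (span residual ", format(mem$residual), ")")
  }
  if (!is_stochastic(Q)) stop("rate matrix is not stochastic")
  n <- model$dimension
  if (n == 1) return(numeric(0))
  A <- model$basis[["A"]]
  R <- Q - A
  others <- model$basis[model$basis_names != "A"]
  S <- vapply(others, as.vector, numeric(16))       # 16 x (n-1)
  cc <- qr.solve(S, as.vector(R))
  mx <- max(abs(cc))
  if (mx < 1e-13) return(numeric(n - 1))
  s <- -min(.lmm_offdiag(R))
  cc * (s / mx)
}

#' Sample random stochastic members of a model
#'
#' Uniform sampling of the Cartesian hypercube, rescaled to the requested
#' trace.  This is the sampling distribution used by all Monte Carlo
#' diagnostics in the package.
#'
#' @param model an [build_model()] object.
#' @param trace target trace (< 0).
#' @param n number of matrices.
#' @param seed optional integer seed (local to this call).
#' @return list of `n` stochastic rate matrices at the requested trace.
#' @export
sample_stochastic <- function(model, trace = -4, n = 1, seed = NULL) {
  stopifnot(trace < 0)
  model <- .lmm_cartesian_model(model)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- model$dimension - 1
  lapply(seq_len(n), function(i) {
    b <- if (k) stats::runif(k, -1, 1) else numeric(0)
    cartesian_to_rate(model, b, trace = trace)
  })
}

#' Enumerate the extreme rays of a model's stochastic cone
#'
#' Active-set enumeration: each extreme ray satisfies dimension-1 linearly
#' independent off-diagonal zero constraints; every such subset of the 12
#' constraints is solved, the sign-feasible null directions kept, and
#' duplicates removed.  The ray count equals the number after the point in the
#' model name for all registered structures.
#'
#' @param model an [build_model()] object.
#' @param normalize_trace trace to normalize each ray to (rays with zero trace
#'   cannot occur; every nonzero stochastic matrix has negative trace).
#' @return object of class `lmm_rays`: list with `model`, `rays` (list of
#'   stochastic rate matrices), `weights` (rows = ray coordinates in the model
#'   basis).
#' @export
enumerate_rays <- function(model, normalize_trace = -4) {
  n <- model$dimension
  mats <- model$basis
  if (n == 1) {
    # one-dimensional cone: the single ray is the generator itself
    return(structure(list(model = model,
                          rays = list(normalize_rate(mats[[1]], normalize_trace)),
                          weights = matrix(1, 1, 1)),
                     class = "lmm_rays"))
  }
  offs <- which(row(diag(4)) != col(diag(4)))
  # constraint matrix: 12 off-diagonals x n weights
  Cmat <- vapply(mats, function(m) m[offs], numeric(12))
  found_g <- list(); found_w <- list(); found_Q <- list()
  combos <- utils::combn(12, n - 1)
  for (ci in seq_len(ncol(combos))) {
    Asub <- Cmat[combos[, ci], , drop = FALSE]
    sv <- svd(Asub, nu = 0, nv = n)
    if (n > 1 && sv$d[n - 1] < 1e-9) next          # rank-deficient active set
    v <- sv$v[, n]
    g <- as.vector(Cmat %*% v)
    if (all(g >= -1e-9)) { } else if (all(g <= 1e-9)) { v <- -v; g <- -g }
    else next
    if (max(abs(g)) < 1e-9) next
    v <- v / max(abs(g)); g <- as.vector(Cmat %*% v)
    dup <- any(vapply(found_g, function(f) max(abs(f - g)) < 1e-8, logical(1)))
    if (dup) next
    Q <- matrix(0, 4, 4)
    for (i in seq_len(n)) Q <- Q + v[i] * mats[[i]]
    Q <- normalize_rate(Q, normalize_trace)
    found_g[[length(found_g) + 1L]] <- g
    found_w[[length(found_w) + 1L]] <- v
    found_Q[[length(found_Q) + 1L]] <- .lmm_named4(Q)
  }
  structure(list(model = model, rays = found_Q,
                 weights = do.call(rbind, found_w)),
            class = "lmm_rays")
}

#' @export
print.lmm_rays <- function(x, ...) {
  cat("Extreme rays of model ", x$model$name, ": ", length(x$rays),
      " rays (model name says ", x$model$ray_count, ")\n", sep = "")
  invisible(x)
}

#' Random rate matrix as a nonnegative ray combination
#'
#' Overparameterized but trivially stochastic: Q = sum of uniform nonnegative
#' weights times the extreme rays.
#'
#' @param model an [build_model()] object.
#' @param weights optional nonnegative weights, one per ray; uniform(0,1)
#'   draws if omitted.
#' @param rays optionally a precomputed [enumerate_rays()] result.
#' @param seed optional integer seed (local to this call).
#' @return stochastic rate matrix in the model.
#' @export
raysum_sample <- function(model, weights = NULL, rays = NULL, seed = NULL) {
  if (is.null(rays)) rays <- enumerate_rays(model)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- length(rays$rays)
  if (is.null(weights)) weights <- stats::runif(k)
  if (length(weights) != k || any(weights < 0)) {
    stop("need ", k, " nonnegative ray weights")
  }
  Q <- matrix(0, 4, 4)
  for (i in seq_len(k)) Q <- Q + weights[i] * rays$rays[[i]]
  .lmm_named4(Q)
}
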