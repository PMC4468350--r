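# Basis generators of the RY Lie Markov hierarchy.
#
# Internal convention (used everywhere below): bases ordered A, G, C, T so the
# purine and pyrimidine pairs sit in 2x2 blocks; rows index the final state and
# columns the initial state, hence COLUMNS sum to zero.  User-facing I/O
# converts to alphabetical A, C, G, T at the boundary (see io.R).

#' Nucleotide orderings
#'
#' `lmm_base_order("canonical")` is the internal A,G,C,T ordering that groups
#' purines and pyrimidines; `"alpha"` is alphabetical A,C,G,T used at I/O
#' boundaries and `"paml"` is T,C,A,G.
#'
#' @param which one of `"canonical"`, `"alpha"`, `"paml"`.
#' @return character vector of the four bases in the requested order.
#' @export
lmm_base_order <- function(which = c("canonical", "alpha", "paml")) {
  switch(match.arg(which),
    canonical = c("A", "G", "C", "T"),
    alpha     = c("A", "C", "G", "T"),
    paml      = c("T", "C", "A", "G"))
}

#' Names of the twelve basis matrices (plus the substitute A2)
#' @export
lmm_basis_names <- c("A", "A1", "B", "C", "D", "D1",
                     "E1", "E2", "F1", "F2", "G1", "G2")

.lmm_named4 <- function(m) {
  dimnames(m) <- list(lmm_base_order("canonical"), lmm_base_order("canonical"))
  m
}

# The 12 generators (+ A2 = 3*A1 - A) in canonical A,G,C,T order.  A, A2, D,
# E1, E2 are pinned entry-by-entry by the weight form of Q5.6b and Q3.4; the
# doubly stochastic generators B, C, D1, F1, F2, G1, G2 are the symmetry-
# adapted complements (see the methods vignette for the derivation).
.lmm_basis_env <- new.env(parent = emptyenv())

.lmm_build_basis <- function() {
  A  <- matrix(1, 4, 4) - 4 * diag(4)
  A1 <- rbind(c(-1, 1, 0, 0), c(1, -1, 0, 0), c(0, 0, -1, 1), c(0, 0, 1, -1))
  A2 <- 3 * A1 - A
  B  <- rbind(c(0, 0, 1, -1), c(0, 0, -1, 1), c(1, -1, 0, 0), c(-1, 1, 0, 0))
  C  <- rbind(c(0, 0, 1, -1), c(0, 0, -1, 1), c(-1, 1, 0, 0), c(1, -1, 0, 0))
  D  <- rbind(rep(1, 4), rep(1, 4), rep(-1, 4), rep(-1, 4))
  D1 <- rbind(c(-1, 1, 0, 0), c(1, -1, 0, 0), c(0, 0, 1, -1), c(0, 0, -1, 1))
  E1 <- rbind(rep(1, 4), rep(-1, 4), rep(0, 4), rep(0, 4))
  E2 <- rbind(rep(0, 4), rep(0, 4), rep(1, 4), rep(-1, 4))
  w  <- c(1, -1, 0, 0); w2 <- c(0, 0, 1, -1); u <- c(1, 1, -1, -1)
  F1 <- outer(w, u); F2 <- outer(w2, -u)
  G1 <- outer(u, w); G2 <- outer(-u, w2)
  out <- list(A = A, A1 = A1, A2 = A2, B = B, C = C, D = D, D1 = D1,
              E1 = E1, E2 = E2, F1 = F1, F2 = F2, G1 = G1, G2 = G2)
  lapply(out, .lmm_named4)
}

.lmm_basis <- function() {
  if (is.null(.lmm_basis_env$basis)) .lmm_basis_env$basis <- .lmm_build_basis()
  .lmm_basis_env$basis
}

#' Base pairings distinguishing one pair of nucleotides
#'
#' The three ways of partitioning \{A,G,C,T\} into two pairs: `RY`
#' (purine/pyrimidine, AG|CT), `WS` (Watson-Crick weak/strong, AT|CG) and `MK`
#' (amino/keto, AC|GT).  Each pairing is realised by a base reordering: the
#' canonical matrices are written for AG|CT, and the WS (MK) variant of a
#' generator is the same matrix with rows and columns reordered so that the
#' distinguished pairs become AT|CG (AC|GT).
#'
#' @param code one of `"RY"`, `"WS"`, `"MK"`.
#' @return list with elements `code` and `perm` (an involution of 1:4 acting
#'   on the canonical A,G,C,T positions).
#' @export
lmm_pairing <- function(code = c("RY", "WS", "MK")) {
  code <- match.arg(code)
  perm <- switch(code,
    RY = 1:4,             # identity: pairs AG | CT
    WS = c(1L, 4L, 3L, 2L),  # swap G and T: pairs AT | CG
    MK = c(1L, 3L, 2L, 4L))  # swap G and C: pairs AC | GT
  structure(list(code = code, perm = perm), class = "lmm_pairing")
}

.lmm_apply_perm <- function(m, perm) {
  out <- m[perm, perm, drop = FALSE]
  # relabel so dimnames stay canonical: entry (i,j) of the variant is the
  # generator entry read with the reordered bases in the canonical slots
  .lmm_named4(unname(out))
}

#' Retrieve a basis matrix
#'
#' Returns one of the 12 basis generators (or the substitute `A2`), optionally
#' permuted to realise the WS or MK pairing.  Columns always sum to zero.
#'
#' @param name basis label, one of [lmm_basis_names] or `"A2"`.
#' @param pairing `"RY"` (canonical), `"WS"`, `"MK"`, or an [lmm_pairing].
#' @return 4x4 matrix in canonical A,G,C,T order.
#' @examples
#' get_basis_matrix("A")            # the Jukes-Cantor generator
#' get_basis_matrix("A1", "WS")
#' @export
get_basis_matrix <- function(name, pairing = "RY") {
  basis <- .lmm_basis()
  if (!name %in% names(basis)) {
    stop("unknown basis matrix '", name, "'; valid labels: ",
         paste(names(basis), collapse = ", "))
  }
  if (is.character(pairing)) pairing <- lmm_pairing(pairing)
  m <- basis[[name]]
  if (identical(pairing$perm, 1:4)) m else .lmm_apply_perm(m, pairing$perm)
}
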