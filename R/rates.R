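# Rate matrix construction and queries: weight form, stochasticity, model
# membership, normalization, equilibrium frequencies.

#' Build a rate matrix from basis weights
#'
#' Q = sum of w_i B_i over the model's generators.  Weights follow the
#' lowercase naming convention (`a` for A, `a1` or `a2`, `d`, `e1`, ...).
#'
#' @param model an [build_model()] object.
#' @param weights numeric vector, length = model dimension; may be named with
#'   lowercase basis names (order then ignored).
#' @return 4x4 rate matrix (canonical A,G,C,T order, columns sum to zero).
#' @examples
#' m <- build_model("5.6b", use_A2 = TRUE)
#' from_weights(m, c(a = 1, a2 = 0.5, d = 0.1, e1 = 0.2, e2 = 0))["A", "G"]
#' @export
from_weights <- function(model, weights) {
  if (length(weights) != model$dimension) {
    stop("model ", model$name, " needs ", model$dimension,
         " weights, got ", length(weights))
  }
  if (!is.null(names(weights))) {
    expect <- tolower(model$basis_names)
    if (!setequal(names(weights), expect)) {
      stop("weight names must be {", paste(expect, collapse = ", "), "}")
    }
    weights <- weights[expect]
  }
  Q <- matrix(0, 4, 4)
  for (i in seq_along(weights)) Q <- Q + weights[[i]] * model$basis[[i]]
  .lmm_named4(Q)
}

#' Convert weights between the A1 and A2 conventions
#'
#' A2 = 3*A1 - A, so a matrix a*A + a1*A1 equals (a + a1/3)*A + (a1/3)*A2.
#'
#' @param weights named or positional weight vector for `model`.
#' @param model the model the weights belong to (`use_A2` says which
#'   convention they are in).
#' @return weights in the opposite convention, same order.
#' @export
convert_weights <- function(weights, model) {
  w <- unname(weights)
  ia <- match("A", model$basis_names)
  if (model$use_A2) {              # a*A + a2*A2 -> (a - a2)*A + 3*a2*A1
    i2 <- match("A2", model$basis_names)
    if (!is.na(i2)) { a2 <- w[i2]; w[ia] <- w[ia] - a2; w[i2] <- 3 * a2 }
    names(w) <- tolower(sub("^A2$", "A1", model$basis_names))
  } else {                         # a*A + a1*A1 -> (a + a1/3)*A + (a1/3)*A2
    i1 <- match("A1", model$basis_names)
    if (!is.na(i1)) { a1 <- w[i1]; w[ia] <- w[ia] + a1 / 3; w[i1] <- a1 / 3 }
    names(w) <- tolower(sub("^A1$", "A2", model$basis_names))
  }
  w
}

#' The six-parameter ray-sum form of model 5.6b
#'
#' Q is the sum of a K2ST part (transition rate `alpha`, transversion rate
#' `beta`) and an F81 part (target-base rates `rhoA`, `rhoG`, `rhoC`, `rhoT`);
#' nonnegative parameters give exactly the stochastic members of RY5.6b.  The
#' parameterization is redundant: adding delta to alpha and beta and
#' subtracting it from every rho leaves Q unchanged.
#'
#' @param alpha,beta,rhoA,rhoG,rhoC,rhoT nonnegative rates.
#' @return 4x4 stochastic rate matrix in model RY5.6b.
#' @export
raysum_to_rate_56b <- function(alpha, beta, rhoA, rhoG, rhoC, rhoT) {
  p <- c(alpha, beta, rhoA, rhoG, rhoC, rhoT)
  if (any(p < 0)) stop("all ray-sum parameters must be nonnegative")
  rho <- c(rhoA, rhoG, rhoC, rhoT)
  Q <- matrix(0, 4, 4)
  within <- rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- rho[i] + if (any(within[, 1] == i & within[, 2] == j)) alpha else beta
  }
  diag(Q) <- -colSums(Q)
  .lmm_named4(Q)
}

#' Is a rate matrix stochastic?
#'
#' Stochastic means every off-diagonal entry is nonnegative (within `tol`).
#'
#' @param Q 4x4 rate matrix.
#' @param tol absolute tolerance on off-diagonal entries.
#' @export
is_stochastic <- function(Q, tol = 1e-9) {
  min(Q[row(Q) != col(Q)]) >= -tol
}

#' Membership of a rate matrix in a model's span
#'
#' Projects vec(Q) onto the span of the model's basis and reports the
#' least-squares residual.
#'
#' @param Q 4x4 rate matrix.
#' @param model an [build_model()] object.
#' @param tol residual threshold for membership.
#' @return list with `member` (logical) and `residual`.
#' @export
in_model_span <- function(Q, model, tol = 1e-9) {
  S <- t(.lmm_span(model))
  v <- as.vector(Q)
  r <- v - S %*% qr.solve(S, v)
  res <- sqrt(sum(r^2))
  list(member = res < tol, residual = res)
}

#' Rescale a rate matrix to a target trace
#'
#' The hierarchy's scale convention: trace -4 corresponds to one expected
#' substitution per site per unit time (exactly, under flat frequencies).
#'
#' @param Q rate matrix with negative trace.
#' @param target_trace requested trace (default -4).
#' @export
normalize_rate <- function(Q, target_trace = -4) {
  tr <- sum(diag(Q))
  if (tr >= 0) stop("rate matrix must have negative trace")
  Q * (target_trace / tr)
}

#' Equilibrium base frequencies of a rate matrix
#'
#' The stationary distribution: the principal right null vector of Q
#' (eigenvalue zero), computed from the null space via SVD.
#'
#' @param Q stochastic, irreducible 4x4 rate matrix.
#' @return named nonnegative vector over A,G,C,T summing to one.
#' @export
equilibrium_frequencies <- function(Q) {
  sv <- svd(Q)
  if (sv$d[3] < 1e-10) {
    stop("rate matrix is reducible or degenerate: equilibrium not unique")
  }
  v <- sv$v[, 4]
  v <- v / sum(v)
  if (min(v) < -1e-8) stop("rate matrix has no nonnegative equilibrium")
  v <- pmax(v, 0); v <- v / sum(v)
  names(v) <- lmm_base_order("canonical")
  v
}

#' Expected substitution rate
#'
#' -sum_i pi_i Q_ii: expected substitutions per site per unit time.  Equals
#' -trace(Q)/4 exactly when the equilibrium is flat.
#'
#' @param Q stochastic rate matrix.
#' @export
expected_rate <- function(Q) {
  pi <- equilibrium_frequencies(Q)
  -sum(pi * diag(Q))
}
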