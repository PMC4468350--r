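# Multiplicative closure and embeddability diagnostics.
#
# The product of two model Markov matrices exp(Q1) exp(Q2) is embeddable in
# the model if Q' = log(exp(Q1) exp(Q2)) is a real, stochastic member.  The
# three failure modes: (i) Q' complex, (ii) Q' real but nonstochastic,
# (iii) Q' outside the model span (Lie theory forbids this for these models;
# it is tracked as a sanity check only).

# 4x4 matrix exponential: eigendecomposition, Pade scaling-squaring fallback
# for near-defective inputs.
.lmm_norm1 <- function(M) max(colSums(abs(M)))   # complex-safe 1-norm

.lmm_expm <- function(Q) {
  e <- eigen(Q)
  V <- e$vectors
  rc <- tryCatch(1 / (.lmm_norm1(V) * .lmm_norm1(solve(V))),
                 error = function(err) 0)
  if (rc > 1e-10) {
    M <- V %*% diag(exp(e$values)) %*% solve(V)
    if (max(abs(Im(M))) < 1e-9) return(Re(M))
  }
  .lmm_expm_pade(Q)
}

# Higham-style [6/6] Pade with scaling and squaring; ample for 4x4 generators.
.lmm_expm_pade <- function(A) {
  s <- max(0L, ceiling(log2(max(norm(A, "1"), 1e-300))) + 1L)
  A <- A / 2^s
  cfs <- c(1, 1/2, 5/44, 1/66, 1/792, 1/15840, 1/665280)
  A2 <- A %*% A; A4 <- A2 %*% A2; A6 <- A4 %*% A2
  U <- A %*% (cfs[2] * diag(4) + cfs[4] * A2 + cfs[6] * A4)
  Vm <- cfs[1] * diag(4) + cfs[3] * A2 + cfs[5] * A4 + cfs[7] * A6
  M <- solve(Vm - U, Vm + U)
  for (i in seq_len(s)) M <- M %*% M
  M
}

# Principal matrix logarithm via eigendecomposition (possibly complex).
# Returns list(log = matrix possibly complex, ok = logical).
.lmm_logm <- function(M) {
  e <- eigen(M)
  if (any(abs(e$values) < 1e-12)) return(list(log = NULL, ok = FALSE))
  V <- e$vectors
  rc <- tryCatch(1 / (.lmm_norm1(V) * .lmm_norm1(solve(V))),
                 error = function(err) 0)
  if (rc < 1e-12) return(list(log = NULL, ok = FALSE))
  L <- V %*% diag(log(as.complex(e$values))) %*% solve(V)
  list(log = L, ok = TRUE)
}

#' Average rate matrix of a product of model Markov matrices
#'
#' Computes Q' = log(exp(Q1) exp(Q2)) with the principal matrix logarithm and
#' classifies the embeddability outcome.
#'
#' @param Q1,Q2 stochastic rate matrices.
#' @param model optional [build_model()] object for the span membership check.
#' @param imag_tol imaginary parts above this make Q' "complex" (numerical
#'   logm emits tiny imaginary dust on real-embeddable inputs).
#' @param stoch_tol tolerance for [is_stochastic()].
#' @param span_tol residual threshold for failure mode (iii).
#' @return object of class `lmm_embed`: list with `Qprime` (real matrix, or
#'   complex if classification is `"complex"`, or NULL if the log failed),
#'   `classification` in `{"stochastic_in_model", "real_nonstochastic",
#'   "complex", "not_in_model"}`, and `residual` (span residual, NA without
#'   `model`).
#' @export
product_rate <- function(Q1, Q2, model = NULL, imag_tol = 1e-8,
                         stoch_tol = 1e-9, span_tol = 1e-8) {
  M <- .lmm_expm(Q1) %*% .lmm_expm(Q2)
  lg <- .lmm_logm(M)
  out <- list(Q1 = Q1, Q2 = Q2, Qprime = NULL,
              classification = "complex", residual = NA_real_)
  class(out) <- "lmm_embed"
  if (!lg$ok) {
    out$diagnostic <- "matrix logarithm numerically undefined"
    return(out)
  }
  L <- lg$log
  if (max(abs(Im(L))) > imag_tol) {
    out$Qprime <- L
    return(out)
  }
  Qp <- .lmm_named4(Re(L))
  out$Qprime <- Qp
  if (!is.null(model)) {
    mem <- in_model_span(Qp, model, span_tol)
    out$residual <- mem$residual
    if (!mem$member) {
      out$classification <- "not_in_model"
      return(out)
    }
  }
  out$classification <- if (is_stochastic(Qp, stoch_tol))
    "stochastic_in_model" else "real_nonstochastic"
  out
}

#' @export
print.lmm_embed <- function(x, ...) {
  cat("Q' = log(exp(Q1) exp(Q2)): ", x$classification,
      if (!is.na(x$residual)) sprintf(" (span residual %.2e)", x$residual),
      "\n", sep = "")
  invisible(x)
}

# Draw n pairs of Cartesian parameter vectors for a model (hypercube uniform).
.lmm_draw_bpairs <- function(model, n) {
  k <- model$dimension - 1
  lapply(seq_len(n), function(i)
    list(b1 = stats::runif(k, -1, 1), b2 = stats::runif(k, -1, 1)))
}

.lmm_pair_nonembeddable <- function(model, b1, b2, trace) {
  Q1 <- cartesian_to_rate(model, b1, trace = trace)
  Q2 <- cartesian_to_rate(model, b2, trace = trace)
  r <- product_rate(Q1, Q2)
  r$classification %in% c("complex", "real_nonstochastic")
}

#' Monte Carlo nonembeddable fraction
#'
#' Fraction of random (Q1, Q2) pairs, sampled at a fixed trace via the
#' Cartesian hypercube, whose average rate matrix Q' is complex or real but
#' nonstochastic.  Mode (iii) (Q' outside the span) is never counted here; it
#' is checked separately in the test suite and has never been observed.
#'
#' @param model an [build_model()] object.
#' @param trace common trace of Q1 and Q2 (< 0).
#' @param n number of pairs.
#' @param seed integer seed.
#' @param bpairs optional precomputed parameter pairs (common random numbers
#'   across traces, used by [threshold_trace()]).
#' @return fraction in [0, 1].
#' @export
nonembeddable_fraction <- function(model, trace, n = 2000, seed = NULL,
                                   bpairs = NULL) {
  stopifnot(trace < 0, n >= 1)
  model <- .lmm_cartesian_model(model)
  if (is.null(bpairs)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    bpairs <- .lmm_draw_bpairs(model, n)
  }
  bad <- vapply(bpairs[seq_len(n)], function(p)
    .lmm_pair_nonembeddable(model, p$b1, p$b2, trace), logical(1))
  mean(bad)
}

#' Trace at which a model reaches a target nonembeddable fraction
#'
#' Bisection over |trace| with common random numbers (the same Cartesian
#' parameter pairs are reused at every trace, making the empirical fraction
#' monotone in |trace| up to boundary effects).
#'
#' @param model an [build_model()] object.
#' @param target_fraction target in (0, 1); the published experiments use 0.05.
#' @param n pairs per trace evaluation.
#' @param seed integer seed.
#' @param trace_range |trace| search interval.  Fractions still below target
#'   at the deep end are reported as `"never"`.  The default deep end of 16
#'   (four expected substitutions per site) is past every saturation band the
#'   experiment distinguishes; far beyond it, products of boundary matrices
#'   have eigenvalues that underflow double precision and the conservative
#'   logarithm guard would misreport them as failures.
#' @param iter bisection iterations.
#' @return list with `trace` (NA for "never"), `never` (logical), `fraction`
#'   at the returned trace, and a Monte Carlo binomial `ci` (95%).
#' @export
threshold_trace <- function(model, target_fraction = 0.05, n = 2000,
                            seed = NULL, trace_range = c(0.25, 16), iter = 14) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  model <- .lmm_cartesian_model(model)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  bpairs <- .lmm_draw_bpairs(model, n)
  frac <- function(tr) nonembeddable_fraction(model, -tr, n, bpairs = bpairs)
  lo <- trace_range[1]; hi <- trace_range[2]
  f_hi <- frac(hi)
  if (f_hi < target_fraction) {
    return(list(trace = NA_real_, never = TRUE, fraction = f_hi,
                ci = stats::binom.test(round(f_hi * n), n)$conf.int))
  }
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target_fraction) lo <- mid else hi <- mid
  }
  tr <- -(lo + hi) / 2
  f <- frac(-tr)
  list(trace = tr, never = FALSE, fraction = f,
       ci = stats::binom.test(round(f * n), n)$conf.int)
}

#' Does embeddability depend on how different Q1 and Q2 are?
#'
#' For each model: at a trace giving roughly 50% nonembeddability, generate
#' random pairs, measure |Q1 - Q2| (root mean square over off-diagonal
#' entries), and standardize the mean difference between nonembeddable and
#' embeddable pairs by the pooled standard deviation.
#'
#' @param models character vector of structure names (RY variants used).
#' @param n_pairs pairs per model.
#' @param seed integer seed.
#' @param n_search pairs per trace evaluation during the 50% search.
#' @return list with `per_model` data.frame (model, trace, fraction, effect)
#'   and `mean_effect`.
#' @export
difference_dependence <- function(models = c("6.6", "8.8", "8.10b", "10.12"),
                                  n_pairs = 1000, seed = NULL, n_search = 500) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  offs <- row(diag(4)) != col(diag(4))
  rows <- lapply(models, function(mn) {
    model <- build_model(mn, "RY", use_A2 = TRUE)
    th <- threshold_trace(model, target_fraction = 0.5, n = n_search,
                          trace_range = c(0.25, 60), iter = 10)
    if (th$never) stop("no trace with 50% nonembeddability for ", mn,
                       " within the search range")
    diffs <- numeric(n_pairs); emb <- logical(n_pairs)
    k <- model$dimension - 1
    for (i in seq_len(n_pairs)) {
      b1 <- stats::runif(k, -1, 1); b2 <- stats::runif(k, -1, 1)
      Q1 <- cartesian_to_rate(model, b1, trace = th$trace)
      Q2 <- cartesian_to_rate(model, b2, trace = th$trace)
      diffs[i] <- sqrt(mean((Q1 - Q2)[offs]^2))
      r <- product_rate(Q1, Q2)
      emb[i] <- r$classification == "stochastic_in_model"
    }
    d1 <- diffs[!emb]; d0 <- diffs[emb]
    sp <- sqrt(((length(d1) - 1) * stats::var(d1) +
                (length(d0) - 1) * stats::var(d0)) /
               (length(d1) + length(d0) - 2))
    data.frame(model = mn, trace = th$trace, fraction = mean(!emb),
               effect = (mean(d1) - mean(d0)) / sp)
  })
  per_model <- do.call(rbind, rows)
  list(per_model = per_model, mean_effect = mean(per_model$effect))
}

#' Run a configured embeddability experiment
#'
#' Drives [nonembeddable_fraction()] over a model list and trace grid from a
#' config (a list or a JSON file path; see [read_config()]): fields `models`
#' (structure names), `traces` (negative), `n` (pairs per cell), `seed`.
#'
#' @param config list or path to a JSON config file.
#' @return data.frame with one row per (model, trace) cell: the estimated
#'   nonembeddable fraction, a 95% binomial confidence interval, and the
#'   seed used for the cell (logged for reproducibility).
#' @export
run_embeddability_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(!is.null(config$models), !is.null(config$traces),
            !is.null(config$seed))
  n <- if (is.null(config$n)) 2000L else as.integer(config$n)
  rows <- list()
  cell_seed <- as.integer(config$seed)
  for (mn in config$models) {
    model <- build_model(mn, "RY", use_A2 = TRUE)
    for (tr in as.numeric(config$traces)) {
      cell_seed <- cell_seed + 1L
      f <- nonembeddable_fraction(model, tr, n, seed = cell_seed)
      ci <- stats::binom.test(round(f * n), n)$conf.int
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, trace = tr, n = n, fraction = f,
        ci_lo = ci[1], ci_hi = ci[2], seed = cell_seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
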