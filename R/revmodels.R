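# The ModelTest panel of time-reversible models.  Five of the original 14 are
# Lie Markov models (JC = 1.1, K80 = RY2.2b, K81 = 3.3a, TrNef = RY3.3c,
# F81 = 4.4a) and resolve to registry entries; the remaining nine are handled
# here as exchangeability x frequency parameterizations.

# pair order: AG, CT (transitions), AC, AT, GC, GT (transversions);
# indices into the canonical A,G,C,T order
.lmm_pairs <- rbind(c(1, 2), c(3, 4), c(1, 3), c(1, 4), c(2, 3), c(2, 4))

# class assignment per model: integer class of each of the 6 pairs
.lmm_rev_defs <- list(
  JC    = list(classes = c(1, 1, 1, 1, 1, 1), free_freqs = FALSE, lie = "1.1"),
  F81   = list(classes = c(1, 1, 1, 1, 1, 1), free_freqs = TRUE,  lie = "4.4a"),
  K80   = list(classes = c(1, 1, 2, 2, 2, 2), free_freqs = FALSE, lie = "RY2.2b"),
  HKY   = list(classes = c(1, 1, 2, 2, 2, 2), free_freqs = TRUE,  lie = NA),
  TrNef = list(classes = c(1, 2, 3, 3, 3, 3), free_freqs = FALSE, lie = "RY3.3c"),
  TrN   = list(classes = c(1, 2, 3, 3, 3, 3), free_freqs = TRUE,  lie = NA),
  K81   = list(classes = c(1, 1, 2, 3, 3, 2), free_freqs = FALSE, lie = "3.3a"),
  K81uf = list(classes = c(1, 1, 2, 3, 3, 2), free_freqs = TRUE,  lie = NA),
  TIMef = list(classes = c(1, 2, 3, 4, 4, 3), free_freqs = FALSE, lie = NA),
  TIM   = list(classes = c(1, 2, 3, 4, 4, 3), free_freqs = TRUE,  lie = NA),
  TVMef = list(classes = c(1, 1, 2, 3, 4, 5), free_freqs = FALSE, lie = NA),
  TVM   = list(classes = c(1, 1, 2, 3, 4, 5), free_freqs = TRUE,  lie = NA),
  SYM   = list(classes = c(1, 2, 3, 4, 5, 6), free_freqs = FALSE, lie = NA),
  GTR   = list(classes = c(1, 2, 3, 4, 5, 6), free_freqs = TRUE,  lie = NA)
)

#' Construct a reversible ModelTest-panel model
#'
#' General time-reversible parameterization Q_ij = s_ij * pi_i (column j =
#' initial state), with the six exchangeabilities s constrained into the
#' model's rate classes and frequencies either free or fixed flat.
#'
#' @param name one of JC, F81, K80, HKY, TrNef, TrN, K81, K81uf, TIMef, TIM,
#'   TVMef, TVM, SYM, GTR.
#' @return object of class `lmm_rev_model` with fields `name`, `classes`,
#'   `n_classes`, `free_freqs`, `dimension` (exchangeability classes + free
#'   frequency parameters, so that `dimension - 1` free parameters remain
#'   once the scale is fixed, as for the Lie models), `lie_equiv` (registry
#'   name when the model is also Lie Markov).
#' @export
modeltest_model <- function(name) {
  if (!name %in% names(.lmm_rev_defs)) {
    stop("unknown ModelTest model '", name, "'; valid: ",
         paste(names(.lmm_rev_defs), collapse = ", "))
  }
  def <- .lmm_rev_defs[[name]]
  structure(list(name = name, classes = def$classes,
                 n_classes = max(def$classes), free_freqs = def$free_freqs,
                 dimension = max(def$classes) + if (def$free_freqs) 3 else 0,
                 lie_equiv = def$lie),
            class = "lmm_rev_model")
}

#' @export
print.lmm_rev_model <- function(x, ...) {
  cat("Reversible model ", x$name, ": ", x$n_classes, " rate classes, ",
      if (x$free_freqs) "free" else "flat", " base frequencies\n", sep = "")
  invisible(x)
}

#' Rate matrix of a reversible model
#'
#' @param model an [modeltest_model()] object.
#' @param rates exchangeability per rate class (length `n_classes`).
#' @param freqs equilibrium frequencies in canonical A,G,C,T order (ignored
#'   and forced flat unless the model has free frequencies).
#' @param trace target trace (NULL keeps the raw scale).
#' @return 4x4 rate matrix; its equilibrium distribution is `freqs`.
#' @export
rev_rate_matrix <- function(model, rates, freqs = rep(0.25, 4), trace = -4) {
  stopifnot(length(rates) == model$n_classes)
  if (!model$free_freqs) freqs <- rep(0.25, 4)
  freqs <- freqs / sum(freqs)
  Q <- matrix(0, 4, 4)
  for (p in seq_len(6)) {
    i <- .lmm_pairs[p, 1]; j <- .lmm_pairs[p, 2]
    s <- rates[model$classes[p]]
    Q[i, j] <- s * freqs[i]
    Q[j, i] <- s * freqs[j]
  }
  diag(Q) <- -colSums(Q)
  if (!is.null(trace)) Q <- normalize_rate(Q, trace)
  .lmm_named4(Q)
}

#' The nine extra reversible models of the ModelTest panel
#'
#' ModelTest compares 14 reversible models; five are Lie Markov models already
#' in the registry, leaving these nine to complete the 108-model panel.
#'
#' @return list of `lmm_rev_model` objects: HKY, TrN, K81uf, TIMef, TIM,
#'   TVMef, TVM, SYM, GTR.
#' @export
reversible_panel_models <- function() {
  lapply(c("HKY", "TrN", "K81uf", "TIMef", "TIM", "TVMef", "TVM", "SYM", "GTR"),
         modeltest_model)
}
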