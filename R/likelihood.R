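# Pruning-algorithm likelihood for (non)reversible models with the root state
# distribution fixed at the model's equilibrium, rate heterogeneity
# (+I, +Gamma(8), +I+Gamma), hill-climbing optimization, and BIC/AICc model
# selection.

#' Rate heterogeneity specification
#'
#' @param kind `"single"`, `"I"` (invariant sites), `"G"` (discrete gamma,
#'   8 equal-probability classes), or `"IG"`.
#' @param p_invariant proportion of invariant sites in [0, 1).
#' @param gamma_shape gamma shape parameter (> 0); the gamma mixture has mean
#'   rate 1 over the variable fraction.
#' @param n_categories number of gamma classes.
#' @return list of class `lmm_het`.
#' @export
rate_heterogeneity <- function(kind = c("single", "I", "G", "IG"),
                               p_invariant = 0, gamma_shape = 1,
                               n_categories = 8) {
  kind <- match.arg(kind)
  if (p_invariant < 0 || p_invariant >= 1) stop("p_invariant must be in [0, 1)")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  structure(list(kind = kind, p_invariant = p_invariant,
                 gamma_shape = gamma_shape, n_categories = n_categories),
            class = "lmm_het")
}

.lmm_het <- function(h) {
  if (inherits(h, "lmm_het")) h else rate_heterogeneity(h)
}

# Discrete gamma: equal-probability categories, category rate = mean of the
# quantile band; mean(X | X in band_i) = ncat * (F_{a+1}(q_{i+1}) - F_{a+1}(q_i))
# for X ~ Gamma(shape = a, rate = a).
discrete_gamma_rates <- function(shape, ncat = 8) {
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = shape, rate = shape)
  p1 <- stats::pgamma(q, shape = shape + 1, rate = shape)
  r <- ncat * diff(p1)
  r / mean(r) * 1  # exact mean 1 (guards qgamma tail rounding)
}

# category rates and probabilities of the full mixture
.lmm_categories <- function(het) {
  switch(het$kind,
    single = list(rates = 1, probs = 1),
    I = list(rates = c(0, 1),
             probs = c(het$p_invariant, 1 - het$p_invariant)),
    G = list(rates = discrete_gamma_rates(het$gamma_shape, het$n_categories),
             probs = rep(1 / het$n_categories, het$n_categories)),
    IG = list(rates = c(0, discrete_gamma_rates(het$gamma_shape, het$n_categories)),
              probs = c(het$p_invariant,
                        rep((1 - het$p_invariant) / het$n_categories,
                            het$n_categories))))
}

# tip conditional likelihoods: 4 x npat indicator matrices per tip
.lmm_tip_conditionals <- function(alignment, struct) {
  lapply(seq_along(alignment$taxa), function(i) {
    tip <- struct$tip_of_taxon[i]
    m <- matrix(1, 4, ncol(alignment$patterns))
    obs <- alignment$patterns[i, ]
    known <- !is.na(obs)
    if (any(known)) {
      m[, known] <- 0
      m[cbind(obs[known], which(known))] <- 1
    }
    m
  })
}

# per-pattern log-likelihood for one rate category (Q scaled by the rate)
.lmm_prune_cat <- function(struct, tipcond_by_node, Q, pi, rate) {
  npat <- ncol(tipcond_by_node[[1]])
  edge <- struct$edge
  partial <- vector("list", struct$ntip + struct$tree$Nnode)
  logscale <- rep(0, npat)
  Ms <- lapply(seq_len(nrow(edge)), function(k) {
    t_eff <- struct$lengths[k] * rate
    if (t_eff == 0) diag(4) else .lmm_expm(Q * t_eff)
  })
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    Lch <- if (ch <= struct$ntip) tipcond_by_node[[ch]] else partial[[ch]]
    contrib <- crossprod(Ms[[k]], Lch)     # t(M) %*% L: child -> parent
    partial[[par]] <- if (is.null(partial[[par]])) contrib
                      else partial[[par]] * contrib
    mx <- apply(partial[[par]], 2, max)
    pos <- mx > 0
    partial[[par]][, pos] <- sweep(partial[[par]][, pos, drop = FALSE], 2,
                                   mx[pos], "/")
    logscale <- logscale + ifelse(pos, log(mx), -Inf)
    if (any(!pos)) partial[[par]][, !pos] <- 0
  }
  site <- as.vector(pi %*% partial[[struct$root]])
  out <- rep(-Inf, npat)
  pos <- site > 0
  out[pos] <- log(site[pos]) + logscale[pos]
  out
}

.lmm_lnl_core <- function(alignment, struct, Q, pi, het) {
  cats <- .lmm_categories(het)
  tipcond <- .lmm_tip_conditionals(alignment, struct)
  # reindex tip conditionals by tip number in the tree
  bynode <- vector("list", struct$ntip)
  for (i in seq_along(tipcond)) bynode[[struct$tip_of_taxon[i]]] <- tipcond[[i]]
  ll <- vapply(seq_along(cats$rates), function(ci)
    .lmm_prune_cat(struct, bynode, Q, pi, cats$rates[ci]),
    numeric(ncol(alignment$patterns)))
  ll <- matrix(ll, ncol = length(cats$rates))
  # mix categories in log space
  lp <- log(cats$probs)
  site <- apply(ll, 1, function(row) {
    m <- max(row + lp)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(row + lp - m)))
  })
  sum(site * alignment$weights)
}

# Build Q and pi from a model + parameter list.
.lmm_model_Q <- function(model, params) {
  if (inherits(model, "lmm_model")) {
    b <- if (is.null(params$b)) numeric(model$dimension - 1) else params$b
    Q <- cartesian_to_rate(model, b, trace = -4)
    list(Q = Q, pi = equilibrium_frequencies(Q))
  } else if (inherits(model, "lmm_rev_model")) {
    rates <- if (is.null(params$rates)) rep(1, model$n_classes) else params$rates
    freqs <- if (is.null(params$freqs)) rep(0.25, 4) else params$freqs
    Q <- rev_rate_matrix(model, rates, freqs, trace = -4)
    list(Q = Q, pi = equilibrium_frequencies(Q))
  } else stop("model must be an lmm_model or lmm_rev_model")
}

#' Log-likelihood of an alignment on a rooted tree
#'
#' Felsenstein pruning over compressed site patterns.  The root state
#' distribution equals the equilibrium distribution of the rate matrix (the
#' same distribution for every rate category); branch transition matrices are
#' exp(Q * t * r) with Q at trace -4 and r the category rate.  Missing data
#' contribute a partial likelihood of one.
#'
#' @param alignment an [lmm_alignment()].
#' @param phylogeny rooted `phylo` with branch lengths.
#' @param model an [build_model()] or [modeltest_model()] object.
#' @param params list: `b` (Cartesian parameters) for Lie models; `rates`,
#'   `freqs` for reversible models.
#' @param heterogeneity an [rate_heterogeneity()] or its `kind` string.
#' @return log-likelihood (scalar).
#' @export
log_likelihood <- function(alignment, phylogeny, model, params = list(),
                           heterogeneity = "single") {
  het <- .lmm_het(heterogeneity)
  struct <- .lmm_tree_struct(phylogeny, alignment$taxa)
  qp <- .lmm_model_Q(model, params)
  if (!is_stochastic(qp$Q)) stop("parameters give a nonstochastic rate matrix")
  .lmm_lnl_core(alignment, struct, qp$Q, qp$pi, het)
}

# ---- optimization ---------------------------------------------------------

# parameter vector layout: [model params][branch lengths][p_inv][log shape]
.lmm_par_layout <- function(model, nbranch, het) {
  if (inherits(model, "lmm_model")) {
    nm <- model$dimension - 1
    lower <- rep(-1, nm); upper <- rep(1, nm)
  } else {
    nm <- (model$n_classes - 1) + if (model$free_freqs) 3 else 0
    lower <- rep(-7, nm); upper <- rep(7, nm)
  }
  lower <- c(lower, rep(1e-8, nbranch)); upper <- c(upper, rep(30, nbranch))
  has_i <- .lmm_het_has_i(het); has_g <- .lmm_het_has_g(het)
  if (has_i) { lower <- c(lower, 1e-6); upper <- c(upper, 0.95) }
  if (has_g) { lower <- c(lower, log(0.02)); upper <- c(upper, log(200)) }
  list(n_model = nm, nbranch = nbranch, has_i = has_i, has_g = has_g,
       lower = lower, upper = upper)
}

.lmm_het_has_i <- function(het) het$kind %in% c("I", "IG")
.lmm_het_has_g <- function(het) het$kind %in% c("G", "IG")

.lmm_unpack <- function(par, layout, model, het) {
  nm <- layout$n_model
  mp <- par[seq_len(nm)]
  bl <- par[nm + seq_len(layout$nbranch)]
  idx <- nm + layout$nbranch
  pinv <- if (layout$has_i) par[idx <- idx + 1] else 0
  shape <- if (layout$has_g) exp(par[idx + 1]) else 1
  params <- if (inherits(model, "lmm_model")) list(b = mp) else {
    k <- model$n_classes - 1
    rates <- c(1, if (k) exp(mp[seq_len(k)]))
    freqs <- if (model$free_freqs) {
      e <- exp(c(0, mp[k + 1:3])); e / sum(e)
    } else rep(0.25, 4)
    list(rates = rates, freqs = freqs)
  }
  het2 <- rate_heterogeneity(het$kind, p_invariant = pinv, gamma_shape = shape,
                             n_categories = het$n_categories)
  list(params = params, branch = bl, het = het2)
}

.lmm_objective <- function(alignment, struct0, model, het, layout) {
  force(alignment); force(struct0); force(model); force(het); force(layout)
  function(par) {
    up <- .lmm_unpack(par, layout, model, het)
    struct <- struct0
    struct$lengths <- up$branch
    qp <- tryCatch(.lmm_model_Q(model, up$params), error = function(e) NULL)
    if (is.null(qp)) return(1e10)
    ll <- tryCatch(.lmm_lnl_core(alignment, struct, qp$Q, qp$pi, up$het),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

# bounded cyclic line search (Brent per coordinate): the hill climb proper.
.lmm_cyclic_polish <- function(fn, par, lower, upper, tol = 1e-6,
                               max_cycles = 8) {
  f0 <- fn(par)
  for (cyc in seq_len(max_cycles)) {
    f_start <- f0
    for (i in seq_along(par)) {
      g <- function(x) { p <- par; p[i] <- x; fn(p) }
      lo <- max(lower[i], par[i] - 0.5 * (upper[i] - lower[i]))
      hi <- min(upper[i], par[i] + 0.5 * (upper[i] - lower[i]))
      opt <- stats::optimize(g, lower = lo, upper = hi, tol = 1e-7)
      if (opt$objective < f0) { par[i] <- opt$minimum; f0 <- opt$objective }
    }
    if (f_start - f0 < tol) break
  }
  list(par = par, value = f0)
}

#' Maximum-likelihood fit of one model on a fixed topology
#'
#' Optimizes model parameters (bounded Cartesian hypercube for Lie models;
#' log exchangeabilities and frequency log-ratios for reversible models),
#' branch lengths, and heterogeneity parameters by bounded quasi-Newton
#' warm-start followed by cyclic derivative-free line search (the Cartesian
#' map is continuous but not smooth).  The overall rate scale is fixed by the
#' trace -4 convention and absorbed into branch lengths.
#'
#' @param alignment an [lmm_alignment()].
#' @param phylogeny rooted `phylo` with branch lengths (initial values).
#' @param model an [build_model()] or [modeltest_model()] object, or a model
#'   name accepted by [resolve_model()].
#' @param heterogeneity [rate_heterogeneity()] or kind string.
#' @param seed integer seed controlling restart draws.
#' @param restarts number of optimization starts (first is deterministic:
#'   Jukes-Cantor parameters, input branch lengths).
#' @param hessian if TRUE, also return the observed-information standard
#'   errors of the model parameters.
#' @return object of class `lmm_fit`: `model`, `het`, `lnL`, `params`,
#'   `branch_lengths`, `tree` (optimized lengths), `Q`, `pi`, `k`, `n_sites`,
#'   `BIC`, `AICc`, `restart_log`, optionally `se_model`.
#' @export
fit_model <- function(alignment, phylogeny, model, heterogeneity = "single",
                      seed = NULL, restarts = 3, hessian = FALSE) {
  if (is.character(model)) model <- resolve_model(model)
  het <- .lmm_het(heterogeneity)
  struct0 <- .lmm_tree_struct(phylogeny, alignment$taxa)
  nbranch <- nrow(struct0$edge)
  layout <- .lmm_par_layout(model, nbranch, het)
  fn <- .lmm_objective(alignment, struct0, model, het, layout)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  init0 <- c(rep(0, layout$n_model),
             pmax(struct0$lengths, 1e-4),
             if (layout$has_i) 0.1, if (layout$has_g) 0)
  best <- NULL; rlog <- list()
  for (r in seq_len(max(1, restarts))) {
    init <- if (r == 1) init0 else {
      jit <- init0
      jit[seq_len(layout$n_model)] <- if (inherits(model, "lmm_model"))
        stats::runif(layout$n_model, -0.8, 0.8) else
        stats::rnorm(layout$n_model, 0, 1)
      bi <- layout$n_model + seq_len(nbranch)
      jit[bi] <- jit[bi] * exp(stats::rnorm(nbranch, 0, 0.3))
      jit
    }
    o <- tryCatch(
      stats::optim(init, fn, method = "L-BFGS-B", lower = layout$lower,
                   upper = layout$upper,
                   control = list(maxit = 300, factr = 1e9)),
      error = function(e) list(par = init, value = fn(init)))
    pol <- .lmm_cyclic_polish(fn, o$par, layout$lower, layout$upper)
    rlog[[r]] <- list(restart = r, lnL = -pol$value)
    if (is.null(best) || pol$value < best$value) best <- pol
  }
  up <- .lmm_unpack(best$par, layout, model, het)
  qp <- .lmm_model_Q(model, up$params)
  tree <- struct0$tree
  tree$edge.length <- up$branch
  k <- (if (inherits(model, "lmm_model")) model$dimension else model$dimension) -
       1 + nbranch + layout$has_i + layout$has_g
  n <- alignment$n_sites
  lnL <- -best$value
  out <- list(model = model, het = up$het, lnL = lnL, params = up$params,
              branch_lengths = up$branch, tree = tree, Q = qp$Q, pi = qp$pi,
              k = k, n_sites = n,
              BIC = k * log(n) - 2 * lnL,
              AICc = 2 * k - 2 * lnL + 2 * k * (k + 1) / max(n - k - 1, 1),
              restart_log = rlog)
  if (hessian && layout$n_model > 0) {
    H <- tryCatch(stats::optimHess(best$par, fn), error = function(e) NULL)
    if (!is.null(H)) {
      cov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(cov)) {
        v <- diag(cov)[seq_len(layout$n_model)]
        out$se_model <- sqrt(pmax(v, 0))
        out$cov <- cov
      }
    }
  }
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Fit: ", x$model$name, " +", x$het$kind, "  lnL = ", sprintf("%.4f", x$lnL),
      "  k = ", x$k, "  BIC = ", sprintf("%.4f", x$BIC), "\n", sep = "")
  invisible(x)
}

#' Resolve a model name to a registry or panel object
#'
#' Accepts structure names (`"5.6b"`), pairing-prefixed names (`"WS3.4"`),
#' classical aliases (`"K2ST"`, `"GM"`, ...) and ModelTest names; ModelTest
#' names that are also Lie Markov models (JC, K80, K81, TrNef, F81) resolve
#' to their registry entries.
#'
#' @param name model name.
#' @return `lmm_model` or `lmm_rev_model`.
#' @export
resolve_model <- function(name) {
  lie_try <- tryCatch(build_model(name), error = function(e) NULL)
  if (!is.null(lie_try)) return(lie_try)
  al <- names(.lmm_aliases)[match(name, .lmm_aliases)]
  if (!is.na(al)) {
    return(build_model(al, if (name == "SSM") "WS" else "RY"))
  }
  if (name %in% names(.lmm_rev_defs)) {
    lie <- .lmm_rev_defs[[name]]$lie
    if (!is.na(lie)) return(build_model(lie))
    return(modeltest_model(name))
  }
  stop("cannot resolve model name '", name, "'")
}

#' Fit a panel of models and rank by information criterion
#'
#' The ModelTest-style pipeline over a fixed topology: every (model,
#' heterogeneity) combination is optimized by [fit_model()] and ranked by
#' BIC, with AICc reported alongside.
#'
#' @param alignment an [lmm_alignment()].
#' @param models character vector of model names ([resolve_model()] syntax);
#'   `"lie"` expands to the 99 Lie Markov variants, `"all"` to the 108-model
#'   panel.
#' @param heterogeneities subset of `c("single","I","G","IG")`.
#' @param tree optional rooted `phylo`; defaults to the midpoint-rooted
#'   neighbor-joining tree on Jukes-Cantor distances.
#' @param seed integer seed.
#' @param restarts optimization starts per fit.
#' @return data.frame sorted by BIC with columns `model`, `het`, `lnL`, `k`,
#'   `BIC`, `dBIC`, `AICc`, `dAICc`; the fitted objects are attached as
#'   attribute `"fits"`.
#' @export
model_scan <- function(alignment, models = "all",
                       heterogeneities = c("single", "I", "G", "IG"),
                       tree = NULL, seed = NULL, restarts = 1) {
  if (identical(models, "lie") || identical(models, "all")) {
    panel <- list_models(pairing_variants = TRUE,
                         modeltest = identical(models, "all"))$name
  } else panel <- models
  if (is.null(tree)) {
    tree <- midpoint_root(neighbor_joining(jc_distance(alignment)))
  }
  rows <- list(); fits <- list()
  for (mn in panel) for (h in heterogeneities) {
    f <- fit_model(alignment, tree, mn, heterogeneity = h, seed = seed,
                   restarts = restarts)
    tag <- paste0(mn, "+", h)
    fits[[tag]] <- f
    rows[[tag]] <- data.frame(model = mn, het = h, lnL = f$lnL, k = f$k,
                              BIC = f$BIC, AICc = f$AICc)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$BIC), ]
  out$dBIC <- out$BIC - min(out$BIC)
  out$dAICc <- out$AICc - min(out$AICc)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
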