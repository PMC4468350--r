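# Sequence simulation under any registered model on a rooted tree: the
# generative law is M = exp(Q t) applied down each branch, with root states
# drawn from the model's equilibrium distribution.

#' Simulate an alignment under a model on a rooted tree
#'
#' Root states are drawn from the equilibrium distribution of Q; each branch
#' applies the column-stochastic transition matrix exp(Q * t * r) with the
#' per-site rate r drawn from the heterogeneity mixture (invariant sites keep
#' the root state everywhere).
#'
#' @param phylogeny rooted `phylo` with branch lengths.
#' @param model [build_model()] / [modeltest_model()] object or model name.
#' @param params as in [log_likelihood()]: `b` for Lie models (default 0,
#'   i.e. Jukes-Cantor), `rates`/`freqs` for reversible models.
#' @param n_sites number of sites.
#' @param heterogeneity [rate_heterogeneity()] or kind string.
#' @param seed integer seed (mandatory for reproducible fixtures).
#' @return [lmm_alignment()] with attribute `"truth"` recording the
#'   generating Q, parameters, rates and tree.
#' @export
simulate_alignment <- function(phylogeny, model, params = list(),
                               n_sites = 1000, heterogeneity = "single",
                               seed) {
  if (is.character(model)) model <- resolve_model(model)
  het <- .lmm_het(heterogeneity)
  qp <- .lmm_model_Q(model, params)
  if (!is_stochastic(qp$Q)) stop("parameters give a nonstochastic rate matrix")
  set.seed(seed)
  cats <- .lmm_categories(het)
  rate <- sample(cats$rates, n_sites, replace = TRUE, prob = cats$probs)
  tr <- ape::reorder.phylo(phylogeny, "cladewise")   # parents before children
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tr$Nnode
  states <- matrix(NA_integer_, nnode, n_sites)
  states[root, ] <- sample.int(4, n_sites, replace = TRUE, prob = qp$pi)
  urates <- sort(unique(rate))
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    t_b <- tr$edge.length[k]
    for (r in urates) {
      sel <- rate == r
      if (!any(sel)) next
      if (t_b * r == 0) {
        states[ch, sel] <- states[par, sel]
        next
      }
      M <- .lmm_expm(qp$Q * t_b * r)          # columns: initial state
      M <- pmax(M, 0); M <- sweep(M, 2, colSums(M), "/")
      for (s in 1:4) {
        from <- sel & states[par, ] == s
        n_from <- sum(from)
        if (n_from) states[ch, from] <- sample.int(4, n_from, replace = TRUE,
                                                   prob = M[, s])
      }
    }
  }
  bases <- lmm_base_order("canonical")
  seqs <- lapply(seq_len(ntip), function(i)
    paste(bases[states[i, ]], collapse = ""))
  names(seqs) <- tr$tip.label
  aln <- lmm_alignment(unlist(seqs))
  attr(aln, "truth") <- list(model = model$name, params = params, Q = qp$Q,
                             pi = qp$pi, het = het, site_rates = rate,
                             tree = phylogeny, seed = seed)
  aln
}

#' Deterministic fixture suite
#'
#' A bundle of simulated alignments + trees + true parameters spanning the
#' equilibrium-frequency classes (0-3 degrees of freedom), reversible and
#' nonreversible models, and all heterogeneity kinds.  Same seed, same bytes.
#'
#' @param seed integer seed.
#' @param n_sites sites per fixture.
#' @return named list of fixtures; each has `alignment`, `tree`, `truth`.
#' @export
make_fixture_suite <- function(seed = 1, n_sites = 2000) {
  tree4 <- ape::read.tree(text = "((t1:0.15,t2:0.25):0.1,(t3:0.2,t4:0.3):0.05);")
  tree8 <- ape::read.tree(text = paste0(
    "(((t1:0.1,t2:0.12):0.05,(t3:0.08,t4:0.2):0.07):0.04,",
    "((t5:0.15,t6:0.1):0.06,(t7:0.18,t8:0.09):0.08):0.03);"))
  specs <- list(
    jc_single    = list(model = "1.1",   b = numeric(0), het = "single", tree = tree4),
    k2st_gamma   = list(model = "RY2.2b", b = 0.6, het = "G", tree = tree4),
    m34_inv      = list(model = "3.4",   b = c(0.5, 0.3), het = "I", tree = tree4),
    f81_skew     = list(model = "4.4a",  b = c(0.5, 0.3, -0.2), het = "single", tree = tree8),
    ry56b_ig     = list(model = "RY5.6b", b = c(0.5, 0.2, 0.3, -0.2), het = "IG", tree = tree8),
    ds920b_flat  = list(model = "9.20b", b = c(0.3, 0.2, -0.2, 0.1, 0.15, -0.1, 0.2, -0.15), het = "single", tree = tree4)
  )
  out <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    het <- switch(sp$het,
      single = rate_heterogeneity("single"),
      I = rate_heterogeneity("I", p_invariant = 0.2),
      G = rate_heterogeneity("G", gamma_shape = 0.8),
      IG = rate_heterogeneity("IG", p_invariant = 0.15, gamma_shape = 1.2))
    aln <- simulate_alignment(sp$tree, sp$model, list(b = sp$b),
                              n_sites = n_sites, heterogeneity = het,
                              seed = seed + i)
    out[[names(specs)[i]]] <- list(alignment = aln, tree = sp$tree,
                                   truth = attr(aln, "truth"))
  }
  out
}
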