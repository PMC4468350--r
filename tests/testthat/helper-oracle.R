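# Independent oracles and small fixture builders used across the test files.
# Everything here is deliberately naive: truncated-series exponentials,
# exhaustive enumeration over internal states, and numeric integration for
# the gamma category means.  None of it shares code with the package paths
# it checks.

oracle_expm <- function(Q) {
  # scaling + truncated Taylor series; ample accuracy for 4x4 generators
  Q <- unname(Q)
  s <- max(0L, ceiling(log2(max(sum(abs(Q)), 1))))
  A <- Q / 2^s
  M <- diag(4); term <- diag(4)
  for (i in 1:40) { term <- term %*% A / i; M <- M + term }
  for (i in seq_len(s)) M <- M %*% M
  M
}

oracle_gamma_rates <- function(shape, ncat = 8) {
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape, rate = shape)
  vapply(seq_len(ncat), function(i) {
    lo <- q[i]; hi <- min(q[i + 1], stats::qgamma(1 - 1e-12, shape, rate = shape))
    ncat * stats::integrate(function(x) x * stats::dgamma(x, shape, rate = shape),
                            lo, hi, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Exhaustive-enumeration log-likelihood for a rooted tree, summing over all
# internal-node state assignments.  Missing tips marginalize to a factor of
# one (transition-matrix columns sum to one), so their edges are skipped.
oracle_loglik <- function(alignment, tree, Q, pi, kind = "single",
                          pinv = 0, shape = 1, ncat = 8) {
  rates <- 1; probs <- 1
  if (kind %in% c("G", "IG")) {
    rates <- oracle_gamma_rates(shape, ncat); probs <- rep(1 / ncat, ncat)
  }
  if (kind %in% c("I", "IG")) {
    rates <- c(0, rates); probs <- c(pinv, (1 - pinv) * probs)
  }
  pi <- unname(pi)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  tipmap <- match(tr$tip.label, alignment$taxa)
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  total <- 0
  for (p in seq_len(ncol(alignment$patterns))) {
    obs <- alignment$patterns[tipmap, p]
    sitelik <- 0
    for (ci in seq_along(rates)) {
      Ms <- lapply(seq_len(nrow(tr$edge)), function(k)
        oracle_expm(Q * tr$edge.length[k] * rates[ci]))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        states <- c(obs, grid[g, ])
        term <- pi[states[ntip + 1]]
        for (k in seq_len(nrow(tr$edge))) {
          ch <- tr$edge[k, 2]
          if (ch <= ntip && is.na(states[ch])) next
          term <- term * Ms[[k]][states[ch], states[tr$edge[k, 1]]]
        }
        lik <- lik + term
      }
      sitelik <- sitelik + probs[ci] * lik
    }
    total <- total + alignment$weights[p] * log(sitelik)
  }
  total
}

# random alignment over complete data (used where the content is irrelevant)
random_alignment <- function(ntaxa = 4, nsites = 50, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(ntaxa), function(i)
    paste(sample(c("A", "C", "G", "T"), nsites, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("t", seq_len(ntaxa))
  lmm_alignment(seqs)
}

tree4 <- function() {
  ape::read.tree(text = "((t1:0.15,t2:0.25):0.1,(t3:0.2,t4:0.3):0.05);")
}

offdiag <- function(Q) Q[row(Q) != col(Q)]

# rejection sampler over raw basis weights (independent of the Cartesian map)
reject_sample_member <- function(model, n = 1) {
  mats <- model$basis
  out <- list()
  while (length(out) < n) {
    w <- stats::runif(length(mats), -1, 1)
    w[model$basis_names == "A"] <- 1
    Q <- matrix(0, 4, 4)
    for (i in seq_along(mats)) Q <- Q + w[i] * mats[[i]]
    if (min(offdiag(Q)) >= 0) out[[length(out) + 1]] <- Q
  }
  out
}

# Frozen expectations: EBF degrees of freedom and reversibility per structure
expected_structure_props <- data.frame(
  structure = c("1.1", "2.2b", "3.3a", "3.3b", "3.3c", "3.4", "4.4a", "4.4b",
                "4.5a", "4.5b", "5.6a", "5.6b", "5.7a", "5.7b", "5.7c",
                "5.11a", "5.11b", "5.11c", "5.16", "6.6", "6.7a", "6.7b",
                "6.8a", "6.8b", "6.17a", "6.17b", "8.8", "8.10a", "8.10b",
                "8.16", "8.17", "8.18", "9.20a", "9.20b", "10.12", "10.34",
                "12.12"),
  ebf_df = c(0, 0, 0, 0, 0, 1, 3, 1, 1, 1, 0, 3, 2, 0, 0,
             2, 0, 0, 1, 1, 3, 3, 3, 1, 1, 1, 3, 3, 1,
             3, 3, 3, 2, 0, 3, 3, 3),
  reversible = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 rep(FALSE, 29))
)
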