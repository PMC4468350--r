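# The likelihood engine: distances, trees, pruning against the enumeration
# oracle, heterogeneity, fitting and model selection.

test_that("Jukes-Cantor distances follow the closed form", {
  a <- lmm_alignment(c(t1 = "ACGTACGTAC", t2 = "ACGTACGTAC"))
  expect_equal(unname(jc_distance(a)), matrix(0, 2, 2, dimnames = NULL))
  # p = 0.3
  a2 <- lmm_alignment(c(t1 = "AAAAAAAAAA", t2 = "CCCAAAAAAA"))
  expect_equal(jc_distance(a2)[1, 2], -0.75 * log(1 - 0.4 * 1))
  expect_equal(jc_distance(a2)[1, 2], -0.75 * log(0.6))
  a3 <- lmm_alignment(c(t1 = "AAAA", t2 = "CCCC"))
  expect_error(jc_distance(a3), "saturated")
})

test_that("neighbor joining recovers additive trees exactly", {
  true <- ape::read.tree(text = "((t1:0.1,t2:0.2):0.05,t3:0.15,t4:0.3);")
  d <- ape::cophenetic.phylo(true)
  nj <- neighbor_joining(d[paste0("t", 1:4), paste0("t", 1:4)])
  expect_equal(unname(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)]),
               unname(d), tolerance = 1e-10)
  expect_error(neighbor_joining(matrix(0, 2, 2)), "3 taxa")
})

test_that("midpoint rooting splits the diameter in half", {
  two <- ape::read.tree(text = "(t1:0.3,t2:0.7);")
  r2 <- midpoint_root(two)
  expect_true(ape::is.rooted(r2))
  expect_equal(sort(r2$edge.length), c(0.5, 0.5))
  tr <- ape::read.tree(text = "((t1:0.5,t2:0.1):0.2,t3:0.1,t4:0.9);")
  r4 <- midpoint_root(tr)
  # diametral path t1..t4 has length 1.6; both root-side halves are 0.8
  depths <- ape::node.depth.edgelength(r4)
  expect_equal(max(depths[1:4]), 0.8)
  expect_equal(tree_diameter(r4), tree_diameter(tr))
})

test_that("degenerate likelihoods match hand calculations", {
  jc <- build_model("1.1")
  # one site, two identical taxa, both branches zero: lnL = log(1/4)
  a <- lmm_alignment(c(t1 = "A", t2 = "A"))
  tr0 <- ape::read.tree(text = "(t1:0,t2:0);")
  expect_equal(log_likelihood(a, tr0, jc), log(0.25), tolerance = 1e-12)
  # saturated branches: taxa independent, each site likelihood (1/4)^2
  trX <- ape::read.tree(text = "(t1:40,t2:40);")
  expect_equal(log_likelihood(a, trX, jc), log(1 / 16), tolerance = 1e-5)
})

test_that("pruning equals the exhaustive enumeration oracle (all het kinds)", {
  tr <- tree4()
  aln <- simulate_alignment(tr, "RY5.6b", list(b = c(0.5, 0.2, 0.3, -0.2)),
                            n_sites = 120, seed = 51)
  m <- build_model("5.6b", "RY")
  params <- list(b = c(0.5, 0.2, 0.3, -0.2))
  Q <- cartesian_to_rate(m, params$b, trace = -4)
  pi <- equilibrium_frequencies(Q)
  cases <- list(
    list(het = rate_heterogeneity("single"), kind = "single", pinv = 0, shape = 1),
    list(het = rate_heterogeneity("I", p_invariant = 0.25), kind = "I",
         pinv = 0.25, shape = 1),
    list(het = rate_heterogeneity("G", gamma_shape = 0.6), kind = "G",
         pinv = 0, shape = 0.6),
    list(het = rate_heterogeneity("IG", p_invariant = 0.15, gamma_shape = 1.3),
         kind = "IG", pinv = 0.15, shape = 1.3))
  for (cs in cases) {
    got <- log_likelihood(aln, tr, m, params, cs$het)
    want <- oracle_loglik(aln, tr, Q, pi, cs$kind, cs$pinv, cs$shape)
    expect_equal(got, want, tolerance = 1e-10, label = paste("lnL", cs$kind))
  }
})

test_that("the oracle agreement also holds with missing data", {
  tr <- tree4()
  aln <- lmm_alignment(c(t1 = "ACGTN-RAGC", t2 = "ACCTAAGAGC",
                         t3 = "GCGTAAGATC", t4 = "ACGTCA-AGT"))
  m <- build_model("3.4")
  Q <- cartesian_to_rate(m, c(0.4, 0.3), trace = -4)
  pi <- equilibrium_frequencies(Q)
  got <- log_likelihood(aln, tr, m, list(b = c(0.4, 0.3)))
  expect_equal(got, oracle_loglik(aln, tr, Q, pi), tolerance = 1e-10)
})

test_that("pattern compression does not change the likelihood", {
  tr <- tree4()
  set.seed(52)
  # heavily repetitive alignment: compression is substantial
  cols <- replicate(30, sample(c("A", "C", "G", "T"), 4, TRUE))
  idx <- sample(30, 400, TRUE)
  seqs <- apply(cols[, idx], 1, paste, collapse = "")
  names(seqs) <- paste0("t", 1:4)
  aln <- lmm_alignment(seqs)
  expect_lt(ncol(aln$patterns), 31)
  # same sites, shuffled order: identical lnL
  idx2 <- sample(idx)
  seqs2 <- apply(cols[, idx2], 1, paste, collapse = "")
  names(seqs2) <- paste0("t", 1:4)
  aln2 <- lmm_alignment(seqs2)
  m <- build_model("5.6b")
  p <- list(b = c(0.3, 0.1, 0.2, -0.1))
  expect_equal(log_likelihood(aln, tr, m, p), log_likelihood(aln2, tr, m, p),
               tolerance = 1e-10)
})

test_that("root placement matters exactly when the model is nonreversible", {
  # same unrooted tree, root slid along the internal branch
  t_a <- ape::read.tree(text = "((t1:0.1,t2:0.2):0.05,(t3:0.15,t4:0.25):0.10);")
  t_b <- ape::read.tree(text = "((t1:0.1,t2:0.2):0.12,(t3:0.15,t4:0.25):0.03);")
  aln <- simulate_alignment(t_a, "RY5.6b", list(b = c(0.5, 0.2, 0.4, -0.3)),
                            n_sites = 300, seed = 53)
  jc <- build_model("1.1")
  expect_equal(log_likelihood(aln, t_a, jc), log_likelihood(aln, t_b, jc),
               tolerance = 1e-9)
  m34 <- build_model("3.4")      # reversible, nonuniform frequencies
  p34 <- list(b = c(0.4, 0.5))
  expect_equal(log_likelihood(aln, t_a, m34, p34),
               log_likelihood(aln, t_b, m34, p34), tolerance = 1e-9)
  m <- build_model("5.6b", "RY")  # nonreversible when e1 != e2
  p <- list(b = c(0.5, 0.2, 0.4, -0.3))
  expect_gt(abs(log_likelihood(aln, t_a, m, p) -
                log_likelihood(aln, t_b, m, p)), 1e-4)
})

test_that("discrete gamma converges to the single-rate model as shape grows", {
  tr <- tree4()
  aln <- simulate_alignment(tr, "1.1", n_sites = 400, seed = 54)
  m <- build_model("2.2b")
  p <- list(b = 0.5)
  single <- log_likelihood(aln, tr, m, p, "single")
  g <- log_likelihood(aln, tr, m, p,
                      rate_heterogeneity("G", gamma_shape = 1e4))
  expect_equal(g, single, tolerance = 1e-4)
  # and the category rates themselves have mean one
  r <- liemarkov:::discrete_gamma_rates(0.4, 8)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  expect_true(all(diff(r) > 0))
})

test_that("fitting respects nesting and the information-criterion identities", {
  tr <- tree4()
  aln <- simulate_alignment(tr, "RY2.2b", list(b = 0.7), n_sites = 800,
                            seed = 55)
  f_jc <- fit_model(aln, tr, "1.1", restarts = 1)
  f_k2 <- fit_model(aln, tr, "RY2.2b", restarts = 1)
  f_k3 <- fit_model(aln, tr, "3.3a", restarts = 1)
  expect_gte(f_k2$lnL, f_jc$lnL)      # 1.1 nested in 2.2b
  expect_gte(f_k3$lnL, f_k2$lnL - 1e-4)  # 2.2b nested in 3.3a
  for (f in list(f_jc, f_k2, f_k3)) {
    expect_equal(f$BIC, f$k * log(f$n_sites) - 2 * f$lnL, tolerance = 1e-12)
    expect_equal(f$AICc, 2 * f$k - 2 * f$lnL +
                   2 * f$k * (f$k + 1) / (f$n_sites - f$k - 1),
                 tolerance = 1e-12)
  }
  # k bookkeeping: (dimension - 1) + branch count (+ heterogeneity params)
  expect_equal(f_k2$k, (2 - 1) + nrow(tr$edge))
  f_ig <- fit_model(aln, tr, "1.1", "IG", restarts = 1)
  expect_equal(f_ig$k, 0 + nrow(tr$edge) + 2)
})

test_that("the same model under two names fits identically", {
  tr <- tree4()
  aln <- simulate_alignment(tr, "RY2.2b", list(b = 0.6), n_sites = 300,
                            seed = 56)
  f1 <- fit_model(aln, tr, "K80", restarts = 1)
  f2 <- fit_model(aln, tr, "RY2.2b", restarts = 1)
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-6)
  expect_equal(f1$k, f2$k)
})

test_that("reversible panel models reduce correctly under constraints", {
  panel <- reversible_panel_models()
  expect_length(panel, 9)
  expect_setequal(vapply(panel, function(m) m$name, character(1)),
                  c("HKY", "TrN", "K81uf", "TIMef", "TIM", "TVMef", "TVM",
                    "SYM", "GTR"))
  # HKY with equal frequencies is K2ST
  hky_flat <- rev_rate_matrix(modeltest_model("HKY"), c(3, 1),
                              rep(0.25, 4), trace = NULL)
  expect_true(in_model_span(hky_flat, build_model("2.2b", "RY"))$member)
  # SYM equals GTR with flat frequencies
  rates <- c(1.5, 2.5, 0.7, 1.2, 3.0, 0.9)
  expect_equal(rev_rate_matrix(modeltest_model("SYM"), rates),
               rev_rate_matrix(modeltest_model("GTR"), rates, rep(0.25, 4)))
  # the five shared ModelTest models resolve to Lie Markov registry entries
  shares <- c(JC = "1.1", K80 = "2.2b", K81 = "3.3a", TrNef = "3.3c",
              F81 = "4.4a")
  for (nm in names(shares)) {
    r <- resolve_model(nm)
    expect_s3_class(r, "lmm_model")
    expect_equal(r$structure, unname(shares[nm]))
  }
})

test_that("model_scan ranks by BIC with the best at dBIC zero", {
  tr <- tree4()
  aln <- simulate_alignment(tr, "RY2.2b", list(b = 0.75), n_sites = 1500,
                            seed = 57)
  tab <- model_scan(aln, models = c("1.1", "RY2.2b", "3.3a", "GTR"),
                    heterogeneities = "single", tree = tr, restarts = 1)
  expect_equal(tab$dBIC[1], 0)
  expect_equal(tab$model[1], "RY2.2b")   # truth wins at this length
  expect_true(all(diff(tab$BIC) >= 0))
  expect_true(!is.null(attr(tab, "fits")))
})

test_that("tree diameter is the longest leaf-to-leaf path", {
  expect_equal(tree_diameter(ape::read.tree(text = "(t1:0.3,t2:0.4);")), 0.7)
  star <- ape::read.tree(text = "(t1:0.5,t2:0.5,t3:0.5,t4:0.5);")
  expect_equal(tree_diameter(star), 1.0)
})

test_that("branch lengths are recovered from data simulated under JC", {
  tr <- tree4()
  aln <- simulate_alignment(tr, "1.1", n_sites = 20000, seed = 58)
  f <- fit_model(aln, tr, "1.1", restarts = 1)
  # total tree length within 10% at this depth and size
  expect_equal(sum(f$tree$edge.length), sum(tr$edge.length), tolerance = 0.1)
})
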