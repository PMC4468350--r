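# Structure of the hierarchy: basis matrices, catalogue counts, Lie closure,
# nesting, equilibrium degrees of freedom, reversibility, aliases.

test_that("basis matrices satisfy the printed structural constraints", {
  basis <- lapply(c(lmm_basis_names, "A2"), get_basis_matrix)
  names(basis) <- c(lmm_basis_names, "A2")
  # columns sum to zero, everywhere
  for (nm in names(basis)) {
    expect_equal(colSums(basis[[nm]]), rep(0, 4), ignore_attr = TRUE)
  }
  # A is the Jukes-Cantor generator
  expect_equal(unname(basis$A), matrix(1, 4, 4) - 4 * diag(4))
  # A2 = 3 A1 - A
  expect_equal(basis$A2, 3 * basis$A1 - basis$A)
  # D: purine rows +1, pyrimidine rows -1, including the diagonal
  expect_equal(unname(basis$D), rbind(rep(1, 4), rep(1, 4), rep(-1, 4), rep(-1, 4)))
  # exactly nine of the twelve are doubly stochastic
  ds <- names(which(vapply(basis[lmm_basis_names], function(m)
    max(abs(rowSums(m))) < 1e-12, logical(1))))
  expect_setequal(ds, c("A", "A1", "B", "C", "D1", "F1", "F2", "G1", "G2"))
})

test_that("the five-parameter weight form of Q5.6b is reproduced entry-exactly", {
  # hand transcription of the printed matrix, parameters a, a2, d, e1, e2
  Q56b <- function(a, a2, d, e1, e2) rbind(
    c(-3*a + d + e1, a + 2*a2 + d + e1, a - a2 + d + e1, a - a2 + d + e1),
    c(a + 2*a2 + d - e1, -3*a + d - e1, a - a2 + d - e1, a - a2 + d - e1),
    c(a - a2 - d + e2, a - a2 - d + e2, -3*a - d + e2, a + 2*a2 - d + e2),
    c(a - a2 - d - e2, a - a2 - d - e2, a + 2*a2 - d - e2, -3*a - d - e2))
  m <- build_model("5.6b", use_A2 = TRUE)
  set.seed(11)
  for (i in 1:5) {
    w <- rnorm(5)
    expect_equal(unname(from_weights(m, w)), Q56b(w[1], w[2], w[3], w[4], w[5]),
                 tolerance = 1e-14)
  }
  # and the printed Q3.4 with parameters a, a2, d
  Q34 <- function(a, a2, d) rbind(
    c(-3*a + d, a + 2*a2 + d, a - a2 + d, a - a2 + d),
    c(a + 2*a2 + d, -3*a + d, a - a2 + d, a - a2 + d),
    c(a - a2 - d, a - a2 - d, -3*a - d, a + 2*a2 - d),
    c(a - a2 - d, a - a2 - d, a + 2*a2 - d, -3*a - d))
  m34 <- build_model("3.4", use_A2 = TRUE)
  for (i in 1:5) {
    w <- rnorm(3)
    expect_equal(unname(from_weights(m34, w)), Q34(w[1], w[2], w[3]),
                 tolerance = 1e-14)
  }
})

test_that("pairing permutations are involutions and produce distinct variants", {
  for (code in c("RY", "WS", "MK")) {
    p <- lmm_pairing(code)
    expect_identical(p$perm[p$perm], 1:4)
  }
  # WS distinguishes AT|CG: the transition generator must couple A with T
  A1ws <- get_basis_matrix("A1", "WS")
  expect_equal(A1ws["A", "T"], 1)
  expect_equal(A1ws["A", "G"], 0)
  A1mk <- get_basis_matrix("A1", "MK")
  expect_equal(A1mk["A", "C"], 1)
})

test_that("catalogue counts: 37 structures, 99 variants, 108 with ModelTest", {
  expect_equal(nrow(list_models()), 37)
  expect_equal(nrow(list_models(pairing_variants = TRUE)), 99)
  expect_equal(nrow(list_models(pairing_variants = TRUE, modeltest = TRUE)), 108)
})

test_that("model 2.2a is hidden but constructible", {
  expect_error(build_model("2.2a"), "forbids transversions")
  expect_false("2.2a" %in% list_models()$structure)
  m <- build_model("2.2a", allow_hidden = TRUE)
  expect_setequal(m$basis_names, c("A1", "D1"))
})

test_that("every registered model span is closed under the commutator", {
  worst <- 0
  for (nm in list_models(pairing_variants = TRUE)$name) {
    r <- verify_lie_closure(build_model(nm))
    worst <- max(worst, r$max_residual)
  }
  expect_lt(worst, 1e-10)
})

test_that("GTR, for contrast, is not multiplicatively closed", {
  g <- modeltest_model("GTR")
  Q1 <- rev_rate_matrix(g, c(4, 2, 1, 1.5, 0.7, 1.2), c(0.4, 0.3, 0.2, 0.1))
  Q2 <- rev_rate_matrix(g, c(1, 5, 2, 0.5, 1.8, 0.9), c(0.15, 0.2, 0.3, 0.35))
  res <- product_rate(Q1 * 0.8, Q2 * 0.8)
  expect_false(is.null(res$Qprime))
  Qp <- Re(res$Qprime)
  pi <- equilibrium_frequencies(Qp)
  db <- outer(1:4, 1:4, function(i, j) pi[i] * Qp[cbind(j, i)] - pi[j] * Qp[cbind(i, j)])
  expect_gt(max(abs(db)), 1e-4)   # detailed balance broken: Q' is not GTR
})

test_that("exactly 31 structures have pairwise distinct RY/WS/MK spans", {
  span <- function(nm, p) t(vapply(build_model(nm, p)$basis, as.vector, numeric(16)))
  same <- function(S1, S2) {
    r <- function(S) sum(svd(S)$d > 1e-9 * max(svd(S)$d))
    r(rbind(S1, S2)) == r(S1) && r(S1) == r(S2)
  }
  sym <- character(0); distinct <- 0
  for (nm in list_models()$structure) {
    s <- lapply(c("RY", "WS", "MK"), function(p) span(nm, p))
    eq <- c(same(s[[1]], s[[2]]), same(s[[1]], s[[3]]), same(s[[2]], s[[3]]))
    if (all(eq)) sym <- c(sym, nm) else { expect_false(any(eq)); distinct <- distinct + 1 }
  }
  expect_equal(distinct, 31)
  expect_setequal(sym, c("1.1", "3.3a", "4.4a", "6.7a", "9.20b", "12.12"))
})

test_that("doubly stochastic submodels of 9.20b have zero row sums everywhere", {
  # 3.3c belongs in this list too: its basis {A, A1, D1} is drawn from the
  # doubly stochastic nine (TrNef has flat equilibrium frequencies)
  ds_models <- c("1.1", "2.2b", "3.3a", "3.3b", "3.3c", "5.6a", "5.7b",
                 "5.7c", "5.11b", "5.11c")
  m920b <- build_model("9.20b")
  set.seed(4)
  for (nm in ds_models) {
    m <- build_model(nm)
    expect_true(is_nested(m, m920b), label = paste(nm, "nested in 9.20b"))
    w <- runif(m$dimension, -1, 1)
    expect_lt(max(abs(rowSums(from_weights(m, w)))), 1e-12)
  }
})

test_that("nesting is reflexive/transitive and matches published examples", {
  m11 <- build_model("1.1")
  for (nm in c("2.2b", "3.4", "5.6b", "9.20b", "12.12")) {
    expect_true(is_nested(m11, build_model(nm)))
  }
  # F81 is a submodel of RY5.6b
  expect_true(is_nested(build_model("4.4a"), build_model("5.6b", "RY")))
  # RY5.7a nested in (fully symmetric) 6.7a, hence in WS8.10a by transitivity
  expect_true(is_nested(build_model("5.7a", "RY"), build_model("6.7a")))
  expect_true(is_nested(build_model("6.7a"), build_model("8.10a", "WS")))
  expect_true(is_nested(build_model("5.7a", "RY"), build_model("8.10a", "WS")))
  # basis-subset nestings
  expect_true(is_nested(build_model("3.4"), build_model("4.4b")))
  # non-nestings
  expect_false(is_nested(build_model("4.4a"), build_model("3.4")))
  expect_false(is_nested(build_model("2.2b", "RY"), build_model("2.2b", "WS")))
  # antisymmetry on spans: mutual nesting only for identical spans
  expect_false(is_nested(build_model("5.6b"), build_model("4.4a")))
})

test_that("EBF degrees of freedom and reversibility match the published table", {
  for (i in seq_len(nrow(expected_structure_props))) {
    nm <- expected_structure_props$structure[i]
    m <- build_model(nm)
    expect_equal(ebf_degrees_of_freedom(m), expected_structure_props$ebf_df[i],
                 label = paste("EBFDF of", nm))
  }
  # reversibility by sampled detailed balance (subset keeps this test quick;
  # the full 37 runs in the acceptance suite)
  spot <- c("1.1", "2.2b", "3.3a", "3.3b", "3.3c", "3.4", "4.4a", "4.4b",
            "5.6b", "6.6", "9.20b", "12.12")
  for (nm in spot) {
    expected <- expected_structure_props$reversible[expected_structure_props$structure == nm]
    expect_equal(is_time_reversible(build_model(nm), n = 25), expected,
                 label = paste("reversibility of", nm))
  }
})

test_that("aliases resolve to the classical rate-matrix sets", {
  # span{A, A1} is exactly the K2ST set
  k80 <- modeltest_model("K80")
  m22b <- build_model("2.2b", "RY")
  set.seed(9)
  for (i in 1:5) {
    Q <- rev_rate_matrix(k80, sort(runif(2, 0.1, 3), decreasing = TRUE))
    expect_true(in_model_span(Q, m22b)$member)
  }
  # 4.4a is F81
  f81 <- modeltest_model("F81")
  m44a <- build_model("4.4a")
  for (i in 1:5) {
    Q <- rev_rate_matrix(f81, 1, runif(4, 0.5, 2))
    expect_true(in_model_span(Q, m44a)$member)
  }
  # 12.12 is the general Markov model: spans all zero-column-sum matrices
  expect_equal(build_model("12.12")$dimension, 12)
  expect_equal(build_model("2.2b")$alias, "K2ST")
  expect_equal(build_model("12.12")$alias, "GM")
  expect_equal(resolve_model("TrNef")$structure, "3.3c")
  expect_equal(resolve_model("GM")$structure, "12.12")
})

test_that("unknown names produce informative errors", {
  expect_error(get_basis_matrix("Z"), "valid labels")
  expect_error(build_model("7.7"), "unknown")
  expect_error(resolve_model("HKY86"), "cannot resolve")
})

test_that("catalogue and DOT exports are well formed", {
  cat37 <- model_catalogue()
  expect_equal(nrow(cat37), 37)
  expect_true(all(c("ebf_df", "reversible", "rays") %in% names(cat37)))
  expect_equal(cat37$alias[cat37$name == "1.1"], "JC")
  dot <- nesting_graph_dot()
  expect_match(dot, "digraph")
  expect_match(dot, "\"1.1\" -> \"2.2b\"", fixed = TRUE)
  # covering edges only: 1.1 -> 12.12 must be absent (goes via intermediates)
  expect_false(grepl("\"1.1\" -> \"12.12\"", dot, fixed = TRUE))
})
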