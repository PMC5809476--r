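test_that("TPM normalization and the zero substitution are exact", {
  tpm <- normalize_tpm(matrix(c(10, 0), 2, 1,
                              dimnames = list(c("a", "b"), "l1")),
                       c(l1 = 2e6))
  expect_equal(tpm["a", "l1"], 5)
  expect_equal(tpm["b", "l1"], 0.01)
  expect_error(normalize_tpm(matrix(-1), c(A = 10)), "negative")
  # conservation bound
  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(NULL, paste0("l", 1:4)))
  tpm <- normalize_tpm(m, setNames(rep(1000, 4), paste0("l", 1:4)))
  expect_true(all(colSums(tpm) <= 1e6 + 1e-6))
})

test_that("the low-expression filter keeps 'at least 1 TPM somewhere'", {
  tpm <- rbind(a = c(0.5, 0.9, 0.2, 0.8),
               b = c(0.5, 1.0, 0.2, 0.8),
               c = c(2, 3, 4, 5))
  kept <- filter_low_expression(tpm)
  expect_setequal(rownames(kept), c("b", "c"))
})

test_that("point probabilities match closed forms and sum to one", {
  expect_equal(ac_point_probability(0, 0, 1, 1), 0.5)
  expect_equal(ac_point_probability(5, 5, 1e6, 1e6), 252 / 2048,
               tolerance = 1e-12)
  for (x in c(0, 1, 3, 10))
    for (r in c(0.5, 1, 2))
      expect_equal(sum(ac_point_probability(0:3000, x, 1, r)), 1,
                   tolerance = 1e-9)
  expect_error(ac_point_probability(1.5, 1, 1, 1), "integer")
})

test_that("tail probabilities and two-sided p behave as defined", {
  t55 <- ac_test(5, 5, 1e6, 1e6)
  expect_equal(t55$C, 0.5, tolerance = 1e-12) # exact for x = y, N1 = N2
  expect_equal(t55$p_value, 1)
  t00 <- ac_test(0, 0, 3e6, 3e6)
  expect_equal(t00$C, 0.5)
  expect_equal(t00$D, 1)
  expect_equal(t00$p_value, 1)
  expect_lt(ac_test(100, 0, 1e6, 1e6)$p_value, 1e-20)
  # C + D = 1 + p(y|x); symmetry; monotonicity
  set.seed(2)
  for (i in 1:25) {
    x <- sample(0:80, 1); y <- sample(0:80, 1)
    n1 <- sample(1:5, 1) * 1e5; n2 <- sample(1:5, 1) * 1e5
    tt <- ac_test(x, y, n1, n2)
    expect_equal(tt$C + tt$D, 1 + tt$p_obs, tolerance = 1e-9)
    # for equal library totals the point mass is exactly symmetric and the
    # doubled-tail p can differ between (x,y) and (y,x) by at most twice
    # the shared point mass (exact at x=0,y=1: p = 1 vs 1/2)
    eq <- ac_test(x, y, n1, n1)
    sw <- ac_test(y, x, n1, n1)
    expect_equal(eq$p_obs, sw$p_obs, tolerance = 1e-9)
    expect_lte(abs(eq$p_value - sw$p_value), 2 * eq$p_obs + 1e-9)
  }
  Cs <- vapply(0:30, function(y) ac_test(7, y, 1e6, 2e6)$C, numeric(1))
  Ds <- vapply(0:30, function(y) ac_test(7, y, 1e6, 2e6)$D, numeric(1))
  expect_true(all(diff(Cs) >= -1e-12))
  expect_true(all(diff(Ds) <= 1e-12))
})

test_that("log-space tails match the summation oracle on a small grid", {
  for (r in c(0.5, 1, 2)) {
    for (x in 0:12) for (y in 0:12) {
      got <- ac_test(x, y, 1e6, r * 1e6)
      want <- oracle_ac(x, y, 1e6, r * 1e6)
      expect_equal(got$C, want$C, tolerance = 1e-9)
      expect_equal(got$D, want$D, tolerance = 1e-9)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
    }
  }
})

test_that("an implementation-independent reference gives the same lower tail", {
  # p(.|x) is negative binomial with size x+1, prob 1/(1+N2/N1)
  for (x in c(0, 4, 17)) for (y in c(0, 3, 40)) for (r in c(0.5, 2)) {
    expect_equal(ac_test(x, y, 1e6, r * 1e6)$C,
                 pnbinom(y, size = x + 1, prob = 1 / (1 + r)),
                 tolerance = 1e-10)
  }
})

test_that("regulation calls combine corrected p and fold-change", {
  res <- data.frame(mirna = c("a", "b", "c"),
                    log2fc = c(2, 3, -2.5),
                    p_value = c(0.01 / 30, 0.2, 0.001 / 30))
  out <- classify_de(res, m = 30)
  expect_equal(out$p_corrected, pmin(1, 30 * res$p_value))
  expect_equal(out$regulation, c("up", "ns", "down"))
  expect_error(classify_de(res, m = 0), "positive")
})
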