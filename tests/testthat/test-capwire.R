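# Continuous-occasion models: ECM/TIRM likelihood searches, model
# selection, bootstrap interval.

test_that("ECM integer MLE matches explicit enumeration", {
  # counts (2,1,1): maximize N(N-1)(N-2)/N^4 -> N = 5
  oracle <- function(counts, max_pop) {
    n <- length(counts); s <- sum(counts)
    ll <- vapply(n:max_pop, function(N)
      sum(log(N - seq_len(n) + 1)) - s * log(N), numeric(1))
    (n:max_pop)[which.max(ll)]
  }
  expect_equal(fit_capwire(c(2, 1, 1), "ecm")$Nhat, 5)
  expect_equal(oracle(c(2, 1, 1), 100), 5)
  # heavily recaptured: saturation at the observed count
  expect_equal(fit_capwire(c(5, 5, 5), "ecm")$Nhat, 3)
  set.seed(5)
  for (i in 1:5) {
    cnt <- simulate_capwire_counts(30, 60, seed = i)
    expect_equal(fit_capwire(cnt, "ecm", 120)$Nhat, oracle(cnt, 120))
  }
  # all singletons: boundary, abundance unidentifiable
  f <- fit_capwire(rep(1, 10), "ecm", max_pop = 50)
  expect_true(f$boundary)
  expect_equal(f$Nhat, 50)
})

test_that("ECM is an exact submodel of the TIRM search", {
  set.seed(6)
  for (i in 1:5) {
    cnt <- simulate_capwire_counts(40, 100, n_b = 20, alpha = 3, seed = i)
    e <- fit_capwire(cnt, "ecm", 150)
    t <- fit_capwire(cnt, "tirm", 150)
    expect_gte(t$logL, e$logL - 1e-9)   # LRT never negative
    expect_equal(t$n_a + t$n_b, t$Nhat)
    expect_gte(t$Nhat, t$n_obs)
  }
})

test_that("TIRM recovers a two-rate population; selection is calibrated", {
  nhat <- vapply(1:25, function(i)
    fit_capwire(simulate_capwire_counts(86, 228, 43, 3, seed = i),
                "tirm", 300)$Nhat, numeric(1))
  expect_lt(abs(median(nhat) - 86) / 86, 0.12)

  sel <- capwire_select_ci(simulate_capwire_counts(86, 228, 43, 3,
                                                   seed = 77),
                           n_boot = 100, seed = 1, max_pop = 300)
  expect_equal(sel$selected, "TIRM")
  expect_gte(sel$ci[1], sel$fit$n_obs)
  expect_lte(sel$ci[1], sel$Nhat)
  expect_gte(sel$ci[2], sel$Nhat)
})

test_that("bootstrap CI lower bound never falls below the observed count", {
  cnt <- simulate_capwire_counts(30, 90, seed = 9)
  sel <- capwire_select_ci(cnt, n_boot = 100, seed = 2, max_pop = 120)
  expect_gte(sel$ci[1], length(cnt))
  # degenerate all-singleton data: upper bound reported at max_pop
  sel1 <- capwire_select_ci(rep(1, 8), n_boot = 100, seed = 3,
                            max_pop = 60)
  expect_true(sel1$boundary)
  expect_equal(sel1$ci[2], 60)
})
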