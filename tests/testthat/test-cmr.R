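# Capture histories, Huggins closed-capture likelihood, model ranking.

test_that("capture histories collapse occasions and compute dbar", {
  snares <- data.frame(snare_id = c("A", "B", "C"),
                       x_km = c(0, 3, 10), y_km = c(0, 4, 0))
  det <- data.frame(individual = "b1", year = 1,
                    occasion = c(1, 1, 3),
                    snare_id = c("A", "A", "B"))
  ch <- build_capture_histories(det, snares, occasions = 4)
  expect_equal(unname(ch[["1"]]$det["b1", ]), c(1, 0, 1, 0))
  # nearest-other distances: A->B = 5, B->A = 5; duplicate same-occasion
  # samples at the same snare collapse, so detections are A and B
  expect_equal(unname(ch[["1"]]$dbar), 5)
  expect_error(build_capture_histories(
    data.frame(individual = "b1", year = 1, occasion = 1,
               snare_id = "Z"), snares, 4), "unknown snare")
})

test_that("Huggins constant-p MLE equals a grid-search oracle", {
  det <- rbind(matrix(rep(c(1, 0), 10), 10, 2, byrow = TRUE),
               matrix(rep(c(0, 1), 10), 10, 2, byrow = TRUE),
               matrix(rep(c(1, 1), 5), 5, 2, byrow = TRUE))
  ch <- structure(list(det = det, sex = rep(0.5, 25),
                       dbar = rep(0, 25), year = 1),
                  class = "capture_history")
  fit <- fit_huggins(ch, model = list(behavior = FALSE))
  ps <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  ll <- vapply(ps, function(p)
    20 * log(p * (1 - p)) + 10 * log(p) - 25 * log(1 - (1 - p)^2),
    numeric(1))
  p_star <- ps[which.max(ll)]
  expect_equal(fit$Nhat, 25 / (1 - (1 - p_star)^2), tolerance = 1e-3)
  expect_equal(unname(ngcmr:::plogis_(fit$beta[1])), p_star,
               tolerance = 1e-3)
})

test_that("fast conditional likelihood equals brute-force enumeration", {
  set.seed(11)
  for (i in 1:3) {
    ch <- simulate_huggins_histories(5, 4, 0.4, 0.6, seed = 40 + i)
    fit <- fit_huggins(ch, model = list(behavior = TRUE))
    bf <- huggins_loglik_bruteforce(ch, fit$p, fit$c)
    expect_equal(fit$logL, bf, tolerance = 1e-10)
  }
})

test_that("detection-certain histories drive Nhat to the observed count", {
  det <- matrix(1L, 8, 4)
  ch <- structure(list(det = det, sex = rep(0.5, 8), dbar = rep(0, 8),
                       year = 1), class = "capture_history")
  fit <- fit_huggins(ch, model = list(behavior = FALSE))
  expect_true(fit$boundary)
  expect_equal(fit$Nhat, 8, tolerance = 1e-3)
})

test_that("Horvitz-Thompson abundance always covers the observed count", {
  for (i in 1:5) {
    ch <- simulate_huggins_histories(60, 6, 0.25, 0.35, seed = 60 + i)
    fit <- fit_huggins(ch, model = list(behavior = TRUE))
    expect_gte(fit$Nhat, fit$n)
    expect_true(all(1 / fit$pstar >= 1))
  }
})

test_that("AICc arithmetic and LRT screening follow the definitions", {
  mk <- function(logL, K, pars) structure(
    list(logL = logL, K = K, param_names = pars, n_eff = 50,
         model = paste(pars, collapse = "+")), class = "model_fit")
  # closed-form AICc: lnL=-100, K=3, n=50 -> 206 + 2*3*4/46
  f1 <- mk(-100, 3, c("a", "b", "c"))
  tab1 <- rank_models(list(m1 = f1), effective_n = 50)
  expect_equal(tab1$AICc, 206 + 24 / 46, tolerance = 1e-10)

  # identical logL: richer model removed by LRT (stat 0)
  f2 <- mk(-100, 4, c("a", "b", "c", "d"))
  tab2 <- rank_models(list(small = f1, big = f2), effective_n = 50)
  expect_true(tab2$removed_by_lrt[tab2$model == "big"])
  expect_false(tab2$removed_by_lrt[tab2$model == "small"])
  # weights over survivors sum to 1
  expect_equal(sum(tab2$weight), 1)

  # strongly better rich model survives
  f3 <- mk(-80, 4, c("a", "b", "c", "d"))
  tab3 <- rank_models(list(small = f1, big = f3), effective_n = 50)
  expect_false(any(tab3$removed_by_lrt))
  expect_equal(sum(tab3$weight), 1)
  expect_equal(tab3$model[1], "big")

  expect_error(rank_models(list(m1 = f1), effective_n = 4), "AICc")
})
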