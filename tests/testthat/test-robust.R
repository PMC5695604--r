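# Robust design: collapse to the closed model, parameter recovery,
# trajectory behavior.

test_that("with no earlier captures the likelihood equals the closed fit", {
  # all first captures in the last primary: the open part contributes
  # nothing, so the maximized likelihood equals fit_huggins on that
  # primary alone
  ch2 <- simulate_huggins_histories(40, 5, 0.3, 0.4, seed = 3)
  empty <- structure(list(det = matrix(0L, 0, 5), sex = numeric(0),
                          dbar = numeric(0), year = 1),
                     class = "capture_history")
  ch2$year <- 2
  rd <- fit_robust_design(list(empty, ch2),
                          model = list(behavior = TRUE))
  hg <- fit_huggins(ch2, model = list(behavior = TRUE))
  expect_equal(rd$logL, hg$logL, tolerance = 1e-6)
  expect_equal(rd$Nhat$Nhat[2], hg$Nhat, tolerance = 1e-4)
})

test_that("single primary period is redirected to the closed model", {
  ch <- simulate_huggins_histories(20, 4, 0.3, seed = 5)
  expect_error(fit_robust_design(list(ch)), "fit_huggins")
})

test_that("survival and emigration are recovered in simulation", {
  res <- vapply(1:8, function(i) {
    ch <- simulate_robust_histories(150, 4, 8, S = 0.85, gamma2 = 0.1,
                                    gamma1 = 0.1, p = 0.25, seed = 400 + i)
    f <- fit_robust_design(ch, model = list(behavior = TRUE))
    c(unname(f$S[1]), f$gamma2)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.85), 0.1)
  expect_true(all(res[2, ] >= 0 & res[2, ] <= 1))
})

test_that("an increasing trajectory yields an increasing abundance trend", {
  slopes <- vapply(1:8, function(i) {
    ch <- simulate_robust_histories(12, 4, 8, S = 0.85, gamma2 = 0.05,
                                    gamma1 = 0.1, p = 0.35,
                                    recruits = c(0L, 3L, 8L, 9L),
                                    seed = 700 + i)
    f <- fit_robust_design(ch, model = list(p_year = TRUE))
    unname(coef(lm(f$Nhat$Nhat ~ f$Nhat$year))[2])
  }, numeric(1))
  expect_gte(mean(slopes > 0), 7 / 8)
})
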