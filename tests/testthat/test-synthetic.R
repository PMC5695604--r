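# Synthetic-data generator: frequency construction, population
# trajectories, survey detection model, genotyping error process.

test_that("error model validates rates", {
  expect_s3_class(error_model(0.1, 0.01, 0.05), "error_model")
  expect_error(error_model(dropout = 1.2), "0, 1")
  expect_error(error_model(dropout = 0.7, false_allele = 0.5), "<= 1")
})

test_that("allele frequency generator honors degenerate targets", {
  af0 <- simulate_allele_frequencies(5, 3, target_fst = 0, n_pops = 3,
                                     seed = 1)
  for (l in names(af0$pop1))
    expect_identical(af0$pop1[[l]], af0$pop3[[l]])
  af1 <- simulate_allele_frequencies(4, 1, target_fst = 0.3, n_pops = 2,
                                     seed = 2)
  expect_true(all(unlist(af1$pop1) == 1))
  expect_error(simulate_allele_frequencies(4, 2, target_fst = 1),
               "degenerate")
  expect_error(simulate_allele_frequencies(4, 0, target_fst = 0.1),
               ">= 1")
  af <- simulate_allele_frequencies(6, 4, 0.15, 2, seed = 3)
  sums <- unlist(lapply(af, function(p) vapply(p, sum, numeric(1))))
  expect_equal(unname(sums), rep(1, 12), tolerance = 1e-12)
})

test_that("realized differentiation tracks the generator target", {
  fst <- vapply(1:40, function(i) {
    af <- simulate_allele_frequencies(14, 4, 0.2, 2, seed = i)
    g <- rbind(hwe_geno(af[[1]], 50), hwe_geno(af[[2]], 50))
    st <- ngcmr:::gst_pair_stat(
      ngcmr:::count_matrices(g, names(af[[1]])), rep(1:2, each = 50))
    st[["fst"]]
  }, numeric(1))
  expect_lt(abs(mean(fst) - 0.2), 0.05)
})

test_that("population realizes trajectory, sibships, and HWE diversity", {
  af <- simulate_allele_frequencies(14, 3, 0, 1, seed = 4,
    ancestral = rep(list(setNames(c(0.8, 0.15, 0.05),
                                  c("100", "102", "104"))), 14))
  pop <- simulate_population(af[[1]], c(12, 13, 19, 25), seed = 5)
  expect_equal(colSums(pop$alive), c(12, 13, 19, 25))
  expect_true(all(is.na(pop$individuals$family)))

  popsib <- simulate_population(af[[1]], 20,
                                sibship = list(n_families = 3, size = 4),
                                seed = 6)
  expect_equal(sum(!is.na(popsib$individuals$family[1:20])), 12)
  expect_error(simulate_population(af[[1]], 5,
                                   sibship = list(n_families = 3, size = 4)),
               "exceeds")

  # MRB-like low-diversity preset: mean He near 0.33 on the full population
  pop86 <- simulate_population(af[[1]], 86, seed = 7)
  he <- diversity_stats(pop86$genotypes[, 1:28])$summary$He
  expect_lt(abs(he - 0.33), 0.05)
})

test_that("survey detection follows the half-normal model limits", {
  af <- simulate_allele_frequencies(4, 3, 0, 1, seed = 8)
  pop <- simulate_population(af[[1]], 10, seed = 9)
  des <- survey_design(3, 3, occasions = 5, years = 1, seed = 10)
  none <- simulate_survey(pop, des, p0 = 0, sigma = 4, seed = 11)
  expect_equal(nrow(none$samples), 0)
  expect_equal(nrow(none$truth$captures), 0)

  # one individual sitting on the only snare, p0 = 1: one sample per occasion
  pop1 <- simulate_population(af[[1]], 1, seed = 12)
  des1 <- survey_design(1, 1, occasions = 5, years = 1, jitter = 0,
                        seed = 13)
  pop1$individuals$x <- des1$snares$x_km
  pop1$individuals$y <- des1$snares$y_km
  sv <- simulate_survey(pop1, des1, p0 = 1, sigma = 2, seed = 14)
  expect_equal(nrow(sv$samples), 5)
  expect_equal(sort(unique(sv$samples$occasion)), 1:5)

  # every emitted sample appears exactly once in the truth table
  sv2 <- simulate_survey(pop, des, p0 = 0.5, sigma = 4, seed = 15)
  expect_identical(sort(sv2$samples$sample_id),
                   sort(unique(sv2$truth$sample_map$sample_id)))
  expect_equal(nrow(sv2$truth$sample_map), nrow(sv2$samples))
})

test_that("genotyping errors behave as specified in the limits", {
  g <- c(L01.1 = 100L, L01.2 = 104L, L02.1 = 102L, L02.2 = 102L)
  clean <- apply_genotyping_errors(g, error_model(), 6, seed = 1)
  expect_true(all(t(clean) == g))

  forced <- apply_genotyping_errors(g, error_model(dropout = 1), 50,
                                    seed = 2)
  expect_true(all(forced[, "L01.1"] == forced[, "L01.2"]))
  expect_true(all(forced[, "L01.1"] %in% c(100L, 104L)))
  expect_true(any(forced[, "L01.1"] == 100L) &&
              any(forced[, "L01.1"] == 104L))

  # dropout frequency: observed homozygous-replicate rate ~ e_D
  reps <- apply_genotyping_errors(g[1:2], error_model(dropout = 0.2),
                                  10000, seed = 3)
  rate <- mean(reps[, 1] == reps[, 2])
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))

  # failure blanks the locus
  fail <- apply_genotyping_errors(g, error_model(failure = 1), 5, seed = 4)
  expect_true(all(is.na(fail)))
})

test_that("generator is reproducible from its seed", {
  af1 <- simulate_allele_frequencies(6, 4, 0.1, 2, seed = 99)
  af2 <- simulate_allele_frequencies(6, 4, 0.1, 2, seed = 99)
  expect_identical(af1, af2)
  pop1 <- simulate_population(af1[[1]], c(10, 12), seed = 100)
  pop2 <- simulate_population(af2[[1]], c(10, 12), seed = 100)
  expect_identical(pop1, pop2)
})
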