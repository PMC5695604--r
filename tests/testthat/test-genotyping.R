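# Genotyping chain: PIDsib panel, consensus calling, matching,
# reliability, cross-lab calibration.

# independent PIDsib oracle: enumerate the joint sib-pair genotype
# distribution from all parental matings and sum squared sharing
pidsib_enumerate <- function(p) {
  alleles <- seq_along(p)
  tot <- 0
  for (m1 in alleles) for (m2 in alleles)
    for (f1 in alleles) for (f2 in alleles) {
      w <- p[m1] * p[m2] * p[f1] * p[f2]
      if (w == 0) next
      # the four equally likely offspring genotypes of this mating
      kids <- rbind(sort(c(m1, f1)), sort(c(m1, f2)),
                    sort(c(m2, f1)), sort(c(m2, f2)))
      key <- paste(kids[, 1], kids[, 2])
      pr <- table(key) / 4
      tot <- tot + w * sum(pr^2)    # P(two sibs share a genotype)
    }
  tot
}

test_that("PIDsib closed form equals the sib-pair enumeration oracle", {
  expect_equal(pidsib_locus(c(0.5, 0.5)), 0.59375)
  expect_equal(pidsib_locus(1), 1)
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- as.numeric(ngcmr:::rdirichlet1(rep(1, k)))
    expect_equal(pidsib_locus(p), pidsib_enumerate(p), tolerance = 1e-12)
  }
  expect_error(pidsib_locus(c(-0.1, 1.1)), "negative")
})

test_that("panel builder reaches the threshold conservatively", {
  f7 <- setNames(rep(list(eqfreq(2)), 7), sprintf("L%02d", 1:7))
  pan <- pidsib_panel(f7, threshold = 0.03)
  expect_length(pan$panel, 7)            # 0.59375^7 ~ 0.026, ^6 ~ 0.044
  expect_lte(pan$product, 0.03)
  expect_gt(prod(rep(0.59375, 6)), 0.03)
  # cumulative product non-increasing along the build
  expect_true(all(diff(pan$table$cumprod) <= 0))
  # unreachable threshold flags
  f2 <- f7[1:2]
  expect_warning(pan2 <- pidsib_panel(f2, threshold = 0.03),
                 "not reached")
  expect_false(pan2$reached)
  expect_length(pan2$panel, 2)
})

test_that("consensus rules: replicate concordance by sample type", {
  het2 <- geno1(list(c(120, 124), c(120, 124)))
  r <- call_consensus(het2, "hair")
  expect_equal(unname(r$genotype), c(120L, 124L))
  expect_equal(unname(r$status), "confirmed")

  hom2 <- geno1(list(c(120, 120), c(120, 120)))
  expect_equal(unname(call_consensus(hom2, "hair")$status), "confirmed")
  expect_equal(unname(call_consensus(hom2, "scat")$status), "unconfirmed")
  hom3 <- geno1(list(c(120, 120), c(120, 120), c(120, 120)))
  expect_equal(unname(call_consensus(hom3, "scat")$status), "confirmed")

  # conflict resolved by a third replicate confirming the heterozygote
  conf <- geno1(list(c(120, 120), c(120, 124)))
  expect_equal(unname(call_consensus(conf, "hair")$status), "conflict")
  conf3 <- geno1(list(c(120, 120), c(120, 124), c(120, 124)))
  r3 <- call_consensus(conf3, "hair")
  expect_equal(unname(r3$status), "confirmed")
  expect_equal(unname(r3$genotype), c(120L, 124L))

  expect_error(call_consensus(het2, "blood"))
  # consensus never invents an allele absent from all replicates
  set.seed(7)
  for (i in 1:25) {
    reps <- geno1(lapply(1:4, function(j) sample(c(100, 102, 104), 2, TRUE)))
    out <- call_consensus(reps, "hair")
    called <- out$genotype[!is.na(out$genotype)]
    expect_true(all(called %in% as.vector(reps)))
  }
})

test_that("matching applies the dropout-aware 7-of-8 rule", {
  af <- simulate_allele_frequencies(8, 4, 0, 1, seed = 21)
  fr <- af[[1]]
  base <- hwe_geno(fr, 1)[1, ]
  # force a heterozygote at L08 for the dropout case
  a <- sort(as.integer(names(fr$L08)[1:2]))
  base[c("L08.1", "L08.2")] <- a
  s1 <- base
  s2 <- base; s2[c("L08.1", "L08.2")] <- c(a[1], a[1])   # dropout-like hom
  geno <- rbind(s1 = s1, s2 = s2, s4 = s1)
  status <- matrix("confirmed", 3, 8,
                   dimnames = list(rownames(geno), names(fr)))
  cs <- structure(list(genotypes = geno, status = status,
                       info = data.frame(sample_id = rownames(geno))),
                  class = "consensus_set")
  res <- match_samples(cs, names(fr), freqs = fr,
                       em = error_model(0.05, 0.01, 0))
  # identical s1/s4 and dropout-explainable s2 merge into one individual
  expect_equal(nrow(res$individuals), 1)
  expect_setequal(res$members[[1]], c("s1", "s2", "s4"))
  # the merged consensus takes the heterozygote at the dropout locus
  expect_equal(unname(res$genotypes[1, c("L08.1", "L08.2")]), a)

  # two different heterozygotes can never be a dropout pair
  s6 <- base
  s6[c("L08.1", "L08.2")] <- sort(as.integer(names(fr$L08))[c(1, 3)])
  geno2 <- rbind(s1 = s1, s6 = s6)
  status2 <- status[1:2, ]; rownames(status2) <- rownames(geno2)
  cs2 <- structure(list(genotypes = geno2, status = status2,
                        info = data.frame(sample_id = rownames(geno2))),
                   class = "consensus_set")
  res2 <- match_samples(cs2, names(fr), freqs = fr,
                        em = error_model(0.05, 0.01, 0),
                        reliability_min = 0)
  expect_equal(nrow(res2$individuals), 2)
})

test_that("matching is order-independent under canonical ordering", {
  tally1 <- run_identification(n_ind = 20, seed = 31)
  tally2 <- run_identification(n_ind = 20, seed = 31)
  expect_identical(tally1, tally2)
})

test_that("reliability score matches explicit Bayes enumeration", {
  fr <- list(L01 = setNames(c(0.5, 0.5), c("100", "102")))
  g <- c(L01.1 = 100L, L01.2 = 100L)
  em <- error_model(dropout = 0.2)
  # oracle: hypotheses true = 100/100 (prior 0.25), true het 100/102
  # (prior 0.5, observed hom via dropout of the right allele: e_D/2 each
  # way -> P(obs 100/100 | het) = 0.2 * 0.5)
  num <- 0.25
  den <- 0.25 + 0.5 * 0.2 * 0.5
  expect_equal(reliability_score(g, fr, em), num / den)
  # zero error rates give certainty
  expect_equal(reliability_score(g, fr, error_model()), 1)
  # heterozygote contributes 1 - e_F
  gh <- c(L01.1 = 100L, L01.2 = 102L)
  expect_equal(reliability_score(gh, fr, error_model(false_allele = 0.03)),
               0.97)
  # a single scored locus carries the whole score
  fr2 <- c(fr, list(L02 = setNames(1, "140")))
  g2 <- c(L01.1 = 100L, L01.2 = 100L, L02.1 = NA_integer_,
          L02.2 = NA_integer_)
  expect_equal(reliability_score(g2, fr2, em), num / den)
})

test_that("allele-size calibration finds constant offsets or fails loudly", {
  ref_a <- geno1(list(c(180, 184), c(180, 180), c(184, 188)), "G10L")
  ref_b <- ref_a + 4L
  colnames(ref_b) <- colnames(ref_a)
  cal <- calibrate_allele_sizes(ref_a, ref_b)
  expect_equal(unname(cal$offsets), -4L)
  expect_identical(cal$transformed, ref_a)

  bad <- ref_b; bad[3, ] <- bad[3, ] + 2L
  expect_error(calibrate_allele_sizes(ref_a, bad), "G10L")

  cal0 <- calibrate_allele_sizes(ref_a, ref_a)
  expect_equal(unname(cal0$offsets), 0L)
  expect_identical(cal0$transformed, ref_a)
})
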