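# Population-genetic statistics: diversity, differentiation, HWE/LE,
# LD-Ne, Evanno, Kruskal-Wallis/Nemenyi, relatedness.

test_that("allele frequencies count alleles and sample sizes", {
  g <- geno1(c(rep(list(c(100, 100)), 10)))
  af <- allele_frequencies(list(a = g))
  expect_equal(unname(af$a$L01), 1)
  expect_equal(attr(af, "n")$a[["L01"]], 10)
  g2 <- geno1(list(c(100, 100), c(100, 102), c(102, 102)))
  af2 <- allele_frequencies(g2)
  expect_equal(unname(af2$pop1$L01), c(0.5, 0.5))
  g3 <- geno1(list(c(100, 100), c(NA, NA)))
  expect_equal(attr(allele_frequencies(g3), "n")$pop1[["L01"]], 1)
})

test_that("diversity closed forms: unbiased He and rarefied richness", {
  # n = 10, two alleles at 0.5 -> He = (20/19) * 0.5
  g <- geno1(c(rep(list(c(100, 100)), 5), rep(list(c(102, 102)), 5)))
  d <- diversity_stats(list(a = g), g = 2)
  expect_equal(d$per_locus$He, (20 / 19) * 0.5, tolerance = 1e-12)
  expect_equal(d$per_locus$Ho, 0)
  # R_2 for copy counts (10, 10)
  expect_equal(allelic_richness(c(10, 10), 2), 2 * (1 - 45 / 190),
               tolerance = 1e-12)
  expect_equal(d$per_locus$richness, 2 * (1 - 45 / 190), tolerance = 1e-12)
  # monomorphic locus
  gm <- geno1(rep(list(c(100, 100)), 8))
  dm <- diversity_stats(list(a = gm), g = 4)
  expect_equal(dm$per_locus$He, 0)
  expect_equal(dm$per_locus$richness, 1)
  # richness at g = 2N equals the observed allele count
  cnt <- c(7, 2, 1)
  expect_equal(allelic_richness(cnt, sum(cnt)), 3, tolerance = 1e-12)
  expect_error(allelic_richness(c(5, 5), 1), ">= 2")
})

test_that("module statistics equal brute-force recomputation", {
  # independent recomputation from the raw genotype table
  set.seed(13)
  af <- simulate_allele_frequencies(3, 4, 0, 1, seed = 13)
  g <- hwe_geno(af[[1]], 20)
  g[3, 1:2] <- NA                      # some missing data
  d <- diversity_stats(list(a = g), g = 6)$per_locus
  for (k in seq_len(3)) {
    l <- sprintf("L%02d", k)
    a <- g[, paste0(l, ".1")]; b <- g[, paste0(l, ".2")]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    ho <- sum(a[ok] != b[ok]) / n
    tab <- table(c(a[ok], b[ok]))
    p <- tab / sum(tab)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    rg <- sum(1 - choose(2 * n - tab, 6) / choose(2 * n, 6))
    expect_equal(d$Ho[d$locus == l], ho, tolerance = 1e-10)
    expect_equal(d$He[d$locus == l], he, tolerance = 1e-10)
    expect_equal(d$richness[d$locus == l], rg, tolerance = 1e-10)
  }
})

test_that("differentiation matches the hand-evaluated example", {
  # frequency-level: p = 0.8 vs 0.2 -> Hs = 0.32, Ht = 0.5,
  # Fst = 0.36, G''st = 0.36 / (0.68 * 0.68)
  mk <- function(p, n) {
    k <- round(p * 2 * n)
    pool <- c(rep(100L, k), rep(102L, 2 * n - k))
    geno1(split(pool, rep(seq_len(n), 2)))
  }
  # build exact-frequency samples so the sample freqs are exactly 0.8/0.2
  g1 <- mk(0.8, 500); g2 <- mk(0.2, 500)
  pd <- pairwise_differentiation(list(a = g1, b = g2), n_perm = 99,
                                 seed = 1)
  expect_equal(pd$fst[1, 2], 0.36, tolerance = 1e-10)
  expect_equal(pd$gst[1, 2], 0.36 / (0.68 * 0.68), tolerance = 1e-10)
  expect_lte(pd$p_fst[1, 2], 0.05)
  # symmetric with zero diagonal
  expect_equal(pd$fst, t(pd$fst))
  expect_equal(unname(diag(pd$fst)), c(0, 0))

  # fixed differences: Fst = G''st = 1
  gA <- geno1(rep(list(c(100, 100)), 30))
  gB <- geno1(rep(list(c(104, 104)), 30))
  pf <- pairwise_differentiation(list(a = gA, b = gB), n_perm = 99,
                                 seed = 2)
  expect_equal(pf$fst[1, 2], 1)
  expect_equal(pf$gst[1, 2], 1)

  # identical frequencies: near zero, not significant
  set.seed(3)
  af <- simulate_allele_frequencies(6, 4, 0, 1, seed = 3)
  h1 <- hwe_geno(af[[1]], 60); h2 <- hwe_geno(af[[1]], 60)
  p0 <- pairwise_differentiation(list(a = h1, b = h2), n_perm = 199,
                                 seed = 4)
  expect_lt(abs(p0$fst[1, 2]), 0.05)
  expect_gt(p0$p_fst[1, 2], 0.05)
  # standardized G''st dominates Fst when Hs > 0
  af2 <- simulate_allele_frequencies(6, 4, 0.2, 2, seed = 5)
  s1 <- hwe_geno(af2[[1]], 50); s2 <- hwe_geno(af2[[2]], 50)
  ps <- pairwise_differentiation(list(a = s1, b = s2), n_perm = 99,
                                 seed = 6)
  expect_gte(ps$gst[1, 2], ps$fst[1, 2])
})

test_that("statistics are invariant under allele relabeling", {
  set.seed(17)
  af <- simulate_allele_frequencies(4, 3, 0.15, 2, seed = 17)
  g1 <- hwe_geno(af[[1]], 30); g2 <- hwe_geno(af[[2]], 30)
  relabel <- function(g, ref) {   # shared allele map across populations
    out <- g
    for (l in unique(sub("\\.[12]$", "", colnames(g)))) {
      cols <- paste0(l, ".", 1:2)
      m <- sort(unique(as.vector(ref[, cols])))
      map <- setNames(rev(900 + 2 * seq_along(m)), m)
      w <- matrix(map[as.character(g[, cols])], nrow(g))
      out[, cols] <- cbind(pmin(w[, 1], w[, 2]), pmax(w[, 1], w[, 2]))
    }
    out
  }
  both <- rbind(g1, g2)
  r1 <- relabel(g1, both); r2 <- relabel(g2, both)
  d0 <- diversity_stats(list(a = g1), g = 10)$summary
  d1 <- diversity_stats(list(a = r1), g = 10)$summary
  expect_equal(d0$He, d1$He, tolerance = 1e-12)
  expect_equal(d0$Ho, d1$Ho, tolerance = 1e-12)
  expect_equal(d0$richness, d1$richness, tolerance = 1e-12)
  p0 <- pairwise_differentiation(list(a = g1, b = g2), n_perm = 99,
                                 seed = 8)
  p1 <- pairwise_differentiation(list(a = r1, b = r2), n_perm = 99,
                                 seed = 8)
  expect_equal(p0$fst[1, 2], p1$fst[1, 2], tolerance = 1e-12)
  expect_equal(p0$gst[1, 2], p1$gst[1, 2], tolerance = 1e-12)
})

test_that("HWE test flags heterozygote excess and honors conventions", {
  # 50 forced heterozygotes at p = q = 0.5
  gh <- geno1(rep(list(c(100, 102)), 50))
  expect_lte(hwe_test(gh, "L01", seed = 1), 0.001)
  # monomorphic -> P = 1
  gm <- geno1(rep(list(c(100, 100)), 20))
  expect_equal(hwe_test(gm, "L01"), 1)
  # HWE-proportioned data: not significant
  ge <- geno1(c(rep(list(c(100, 100)), 25), rep(list(c(100, 102)), 50),
                rep(list(c(102, 102)), 25)))
  expect_gt(hwe_test(ge, "L01", seed = 2), 0.2)
  expect_error(hwe_test(geno1(list(c(100, 102))), "L01"), ">= 5")
})

test_that("LD test: self-copy maximal, independent loci null, monomorphic 1", {
  set.seed(19)
  af <- simulate_allele_frequencies(2, 4, 0, 1, seed = 19)
  g <- hwe_geno(af[[1]], 60)
  dup <- cbind(g[, 1:2], g[, 1:2])
  colnames(dup) <- c("L01.1", "L01.2", "L02.1", "L02.2")
  expect_equal(ld_test(dup, c("L01", "L02"), n_perm = 199, seed = 1),
               1 / 200)
  expect_gt(ld_test(g, c("L01", "L02"), n_perm = 199, seed = 4), 0.01)
  mono <- cbind(g[, 1:2], geno1(rep(list(c(100, 100)), 60), "L02"))
  expect_equal(ld_test(mono, c("L01", "L02"), n_perm = 99, seed = 3), 1)
})

test_that("LD-Ne plug-in closed form and degenerate cases", {
  est <- ne_from_r2(0.05, 50)
  expect_equal(est$Er2, 1 / 50 + 3.19 / 2500, tolerance = 1e-12)
  expect_equal(est$r2_drift, 0.05 - est$Er2, tolerance = 1e-12)
  expect_equal(est$Ne, 8.91, tolerance = 0.01)
  # drift signal at or below sampling expectation -> infinite Ne
  expect_equal(ne_from_r2(0.019, 50)$Ne, Inf)
  # unlinked HWE draws should usually show no drift signal
  af <- simulate_allele_frequencies(8, 4, 0, 1, seed = 23)
  g <- hwe_geno(af[[1]], 80)
  ne <- ne_ld(g)
  expect_true(ne$Ne > 80 || is.infinite(ne$Ne))
  expect_error(ne_ld(g[, 1:2]), "polymorphic")
})

test_that("Evanno delta-K arithmetic and contracts", {
  means <- c(-1000, -800, -750, -745)
  runs <- data.frame(K = rep(1:4, each = 3),
                     logL = rep(means, each = 3) + c(-10, 0, 10))
  ev <- evanno_delta_k(runs)   # sd exactly 10 at each K
  expect_equal(ev$deltaK[2], 15)
  expect_equal(ev$deltaK[3], 4.5)
  expect_true(is.na(ev$deltaK[1]) && is.na(ev$deltaK[4]))
  # linear L(K): all interior deltaK are zero
  lin <- data.frame(K = rep(1:5, each = 2),
                    logL = rep(seq(-900, -500, by = 100), each = 2) +
                      c(-1, 1))
  expect_equal(evanno_delta_k(lin)$deltaK[2:4], rep(0, 3))
  # zero replicate spread at an interior K is flagged undefined
  degen <- data.frame(K = rep(1:3, each = 2),
                      logL = c(-10, -12, -5, -5, -4, -6))
  expect_true(is.na(evanno_delta_k(degen)$deltaK[2]))
  expect_error(evanno_delta_k(runs[runs$K < 3, ]), ">= 3")
})

test_that("diversity comparison: Kruskal-Wallis H oracle and Nemenyi", {
  vals <- list(a = c(1, 2, 3), b = c(11, 12, 13), c = c(21, 22, 23))
  cd <- compare_diversity(vals)
  # H recomputed from first principles on this instance (no ties):
  # ranks 1..9, group mean ranks 2, 5, 8
  H <- 12 / (9 * 10) * 3 * ((2 - 5)^2 + 0 + (8 - 5)^2)
  expect_equal(cd$H, H, tolerance = 1e-12)
  expect_lt(cd$p, 0.05)
  expect_equal(cd$nemenyi, t(cd$nemenyi))
  expect_equal(unname(diag(cd$nemenyi)), rep(1, 3))
  # extreme groups differ, adjacent may not
  expect_lt(cd$nemenyi["a", "c"], 0.05)
  # identical values in every group
  same <- compare_diversity(list(a = c(1, 1), b = c(1, 1)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("ML relatedness ranks known relationships correctly", {
  af <- simulate_allele_frequencies(14, 6, 0, 1, seed = 29,
                                    ancestral_alpha = 3)
  fr <- af[[1]]
  # identical genotypes: highest-r classes win
  g <- hwe_geno(fr, 1)
  twin <- rbind(g, g)
  rownames(twin) <- c("a", "b")
  r <- pairwise_relatedness(twin, fr)
  expect_true(r$pairs$class %in% c("FS", "PO"))
  expect_gte(r$pairs$r, 0.5)
  # unrelated pairs: low mean relatedness
  un <- hwe_geno(fr, 30)
  rownames(un) <- sprintf("u%02d", 1:30)
  ru <- pairwise_relatedness(un, fr)
  expect_lte(mean(ru$pairs$r, na.rm = TRUE), 0.05)
  # parent-offspring: sharing at every locus, PO likelihood positive
  mom <- hwe_geno(fr, 1); dad <- hwe_geno(fr, 1)
  kid <- ngcmr:::mendel_offspring(mom[1, ], dad[1, ], 1)
  po <- rbind(mom, kid); rownames(po) <- c("mom", "kid")
  rp <- pairwise_relatedness(po, fr)
  expect_true(is.finite(rp$pairs$logL))
  expect_true(rp$pairs$class != "U")
  # least-related subset has the requested size
  sub <- pairwise_relatedness(un, fr, subset_size = 10)
  expect_length(sub$subset, 10)
  # insufficient shared loci -> missing relatedness
  sparse <- twin
  sparse[2, 1:20] <- NA
  rs <- pairwise_relatedness(sparse, fr, min_shared = 5)
  expect_true(is.na(rs$pairs$r))
})
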