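## Hardy-Weinberg and linkage-equilibrium permutation tests, and the
## linkage-disequilibrium effective population size (Burrows composite
## disequilibrium with finite-sample correction and missing-data
## weighting).

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Test statistic is the observed heterozygote count; its null
#' distribution is generated by randomly re-pairing the locus's allele
#' pool.  The two-sided P-value doubles the smaller tail (add-one rule,
#' capped at 1).  Monomorphic loci return `P = 1` by convention.
#'
#' @param geno Genotype matrix (individuals x two columns per locus).
#' @param locus Locus name.
#' @param n_shuffle Number of allele-pool shuffles (default 2000).
#' @param seed Optional integer seed.
#' @return P-value in `(0, 1]`.
#' @export
hwe_test <- function(geno, locus, n_shuffle = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- geno[, paste0(locus, ".1")]; b <- geno[, paste0(locus, ".2")]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 5) stop("need >= 5 genotyped individuals")
  pool <- c(a, b)
  if (length(unique(pool)) == 1) return(1)
  t_obs <- sum(a != b)
  t_null <- integer(n_shuffle)
  for (i in seq_len(n_shuffle)) {
    s <- sample(pool)
    t_null[i] <- sum(s[seq_len(n)] != s[n + seq_len(n)])
  }
  p_lo <- (1 + sum(t_null <= t_obs)) / (1 + n_shuffle)
  p_hi <- (1 + sum(t_null >= t_obs)) / (1 + n_shuffle)
  min(1, 2 * min(p_lo, p_hi))
}

## Burrows composite disequilibrium Delta_AB for allele A at locus with
## count vector x (0/1/2 per individual) and allele B with counts y.
## With small-sample correction factor n/(n-1).
burrows_delta <- function(x, y) {
  n <- length(x)
  d <- mean(x * y) / 2 - 2 * mean(x / 2) * mean(y / 2)
  n / (n - 1) * d
}

## Individual allele-count vectors for every allele at a locus.
allele_count_cols <- function(geno, locus) {
  a <- geno[, paste0(locus, ".1")]; b <- geno[, paste0(locus, ".2")]
  alleles <- sort(unique(c(a[!is.na(a)], b[!is.na(b)])))
  m <- sapply(alleles, function(al)
    (!is.na(a) & a == al) + (!is.na(b) & b == al))
  m <- matrix(m, nrow = nrow(geno))
  colnames(m) <- as.character(alleles)
  m[is.na(a) | is.na(b), ] <- NA_integer_
  m
}

#' Permutation test of linkage equilibrium between two loci
#'
#' Statistic: the sum of squared Burrows composite disequilibrium
#' coefficients over all allele pairs, computed on individuals typed at
#' both loci.  The null distribution permutes one locus's genotypes
#' across individuals; P uses the add-one rule.
#'
#' @param geno Genotype matrix.
#' @param loci Character vector of the two locus names.
#' @param n_perm Permutations (default 999).
#' @param seed Optional integer seed.
#' @return P-value in `(0, 1]`.
#' @export
ld_test <- function(geno, loci, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(loci) == 2)
  mx <- allele_count_cols(geno, loci[1])
  my <- allele_count_cols(geno, loci[2])
  ok <- !is.na(mx[, 1]) & !is.na(my[, 1])
  if (sum(ok) < 5) stop("need >= 5 individuals typed at both loci")
  mx <- mx[ok, , drop = FALSE]; my <- my[ok, , drop = FALSE]
  stat <- function(mx, my) {
    s <- 0
    for (i in seq_len(ncol(mx))) for (j in seq_len(ncol(my)))
      s <- s + burrows_delta(mx[, i], my[, j])^2
    s
  }
  t_obs <- stat(mx, my)
  b <- 0L
  n <- nrow(mx)
  for (r in seq_len(n_perm)) {
    if (stat(mx, my[sample.int(n), , drop = FALSE]) >= t_obs) b <- b + 1L
  }
  (1 + b) / (1 + n_perm)
}

#' Effective population size from a mean squared LD correlation
#'
#' Plug-in transform of the LD method (random mating): subtracts the
#' finite-sample expectation `E[r^2_S] = 1/S + 3.19/S^2` (for
#' `S >= 30`; `0.0018 + 0.907/S + 4.44/S^2` below) and solves
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')`; a non-positive drift
#' component returns `Inf`.
#'
#' @param r2 Weighted mean squared LD correlation.
#' @param S (Harmonic mean) sample size in individuals.
#' @return List with `Ne`, `Er2`, `r2_drift`.
#' @examples
#' ne_from_r2(0.05, 50)$Ne   # about 8.91
#' @export
ne_from_r2 <- function(r2, S) {
  er2 <- if (S >= 30) 1 / S + 3.19 / S^2 else
    0.0018 + 0.907 / S + 4.44 / S^2
  rd <- r2 - er2
  ne <- if (rd <= 0) Inf else
    (1 / 3 + sqrt(max(0, 1 / 9 - 2.76 * rd))) / (2 * rd)
  list(Ne = ne, Er2 = er2, r2_drift = rd)
}

#' Effective population size from linkage disequilibrium
#'
#' Single-sample LD estimator of `Ne` for randomly mating populations:
#' squared correlations `r^2` of Burrows composite disequilibrium are
#' averaged over allele pairs within each locus pair, then combined
#' across locus pairs weighted by their pairwise sample size `S`
#' (individuals typed at both loci: the missing-data correction).  The
#' sampling expectation `E[r^2_S] = 1/S + 3.19/S^2` (for `S >= 30`,
#' else `0.0018 + 0.907/S + 4.44/S^2`) evaluated at the harmonic mean
#' `S` is subtracted, and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')`; a drift signal at or
#' below zero yields `Ne = Inf`.  Alleles rarer than `min_freq` are
#' screened out.  The confidence interval is a delete-one-locus
#' jackknife on the drift component.
#'
#' @param geno Genotype matrix of one population.
#' @param mating Mating system; only `"random"` is implemented.
#' @param min_freq Minimum allele frequency retained (default 0.02).
#' @param loci Loci to use (default all but the sex marker).
#' @param conf Confidence level (default 0.95).
#' @return An `ne_estimate`: list with `Ne`, `ci`, `r2` (weighted mean),
#'   `Er2` (sampling expectation), `r2_drift`, `S` (harmonic mean
#'   pairwise sample size), `n_locus_pairs`.
#' @export
ne_ld <- function(geno, mating = "random", min_freq = 0.02, loci = NULL,
                  conf = 0.95) {
  mating <- match.arg(mating, "random")
  if (is.null(loci)) loci <- setdiff(geno_loci(geno), "sex")
  mats <- lapply(loci, function(l) allele_count_cols(geno, l))
  names(mats) <- loci
  poly <- vapply(mats, function(m) ncol(m) > 1, logical(1))
  loci <- loci[poly]; mats <- mats[poly]
  if (length(loci) < 2) stop("need >= 2 polymorphic loci")

  pairs <- combn(seq_along(loci), 2)
  pr2 <- ps <- pl1 <- pl2 <- numeric(0)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    mx <- mats[[i]]; my <- mats[[j]]
    ok <- !is.na(mx[, 1]) & !is.na(my[, 1])
    S <- sum(ok)
    if (S < 5) next
    mx <- mx[ok, , drop = FALSE]; my <- my[ok, , drop = FALSE]
    fx <- colMeans(mx) / 2; fy <- colMeans(my) / 2
    ux <- which(fx >= min_freq & fx <= 1 - min_freq)
    uy <- which(fy >= min_freq & fy <= 1 - min_freq)
    if (!length(ux) || !length(uy)) next
    r2s <- numeric(0)
    for (ai in ux) for (bj in uy) {
      denom <- fx[ai] * (1 - fx[ai]) * fy[bj] * (1 - fy[bj])
      r2s <- c(r2s, burrows_delta(mx[, ai], my[, bj])^2 / denom)
    }
    pr2 <- c(pr2, mean(r2s)); ps <- c(ps, S)
    pl1 <- c(pl1, i); pl2 <- c(pl2, j)
  }
  if (!length(pr2)) stop("no usable locus pairs")

  est <- function(keep) {
    w <- ps[keep]
    r2 <- sum(w * pr2[keep]) / sum(w)
    S <- length(w) / sum(1 / w)          # harmonic mean
    tr <- ne_from_r2(r2, S)
    c(r2 = r2, S = S, er2 = tr$Er2, rd = tr$r2_drift, ne = tr$Ne)
  }
  full <- est(seq_along(pr2))

  ## jackknife over loci on the drift component
  rds <- vapply(seq_along(loci), function(l) {
    keep <- which(pl1 != l & pl2 != l)
    if (length(keep) < 1) return(NA_real_)
    est(keep)["rd"]
  }, numeric(1))
  rds <- rds[!is.na(rds)]
  m <- length(rds)
  ci <- c(NA_real_, NA_real_)
  if (m >= 2) {
    se <- sqrt((m - 1) / m * sum((rds - mean(rds))^2))
    z <- qnorm(1 - (1 - conf) / 2)
    rd_lo <- full["rd"] - z * se; rd_hi <- full["rd"] + z * se
    ne_of <- function(rd) if (rd <= 0) Inf else
      (1 / 3 + sqrt(max(0, 1 / 9 - 2.76 * rd))) / (2 * rd)
    ci <- c(ne_of(rd_hi), ne_of(rd_lo))   # high drift -> low Ne
  }
  structure(list(Ne = unname(full["ne"]), ci = unname(ci),
                 r2 = unname(full["r2"]), Er2 = unname(full["er2"]),
                 r2_drift = unname(full["rd"]), S = unname(full["S"]),
                 n_locus_pairs = length(pr2)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "LD Ne estimate: %.2f (%.0f%% CI %.2f-%.2f); r2=%.5f E[r2]=%.5f S=%.1f (%d locus pairs)\n",
    x$Ne, 95, x$ci[1], x$ci[2], x$r2, x$Er2, x$S, x$n_locus_pairs))
  invisible(x)
}
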