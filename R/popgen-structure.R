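## Differentiation (Gst / Hedrick's standardized G''st) with permutation
## tests, and the Evanno delta-K clustering-support statistic.

## Per-locus individual x allele copy-count matrices for fast
## permutation: rows sum to 2 (typed) or 0 (missing).
count_matrices <- function(geno, loci) {
  lapply(loci, function(l) {
    a <- geno[, paste0(l, ".1")]; b <- geno[, paste0(l, ".2")]
    alleles <- sort(unique(c(a, b)))
    alleles <- alleles[!is.na(alleles)]
    m <- matrix(0L, nrow(geno), length(alleles),
                dimnames = list(NULL, as.character(alleles)))
    for (j in seq_along(alleles))
      m[, j] <- (!is.na(a) & a == alleles[j]) + (!is.na(b) & b == alleles[j])
    m
  })
}

## Gst and G''st for a 2-group split given per-locus count matrices.
## Aggregates Hs and Ht across polymorphic loci before forming ratios.
gst_pair_stat <- function(mats, grp) {
  hs <- ht <- numeric(0)
  for (m in mats) {
    c1 <- colSums(m[grp == 1L, , drop = FALSE])
    c2 <- colSums(m[grp == 2L, , drop = FALSE])
    if (sum(c1) == 0 || sum(c2) == 0) next
    f1 <- c1 / sum(c1); f2 <- c2 / sum(c2)
    fbar <- (f1 + f2) / 2
    ht_l <- 1 - sum(fbar^2)
    if (ht_l <= 0) next                     # pooled monomorphic locus
    hs <- c(hs, 1 - (sum(f1^2) + sum(f2^2)) / 2)
    ht <- c(ht, ht_l)
  }
  if (!length(ht)) return(c(fst = NA_real_, gst = NA_real_))
  Hs <- mean(hs); Ht <- mean(ht)
  fst <- (Ht - Hs) / Ht
  gst <- if (Hs >= 1) NA_real_ else
    2 * (Ht - Hs) / ((2 * Ht - Hs) * (1 - Hs))
  c(fst = fst, gst = gst, Hs = Hs, Ht = Ht)
}

#' Pairwise genetic differentiation with permutation tests
#'
#' For every pair of populations computes Nei's Gst,
#' `Fst = (Ht - Hs)/Ht`, and Hedrick's standardized
#' `G''st = k (Ht - Hs) / ((k Ht - Hs)(1 - Hs))` with `k = 2`, where
#' `Hs` is the mean within-population gene diversity and `Ht` the gene
#' diversity of the pooled (unweighted mean) frequencies, both averaged
#' over polymorphic loci before forming the ratios.  Significance is
#' assessed by permuting individuals between the two populations with
#' the add-one rule `P = (1 + b) / (1 + n_perm)`.
#'
#' @param geno_by_pop Named list of genotype matrices.
#' @param n_perm Number of permutations (default 999; minimum 99).
#' @param seed Optional integer seed.
#' @param loci Loci to use (default all but the sex marker).
#' @return A `differentiation_result`: list of symmetric matrices
#'   `fst`, `gst`, `p_fst`, `p_gst`, `Hs`, `Ht`, plus `n_perm` and `k`.
#' @export
pairwise_differentiation <- function(geno_by_pop, n_perm = 999,
                                     seed = NULL, loci = NULL) {
  if (length(geno_by_pop) < 2) stop("need at least two populations")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loci))
    loci <- setdiff(geno_loci(geno_by_pop[[1]]), "sex")
  pops <- names(geno_by_pop)
  k <- length(pops)
  mk <- function() matrix(0, k, k, dimnames = list(pops, pops))
  fst <- gst <- hs <- ht <- mk()
  p_fst <- p_gst <- matrix(NA_real_, k, k, dimnames = list(pops, pops))

  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    g12 <- rbind(geno_by_pop[[i]][, c(rbind(paste0(loci, ".1"),
                                            paste0(loci, ".2")))],
                 geno_by_pop[[j]][, c(rbind(paste0(loci, ".1"),
                                            paste0(loci, ".2")))])
    n1 <- nrow(geno_by_pop[[i]])
    grp <- rep(c(1L, 2L), c(n1, nrow(geno_by_pop[[j]])))
    mats <- count_matrices(g12, loci)
    obs <- gst_pair_stat(mats, grp)
    fst[i, j] <- fst[j, i] <- obs["fst"]
    gst[i, j] <- gst[j, i] <- obs["gst"]
    hs[i, j] <- hs[j, i] <- obs["Hs"]
    ht[i, j] <- ht[j, i] <- obs["Ht"]
    if (!is.na(obs["fst"])) {
      bf <- bg <- 0L
      for (b in seq_len(n_perm)) {
        st <- gst_pair_stat(mats, sample(grp))
        if (!is.na(st["fst"]) && st["fst"] >= obs["fst"]) bf <- bf + 1L
        if (!is.na(st["gst"]) && st["gst"] >= obs["gst"]) bg <- bg + 1L
      }
      p_fst[i, j] <- p_fst[j, i] <- (1 + bf) / (1 + n_perm)
      p_gst[i, j] <- p_gst[j, i] <- (1 + bg) / (1 + n_perm)
    }
  }
  structure(list(fst = fst, gst = gst, p_fst = p_fst, p_gst = p_gst,
                 Hs = hs, Ht = ht, n_perm = n_perm, k = 2L),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat("pairwise Fst (Nei Gst):\n"); print(round(x$fst, 3))
  cat("pairwise G''st (Hedrick):\n"); print(round(x$gst, 3))
  invisible(x)
}

#' Evanno delta-K from clustering log-likelihoods
#'
#' Second-difference support statistic for choosing the number of
#' genetic clusters: `deltaK = mean|L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`
#' computed from replicate runs at each K.  Defined only at interior K
#' values; a zero replicate standard deviation leaves deltaK undefined
#' there (flagged `NA`).
#'
#' @param runs Data frame with columns `K` and `logL` (one row per
#'   replicate run), or a matrix with replicates in rows and K values as
#'   columns.
#' @return An `evanno_result` data frame: K, n_rep, mean_L, sd_L,
#'   deltaK.
#' @examples
#' runs <- expand.grid(rep = 1:3, K = 1:4)
#' runs$logL <- c(-1000, -800, -750, -745)[runs$K] + rnorm(12, 0, 1)
#' evanno_delta_k(runs)
#' @export
evanno_delta_k <- function(runs) {
  if (is.matrix(runs))
    runs <- data.frame(K = as.integer(colnames(runs))[col(runs)],
                       logL = as.vector(runs))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3) stop("need >= 3 consecutive K values")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  m <- vapply(ks, function(k) mean(runs$logL[runs$K == k]), numeric(1))
  s <- vapply(ks, function(k) sd(runs$logL[runs$K == k]), numeric(1))
  nr <- vapply(ks, function(k) sum(runs$K == k), numeric(1))
  if (any(nr < 2)) stop("need >= 2 replicates at each K")
  dk <- rep(NA_real_, length(ks))
  for (i in 2:(length(ks) - 1)) {
    if (is.na(s[i]) || s[i] == 0) next   # flagged undefined
    dk[i] <- abs(m[i + 1] - 2 * m[i] + m[i - 1]) / s[i]
  }
  structure(data.frame(K = ks, n_rep = nr, mean_L = m, sd_L = s,
                       deltaK = dk),
            class = c("evanno_result", "data.frame"))
}
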