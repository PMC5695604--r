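## Maximum-likelihood pairwise relatedness over the standard
## relationship classes, and selection of a least-related subset.

## IBD k-coefficients (k0, k1, k2) per relationship class.
relatedness_classes <- function() {
  rbind(U  = c(1,    0,   0),
        HS = c(0.5,  0.5, 0),
        FS = c(0.25, 0.5, 0.25),
        PO = c(0,    1,   0))
}

## Unordered genotype probability under HWE.
hwe_geno_prob <- function(a, b, p) {
  pa <- unname(p[as.character(a)]); pb <- unname(p[as.character(b)])
  if (is.na(pa) || is.na(pb)) return(NA_real_)
  if (a == b) pa * pb else 2 * pa * pb
}

## P(G2 | G1, exactly one allele IBD): IBD allele uniform over G1's
## alleles, the non-IBD allele drawn from population frequencies.
trans_one_ibd <- function(g1, g2, p) {
  pr <- 0
  for (ib in g1) {
    others <- if (g2[1] == ib) g2[2] else if (g2[2] == ib) g2[1] else NA
    if (!is.na(others)) {
      w <- unname(p[as.character(others)])
      ## heterozygote {ib, x} arises once; homozygote {ib, ib} needs x = ib
      pr <- pr + 0.5 * (if (is.na(w)) 0 else w)
    }
  }
  pr
}

## Per-locus genotype-pair likelihood under (k0, k1, k2).
pair_locus_lik <- function(g1, g2, p, kvec) {
  p1 <- hwe_geno_prob(g1[1], g1[2], p)
  p2 <- hwe_geno_prob(g2[1], g2[2], p)
  if (is.na(p1) || is.na(p2)) return(NA_real_)
  l0 <- p1 * p2
  l1 <- p1 * trans_one_ibd(g1, g2, p)
  l2 <- p1 * as.numeric(g1[1] == g2[1] && g1[2] == g2[2])
  kvec[1] * l0 + kvec[2] * l1 + kvec[3] * l2
}

#' Maximum-likelihood pairwise relatedness
#'
#' For every pair of individuals, evaluates the multilocus likelihood of
#' the four standard relationship classes -- unrelated (U), half-sib
#' (HS), full-sib (FS), parent-offspring (PO) -- using IBD-conditioned
#' genotype-pair probabilities from allele frequencies, and reports the
#' ML class and its relatedness coefficient r = k1/2 + k2.  Optionally
#' returns the `subset_size` individuals with the lowest mean pairwise
#' relatedness (greedy rank selection), used to de-bias clustering runs
#' dominated by family groups.
#'
#' @param geno Genotype matrix (individuals x two columns per locus;
#'   rownames are individual ids).
#' @param freqs Per-locus allele frequency list.
#' @param subset_size Optional size of the least-related subset.
#' @param min_shared Minimum shared scored loci per pair (default 5);
#'   pairs below it get `NA` relatedness.
#' @return List with `pairs` (data frame: id1, id2, n_loci, class, r,
#'   logL), `r_matrix` (symmetric), and `subset` (character ids or
#'   `NULL`).
#' @export
pairwise_relatedness <- function(geno, freqs, subset_size = NULL,
                                 min_shared = 5) {
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(geno)))
  loci <- setdiff(intersect(geno_loci(geno), names(freqs)), "sex")
  classes <- relatedness_classes()
  rvals <- c(U = 0, HS = 0.25, FS = 0.5, PO = 0.5)
  n <- nrow(geno)
  rmat <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(rmat) <- 0
  rows <- vector("list", n * (n - 1) / 2)
  q <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ll <- setNames(numeric(4), rownames(classes))
    used <- 0L
    for (l in loci) {
      g1 <- geno[i, paste0(l, ".", 1:2)]
      g2 <- geno[j, paste0(l, ".", 1:2)]
      if (anyNA(g1) || anyNA(g2)) next
      g1 <- sort(g1); g2 <- sort(g2)
      p <- freqs[[l]]
      lk <- vapply(rownames(classes), function(cl)
        pair_locus_lik(g1, g2, p, classes[cl, ]), numeric(1))
      if (anyNA(lk)) next
      used <- used + 1L
      ll <- ll + log(pmax(lk, 1e-300))
    }
    q <- q + 1L
    if (used < min_shared) {
      rows[[q]] <- data.frame(id1 = ids[i], id2 = ids[j], n_loci = used,
                              class = NA_character_, r = NA_real_,
                              logL = NA_real_, stringsAsFactors = FALSE)
      next
    }
    best <- names(which.max(ll))
    rows[[q]] <- data.frame(id1 = ids[i], id2 = ids[j], n_loci = used,
                            class = best, r = unname(rvals[best]),
                            logL = max(ll), stringsAsFactors = FALSE)
    rmat[i, j] <- rmat[j, i] <- rvals[best]
  }
  pairs <- do.call(rbind, rows[seq_len(q)])

  subset <- NULL
  if (!is.null(subset_size)) {
    if (subset_size > n) stop("subset_size exceeds number of individuals")
    mean_r <- rowMeans(rmat, na.rm = TRUE)
    subset <- ids[order(mean_r, ids)][seq_len(subset_size)]
  }
  list(pairs = pairs, r_matrix = rmat, subset = subset)
}
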