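## Allele frequencies, heterozygosity and rarefied allelic richness.

## Per-locus allele counts of a genotype matrix (n x 2L).  Returns
## list(counts = named integer vector, n = individuals genotyped).
locus_counts <- function(geno, locus) {
  a <- geno[, paste0(locus, ".1")]
  b <- geno[, paste0(locus, ".2")]
  ok <- !is.na(a) & !is.na(b)
  cnt <- table(factor(c(a[ok], b[ok])))
  list(counts = setNames(as.integer(cnt), names(cnt)), n = sum(ok))
}

#' Estimate allele frequencies from genotypes
#'
#' @param geno_by_pop Named list of genotype matrices (individuals x
#'   two columns per locus), one per population; or a single matrix
#'   (treated as one population `"pop1"`).
#' @return An `allele_freqs` object (per population, per locus named
#'   frequency vectors) with attribute `n`: per population, the number
#'   of individuals genotyped at each locus.
#' @export
allele_frequencies <- function(geno_by_pop) {
  if (is.matrix(geno_by_pop)) geno_by_pop <- list(pop1 = geno_by_pop)
  out <- lapply(geno_by_pop, function(g) {
    loci <- geno_loci(g)
    res <- lapply(loci, function(l) {
      lc <- locus_counts(g, l)
      if (lc$n == 0) return(setNames(numeric(0), character(0)))
      lc$counts / sum(lc$counts)
    })
    names(res) <- loci
    if (all(vapply(res, length, integer(1)) == 0))
      stop("population with zero genotyped individuals at every locus")
    res
  })
  ns <- lapply(geno_by_pop, function(g)
    vapply(geno_loci(g), function(l) locus_counts(g, l)$n, integer(1)))
  structure(out, n = ns, class = "allele_freqs")
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random draw of `g` gene
#' copies: `R_g = sum_i [1 - C(2N - N_i, g) / C(2N, g)]` where `N` is
#' the number of genotyped individuals and `N_i` the observed copies of
#' allele `i`.
#'
#' @param counts Named integer vector of allele copy counts.
#' @param g Rarefaction size in gene copies (>= 2, <= `sum(counts)`).
#' @return Expected allele count in `[1, length(counts)]`.
#' @export
allelic_richness <- function(counts, g) {
  if (g < 2) stop("rarefaction size g must be >= 2")
  total <- sum(counts)
  if (g > total) stop("g exceeds available gene copies")
  sum(1 - exp(lchoose(total - counts, g) - lchoose(total, g)))
}

#' Per-population genetic diversity
#'
#' Observed heterozygosity `Ho`, Nei's unbiased expected heterozygosity
#' `He = (2n/(2n-1)) (1 - sum p_i^2)`, and rarefied allelic richness
#' `R_g`, per locus and as mean +/- SE across loci.
#'
#' @param geno_by_pop Named list of genotype matrices (or one matrix).
#' @param g Rarefaction size in gene copies; defaults to twice the
#'   smallest locus-wise sample size across populations.
#' @param loci Loci to use (default: all except the `sex` marker).
#' @return List with `per_locus` (data frame: pop, locus, n, Ho, He,
#'   richness) and `summary` (data frame: pop, n, Ho, Ho_se, He, He_se,
#'   richness, richness_se, g).
#' @export
diversity_stats <- function(geno_by_pop, g = NULL, loci = NULL) {
  if (is.matrix(geno_by_pop)) geno_by_pop <- list(pop1 = geno_by_pop)
  if (is.null(loci))
    loci <- setdiff(geno_loci(geno_by_pop[[1]]), "sex")
  ns <- unlist(lapply(geno_by_pop, function(gm)
    vapply(loci, function(l) locus_counts(gm, l)$n, integer(1))))
  if (is.null(g)) g <- 2L * min(ns)
  if (g < 2) stop("rarefaction size g must be >= 2")
  if (g > 2 * min(ns))
    stop("g exceeds 2 * smallest locus-wise sample size")

  rows <- list()
  for (p in names(geno_by_pop)) {
    gm <- geno_by_pop[[p]]
    for (l in loci) {
      a <- gm[, paste0(l, ".1")]; b <- gm[, paste0(l, ".2")]
      ok <- !is.na(a) & !is.na(b)
      n <- sum(ok)
      if (n == 0) next
      ho <- mean(a[ok] != b[ok])
      lc <- locus_counts(gm, l)
      pr <- lc$counts / sum(lc$counts)
      he <- (2 * n / (2 * n - 1)) * (1 - sum(pr^2))
      rows[[length(rows) + 1]] <- data.frame(
        pop = p, locus = l, n = n, Ho = ho, He = he,
        richness = allelic_richness(lc$counts, g),
        stringsAsFactors = FALSE)
    }
  }
  per_locus <- do.call(rbind, rows)
  se <- function(x) sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(split(per_locus, per_locus$pop), function(d)
    data.frame(pop = d$pop[1], n = mean(d$n),
               Ho = mean(d$Ho), Ho_se = se(d$Ho),
               He = mean(d$He), He_se = se(d$He),
               richness = mean(d$richness), richness_se = se(d$richness),
               g = g, stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(per_locus = per_locus, summary = summ)
}
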