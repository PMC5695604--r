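## Cross-population comparison of per-locus diversity statistics:
## Kruskal-Wallis omnibus test with Nemenyi all-pairs post hoc
## comparisons on the studentized range distribution.

#' Compare per-locus diversity across populations
#'
#' Treats per-locus statistic values (e.g. He, Ho or allelic richness at
#' each locus) as replicates within each population: Kruskal-Wallis rank
#' sum test (tie-corrected) for the omnibus hypothesis, then Nemenyi
#' all-pairs comparisons of mean ranks referred to the studentized range
#' distribution.
#'
#' @param values Named list of numeric vectors, one per population
#'   (per-locus statistic values).
#' @return List with `H` (Kruskal-Wallis statistic), `p` (omnibus
#'   P-value), `nemenyi` (symmetric matrix of pairwise P-values, 1 on
#'   the diagonal).
#' @examples
#' compare_diversity(list(a = c(1, 2, 3), b = c(11, 12, 13),
#'                        c = c(21, 22, 23)))
#' @export
compare_diversity <- function(values) {
  if (length(values) < 2) stop("need >= 2 groups")
  if (any(vapply(values, length, integer(1)) < 2))
    stop("need >= 2 per-locus values in each group")
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), vapply(values, length, integer(1))))
  if (length(unique(x)) == 1) {
    k <- length(values)
    ones <- matrix(1, k, k, dimnames = list(names(values), names(values)))
    return(list(H = 0, p = 1, nemenyi = ones))
  }
  kw <- kruskal.test(x, g)

  N <- length(x)
  k <- nlevels(g)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  ties <- table(r)
  tie_c <- 1 - sum(ties^3 - ties) / (N^3 - N)
  pops <- levels(g)
  pm <- matrix(1, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12) * tie_c * (1 / ni[i] + 1 / ni[j]))
    q <- abs(rbar[i] - rbar[j]) / se * sqrt(2)
    pm[i, j] <- pm[j, i] <- ptukey(q, nmeans = k, df = Inf,
                                   lower.tail = FALSE)
  }
  list(H = unname(kw$statistic), p = kw$p.value, nemenyi = pm)
}
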