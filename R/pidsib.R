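## Sibling probability of identity and locus-panel construction.

#' Per-locus sibling probability of identity
#'
#' Probability that two full siblings share the same single-locus
#' genotype, from allele frequencies `p`:
#' `PIDsib = 1/4 + (1/2) S2 + (1/2) S2^2 - (1/4) S4`
#' with `S2 = sum(p^2)`, `S4 = sum(p^4)`.
#'
#' @param p Numeric vector of allele frequencies (must be non-negative
#'   and sum to 1).
#' @return PIDsib in `(0, 1]`.
#' @examples
#' pidsib_locus(c(0.5, 0.5))  # 0.59375
#' @export
pidsib_locus <- function(p) {
  if (any(p < 0)) stop("negative allele frequencies")
  if (length(p) == 0) stop("empty frequency vector")
  if (abs(sum(p) - 1) > 1e-8) stop("frequencies must sum to 1")
  s2 <- sum(p^2); s4 <- sum(p^4)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
}

#' Build a PIDsib locus panel
#'
#' Orders loci from least powerful (highest PIDsib) to most powerful and
#' takes the shortest prefix whose cumulative PIDsib product falls at or
#' below `threshold`.  Starting from the weak end makes the selected
#' panel size conservative: any other subset of the same size has equal
#' or lower sibling-identity probability.  If even the full product
#' stays above the threshold, all loci are returned with
#' `reached = FALSE`.
#'
#' @param freqs Per-locus list of allele frequency vectors (one
#'   population's element of an `allele_freqs` object, or pooled-sample
#'   frequencies from [allele_frequencies()]).
#' @param threshold Maximum acceptable multilocus sibling identity
#'   probability (default 0.03).
#' @return A `locus_panel`: list with `table` (locus, pidsib, cumulative
#'   product in build order), `panel` (selected locus names), `pidsib`
#'   (named per-locus values, build order), `product`, `threshold`,
#'   `reached`.
#' @export
pidsib_panel <- function(freqs, threshold = 0.03) {
  if (length(freqs) == 0) stop("empty locus set")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  freqs <- freqs[names(freqs) != "sex"]
  v <- vapply(freqs, pidsib_locus, numeric(1))
  ord <- order(v, decreasing = TRUE)   # least powerful first
  v <- v[ord]
  cp <- cumprod(v)
  k <- which(cp <= threshold)
  reached <- length(k) > 0
  n_sel <- if (reached) min(length(v), max(2L, min(k))) else length(v)
  if (!reached)
    warning("PIDsib threshold not reached; panel uses all loci")
  tab <- data.frame(locus = names(v), pidsib = unname(v),
                    cumprod = unname(cp), stringsAsFactors = FALSE)
  structure(list(table = tab, panel = names(v)[seq_len(n_sel)],
                 pidsib = v, product = cp[n_sel],
                 threshold = threshold, reached = reached),
            class = "locus_panel")
}

#' @export
print.locus_panel <- function(x, ...) {
  cat(sprintf(
    "PIDsib panel: %d of %d loci, product %.4g (threshold %g%s)\n",
    length(x$panel), nrow(x$table), x$product, x$threshold,
    if (x$reached) "" else ", NOT reached"))
  invisible(x)
}
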