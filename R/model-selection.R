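## LRT screening of nested model pairs and AICc ranking with Akaike
## weights.

#' Screen and rank a set of model fits
#'
#' Applies a likelihood-ratio test to every nested pair (nesting is
#' declared by containment of `param_names`): a richer model that does
#' not improve significantly (chi-square with df = difference in K, at
#' `alpha`) on one of its nested reductions in the set is removed.
#' Survivors are ranked by `AICc = -2 logL + 2K + 2K(K+1)/(n_eff-K-1)`
#' with delta-AICc and Akaike weights.
#'
#' @param fits Named list of `model_fit` objects sharing the same data.
#' @param effective_n Effective sample size for AICc; defaults to the
#'   fits' own `n_eff` (total detection-occasion trials of observed
#'   animals).
#' @param alpha LRT significance level (default 0.05).
#' @return A `model_table`: data frame (model, K, logL, AICc,
#'   delta_AICc, weight, removed_by_lrt, lrt_p) sorted by AICc among
#'   survivors first.
#' @export
rank_models <- function(fits, effective_n = NULL, alpha = 0.05) {
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$model, character(1))
  K <- vapply(fits, function(f) f$K, numeric(1))
  logL <- vapply(fits, function(f) f$logL, numeric(1))
  n_eff <- if (is.null(effective_n))
    vapply(fits, function(f) f$n_eff, numeric(1)) else
    rep(effective_n, length(fits))
  if (any(n_eff <= K + 1)) stop("effective_n <= K + 1: AICc undefined")
  aicc <- -2 * logL + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)

  nested_in <- function(a, b)   # a nested in b
    length(fits[[a]]$param_names) < length(fits[[b]]$param_names) &&
    all(fits[[a]]$param_names %in% fits[[b]]$param_names)

  removed <- logical(length(fits))
  lrt_p <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i == j || !nested_in(i, j)) next
    stat <- max(0, 2 * (logL[j] - logL[i]))
    df <- K[j] - K[i]
    p <- pchisq(stat, df, lower.tail = FALSE)
    if (is.na(lrt_p[j]) || p > lrt_p[j]) lrt_p[j] <- p
    if (p >= alpha) removed[j] <- TRUE
  }
  keep <- !removed
  d <- aicc - min(aicc[keep])
  w <- rep(0, length(fits))
  w[keep] <- exp(-d[keep] / 2) / sum(exp(-d[keep] / 2))
  out <- data.frame(model = names(fits), K = K, logL = logL, AICc = aicc,
                    delta_AICc = ifelse(keep, d, NA_real_), weight = w,
                    removed_by_lrt = removed, lrt_p = lrt_p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$removed_by_lrt, out$AICc), ]
  rownames(out) <- NULL
  structure(out, class = c("model_table", "data.frame"))
}
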