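## Individual identification: dropout-aware sample matching under a
## PIDsib panel, single-sample reliability screening, and cross-lab
## allele-size calibration.

## Dropout-explainable mismatch: one call homozygous for an allele the
## other call's heterozygote contains.
dropout_explainable <- function(a1, a2, b1, b2) {
  (a1 == a2 & b1 != b2 & (a1 == b1 | a1 == b2)) |
  (b1 == b2 & a1 != a2 & (b1 == a1 | b1 == a2))
}

#' Merge consensus genotypes into individuals
#'
#' Two samples match when, over mutually non-missing panel loci, (i) the
#' number of mismatching loci is at most `max_mismatch`, (ii) every
#' mismatch is dropout-explainable (one sample homozygous for an allele
#' contained in the other's heterozygote), and (iii) the PIDsib product
#' over the matching compared loci stays at or below `threshold`, so the
#' comparison retains enough power to exclude siblings.  Matching
#' samples are merged by complete linkage in canonical sample-id order:
#' a sample joins a cluster only if it matches every member, so
#' non-transitive triples (A~B, B~C, A!~C) are refused and flagged for
#' re-amplification rather than chained into one individual.  Merged
#' genotypes take the heterozygote at dropout-explained loci.
#' Individuals represented by a single sample are retained only if their
#' [reliability_score()] is at least `reliability_min` and they
#' amplified at no fewer than `panel size - max_mismatch` panel loci
#' ("7 of 8" / "12 of 14").  Because the inputs are consensus genotypes
#' (a homozygote is only confirmed by two concordant replicates), the
#' reliability screen uses the consensus-level dropout rate
#' `e_D^2 / 2` -- the probability that two independent replicates both
#' dropped the same allele -- rather than the per-replicate `e_D`.
#'
#' @param cs A `consensus_set` from [consensus_set()].
#' @param panel A `locus_panel` from [pidsib_panel()] (or a character
#'   vector of panel loci plus `pidsib` attribute).
#' @param freqs Per-locus allele frequency list used for PIDsib values
#'   and reliability (typically pooled pre-individualization frequencies
#'   from [allele_frequencies()]).
#' @param em [error_model()] used by the reliability screen.
#' @param max_mismatch Mismatch budget; default 1 for panels of up to 10
#'   loci ("7 of 8"), otherwise 2 ("12 of 14").
#' @param threshold PIDsib product that compared loci must maintain
#'   (default 0.03).
#' @param reliability_min Minimum reliability for singletons (default
#'   0.9).
#' @return An `individual_set`: list with `individuals` (data frame: id,
#'   sex, n_samples, reliability, flagged), `genotypes` (individuals x
#'   2L matrix), `members` (list of sample ids), `dropped` (data frame
#'   of excluded samples with reasons), `log` (pairwise merge decisions
#'   for flagged cases).
#' @export
match_samples <- function(cs, panel, freqs, em = error_model(),
                          max_mismatch = NULL, threshold = 0.03,
                          reliability_min = 0.9) {
  panel_loci <- if (inherits(panel, "locus_panel")) panel$panel else panel
  pid <- if (inherits(panel, "locus_panel")) panel$pidsib else
    vapply(freqs[panel_loci], pidsib_locus, numeric(1))
  pid <- pid[panel_loci]
  if (is.null(max_mismatch))
    max_mismatch <- if (length(panel_loci) <= 10) 1L else 2L
  ## consensus-level dropout: both confirming replicates dropped the
  ## same allele of a true heterozygote
  screen_em <- error_model(dropout = em$dropout^2 / 2,
                           false_allele = em$false_allele,
                           failure = em$failure)

  ord <- order(rownames(cs$genotypes))
  geno <- cs$genotypes[ord, , drop = FALSE]
  status <- cs$status[ord, , drop = FALSE]
  ids <- rownames(geno)
  n <- length(ids)

  ## panel allele matrices (confirmed calls only)
  conf <- status[, panel_loci, drop = FALSE] == "confirmed"
  A1 <- geno[, paste0(panel_loci, ".1"), drop = FALSE]
  A2 <- geno[, paste0(panel_loci, ".2"), drop = FALSE]
  A1[!conf] <- NA_integer_; A2[!conf] <- NA_integer_

  usable <- rowSums(!is.na(A1)) > 0
  dropped <- data.frame(sample_id = ids[!usable],
                        reason = rep("no scored panel loci", sum(!usable)),
                        stringsAsFactors = FALSE)

  pair_match <- function(i, j) {
    ok <- !is.na(A1[i, ]) & !is.na(A1[j, ])
    if (!any(ok)) return(FALSE)
    same <- A1[i, ok] == A1[j, ok] & A2[i, ok] == A2[j, ok]
    mism <- which(!same)
    if (length(mism) > max_mismatch) return(FALSE)
    if (length(mism)) {
      k <- which(ok)[mism]
      if (!all(dropout_explainable(A1[i, k], A2[i, k], A1[j, k], A2[j, k])))
        return(FALSE)
    }
    prod(pid[which(ok)[same]]) <= threshold
  }

  clusters <- list()
  flagged <- character(0)
  logs <- list()
  for (i in which(usable)) {
    hits <- integer(0)
    partial <- FALSE
    for (c in seq_along(clusters)) {
      m <- vapply(clusters[[c]], function(j) pair_match(i, j), logical(1))
      if (all(m)) hits <- c(hits, c) else if (any(m)) partial <- TRUE
    }
    if (length(hits) == 0) {
      clusters[[length(clusters) + 1]] <- i
    } else {
      clusters[[hits[1]]] <- c(clusters[[hits[1]]], i)
    }
    if (partial || length(hits) > 1) {
      flagged <- c(flagged, ids[i])
      logs[[length(logs) + 1]] <- data.frame(
        sample_id = ids[i],
        event = if (length(hits) > 1) "ambiguous multi-cluster match"
                else "non-transitive match refused",
        stringsAsFactors = FALSE)
    }
  }

  ## merged consensus per cluster
  loci <- geno_loci(geno)
  merge_cluster <- function(members) {
    out <- rep(NA_integer_, ncol(geno))
    names(out) <- colnames(geno)
    for (l in loci) {
      i1 <- paste0(l, ".1"); i2 <- paste0(l, ".2")
      ok <- members[status[members, l] == "confirmed"]
      if (!length(ok)) next
      a <- geno[ok, i1]; b <- geno[ok, i2]
      key <- norm_pair(a, b)
      hets <- unique(key[a != b])
      if (length(hets) == 1) {
        homs <- unique(a[a == b])
        ab <- as.integer(strsplit(hets, "/")[[1]])
        if (all(homs %in% ab)) { out[c(i1, i2)] <- ab; next }
      }
      if (length(hets) == 0 && length(unique(key)) == 1) {
        out[c(i1, i2)] <- c(a[1], b[1]); next
      }
      ## disagreement among member consensus calls: majority, ties -> NA
      tab <- sort(table(key), decreasing = TRUE)
      if (length(tab) == 1 || tab[1] > tab[2])
        out[c(i1, i2)] <- as.integer(strsplit(names(tab)[1], "/")[[1]])
    }
    out
  }

  sex_of <- function(members) {
    if (!"sex" %in% loci) return("unknown")
    ok <- members[status[members, "sex"] == "confirmed"]
    if (!length(ok)) return("unknown")
    y <- geno[ok, "sex.2"] == 2L
    if (any(y)) "M" else "F"
  }

  res_geno <- matrix(NA_integer_, length(clusters), ncol(geno),
                     dimnames = list(NULL, colnames(geno)))
  ind <- data.frame(id = character(length(clusters)),
                    sex = character(length(clusters)),
                    n_samples = integer(length(clusters)),
                    reliability = numeric(length(clusters)),
                    flagged = logical(length(clusters)),
                    stringsAsFactors = FALSE)
  members <- vector("list", length(clusters))
  keep <- logical(length(clusters))
  for (c in seq_along(clusters)) {
    mem <- clusters[[c]]
    members[[c]] <- ids[mem]
    res_geno[c, ] <- merge_cluster(mem)
    rel <- tryCatch(
      reliability_score(res_geno[c, ], freqs, screen_em,
                        loci = panel_loci),
      error = function(e) 0)
    n_amp <- sum(!is.na(res_geno[c, paste0(panel_loci, ".1")]))
    ind$id[c] <- sprintf("B%03d", c)
    ind$sex[c] <- sex_of(mem)
    ind$n_samples[c] <- length(mem)
    ind$reliability[c] <- rel
    ind$flagged[c] <- any(ids[mem] %in% flagged)
    keep[c] <- length(mem) > 1 ||
      (rel >= reliability_min && n_amp >= length(panel_loci) - max_mismatch)
    if (!keep[c])
      dropped <- rbind(dropped, data.frame(
        sample_id = ids[mem],
        reason = "singleton below reliability/amplification screen",
        stringsAsFactors = FALSE))
  }

  res_geno <- res_geno[keep, , drop = FALSE]
  ind <- ind[keep, , drop = FALSE]
  members <- members[keep]
  ind$id <- sprintf("B%03d", seq_len(nrow(ind)))
  rownames(res_geno) <- ind$id
  rownames(ind) <- NULL
  names(members) <- ind$id

  structure(list(individuals = ind, genotypes = res_geno,
                 members = members, dropped = dropped,
                 log = if (length(logs)) do.call(rbind, logs) else
                   data.frame(sample_id = character(), event = character())),
            class = "individual_set")
}

#' @export
print.individual_set <- function(x, ...) {
  cat(sprintf("individuals: %d (from %d samples; %d dropped, %d flagged)\n",
              nrow(x$individuals), sum(x$individuals$n_samples),
              nrow(x$dropped), sum(x$individuals$flagged)))
  invisible(x)
}

#' Reliability of a consensus genotype
#'
#' Simplified single-sample reliability surrogate: each observed
#' homozygote A/A contributes the posterior probability that the true
#' genotype is A/A rather than a heterozygote A/x observed through
#' allelic dropout, under an HWE prior:
#' `P(AA|obs) = p_A / (p_A + e_D (1 - p_A))`;
#' each observed heterozygote contributes `1 - e_F`.  The score is the
#' product over non-missing loci.  This is a deliberately simplified
#' stand-in for full multi-replicate reliability algorithms: it uses the
#' consensus call only, not the replicate count behind it.
#'
#' @param genotype Named integer vector (two entries per locus).
#' @param freqs Per-locus allele frequency list.
#' @param em [error_model()].
#' @param loci Loci to include (default: all loci present in both the
#'   genotype and `freqs`, excluding the sex marker).
#' @return Probability in `[0, 1]`.
#' @export
reliability_score <- function(genotype, freqs, em = error_model(),
                              loci = NULL) {
  if (is.null(loci))
    loci <- setdiff(intersect(geno_loci(t(as.matrix(genotype))),
                              names(freqs)), "sex")
  score <- 1
  any_locus <- FALSE
  for (l in loci) {
    a <- genotype[[paste0(l, ".1")]]; b <- genotype[[paste0(l, ".2")]]
    if (is.na(a) || is.na(b)) next
    any_locus <- TRUE
    if (a != b) {
      score <- score * (1 - em$false_allele)
    } else if (em$dropout > 0) {
      p <- unname(freqs[[l]][as.character(a)])
      if (is.na(p)) p <- 0
      score <- score * p / (p + em$dropout * (1 - p))
    }
  }
  if (!any_locus) stop("genotype has no scored locus")
  score
}

#' Cross-source allele-size calibration
#'
#' Computes per-locus integer size offsets from reference individuals
#' genotyped by two laboratories/chemistries and shifts the second
#' source onto the first source's scale.  The offset at a locus must be
#' constant across all reference alleles; any inconsistency raises an
#' error naming the offending loci.
#'
#' @param ref_a,ref_b Integer genotype matrices (two columns per locus,
#'   same loci, same reference individuals in the same row order) from
#'   sources A and B.
#' @param genotypes_b Optional genotype matrix from source B to
#'   transform onto source A's scale (defaults to `ref_b`).
#' @return List with `offsets` (named per-locus integer, A - B) and
#'   `transformed` (shifted `genotypes_b`).
#' @export
calibrate_allele_sizes <- function(ref_a, ref_b, genotypes_b = ref_b) {
  loci <- geno_loci(ref_a)
  if (!identical(loci, geno_loci(ref_b)))
    stop("reference matrices must share loci")
  offsets <- setNames(rep(NA_integer_, length(loci)), loci)
  bad <- character(0)
  for (l in loci) {
    cols <- paste0(l, ".", 1:2)
    a <- t(apply(ref_a[, cols, drop = FALSE], 1, sort.int, method = "quick"))
    b <- t(apply(ref_b[, cols, drop = FALSE], 1, sort.int, method = "quick"))
    d <- (a - b)[!is.na(a - b)]
    if (length(d) == 0) next
    u <- unique(d)
    if (length(u) > 1) bad <- c(bad, l) else offsets[l] <- u
  }
  if (length(bad))
    stop("inconsistent allele-size offsets at loci: ",
         paste(bad, collapse = ", "))
  offsets[is.na(offsets)] <- 0L
  out <- genotypes_b
  for (l in loci) {
    cols <- paste0(l, ".", 1:2)
    out[, cols] <- out[, cols] + offsets[l]
  }
  list(offsets = offsets, transformed = out)
}
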