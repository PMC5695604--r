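## Consensus genotype calling from replicate amplifications.

norm_pair <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")

## Consensus for a single locus from replicate calls (2-col matrix,
## possibly with NA rows).  req_hom = concordant replicates needed to
## confirm a homozygote.  Returns list(call = c(a, b) or NA, status).
consensus_locus <- function(calls, req_hom) {
  ok <- !is.na(calls[, 1]) & !is.na(calls[, 2])
  calls <- calls[ok, , drop = FALSE]
  if (nrow(calls) == 0)
    return(list(call = c(NA_integer_, NA_integer_), status = "missing"))
  is_het <- calls[, 1] != calls[, 2]
  key <- norm_pair(calls[, 1], calls[, 2])
  cnt <- table(key)
  het_keys <- unique(key[is_het])
  het_conf <- het_keys[cnt[het_keys] >= 2]
  if (length(het_conf) > 1)        # two different confirmed heterozygotes
    return(list(call = c(NA_integer_, NA_integer_), status = "conflict"))
  if (length(het_conf) == 1) {     # dropout explains any homozygous reps
    ab <- as.integer(strsplit(het_conf, "/")[[1]])
    return(list(call = ab, status = "confirmed"))
  }
  hom_keys <- unique(key[!is_het])
  hom_conf <- hom_keys[cnt[hom_keys] >= req_hom]
  if (length(hom_conf) == 1 && length(het_keys) == 0 &&
      length(hom_keys) == 1) {
    a <- as.integer(strsplit(hom_conf, "/")[[1]][1])
    return(list(call = c(a, a), status = "confirmed"))
  }
  ## disagreement among replicates that no rule resolves
  if (length(unique(key)) > 1)
    return(list(call = c(NA_integer_, NA_integer_), status = "conflict"))
  list(call = c(NA_integer_, NA_integer_), status = "unconfirmed")
}

#' Call a consensus genotype from replicate amplifications
#'
#' Applies the replicate-concordance rules: an unordered heterozygous
#' pair seen in at least two replicates is confirmed (homozygous
#' replicates of its alleles are attributed to dropout); a homozygote
#' needs two concordant replicates for hair/tissue and three for scat,
#' and is demoted to a conflict if a heterozygous call was also seen.
#' Replicates are consumed progressively: the caller starts with two and
#' adds one at a time (emulating re-amplification of unresolved loci) up
#' to `max_reps` (4 for hair/tissue, 6 for scat by default).  Loci left
#' unconfirmed or in conflict after all replicates are reported missing.
#'
#' @param replicates Integer matrix, one row per replicate, two adjacent
#'   columns per locus (`<locus>.1`, `<locus>.2`); `NA` = no call.
#' @param sample_type One of `"hair"`, `"scat"`, `"tissue"`.
#' @param max_reps Maximum replicates to use; default 4 (hair/tissue)
#'   or 6 (scat).
#' @return A `consensus_genotype`: list with `genotype` (named integer
#'   vector, `NA` at unresolved loci), `status` (per-locus:
#'   confirmed/unconfirmed/conflict/missing), `n_reps_used`.
#' @examples
#' reps <- rbind(c(120, 124), c(120, 124))
#' colnames(reps) <- c("L01.1", "L01.2")
#' call_consensus(reps, "hair")$status
#' @export
call_consensus <- function(replicates,
                           sample_type = c("hair", "scat", "tissue"),
                           max_reps = NULL) {
  sample_type <- match.arg(sample_type)
  if (is.null(dim(replicates)))
    replicates <- matrix(replicates, nrow = 1,
                         dimnames = list(NULL, names(replicates)))
  if (nrow(replicates) < 1) stop("need at least one replicate")
  if (ncol(replicates) %% 2 != 0)
    stop("replicate calls must have two columns per locus (<=2 alleles)")
  req_hom <- if (sample_type == "scat") 3L else 2L
  max_reps <- if (is.null(max_reps)) {
    if (sample_type == "scat") 6L else 4L
  } else as.integer(max_reps)
  n_avail <- min(nrow(replicates), max_reps)

  loci <- geno_loci(replicates)
  L <- length(loci)
  geno <- rep(NA_integer_, 2 * L)
  names(geno) <- colnames(replicates)[seq_len(2 * L)]
  status <- setNames(rep("unconfirmed", L), loci)

  k <- min(2L, n_avail)
  repeat {
    for (l in seq_len(L)) {
      res <- consensus_locus(replicates[seq_len(k), c(2 * l - 1, 2 * l),
                                        drop = FALSE], req_hom)
      geno[c(2 * l - 1, 2 * l)] <- res$call
      status[l] <- res$status
    }
    unresolved <- status %in% c("unconfirmed", "conflict")
    if (!any(unresolved) || k >= n_avail) break
    k <- k + 1L           # re-amplify: consume one more replicate
  }
  structure(list(genotype = geno, status = status, n_reps_used = k),
            class = "consensus_genotype")
}

#' Consensus genotypes for a replicate-call sheet
#'
#' Runs [call_consensus()] on every sample of a replicate-call table
#' (the [genotype_samples()] dialect).
#'
#' @param calls Data frame with columns sample_id, type, replicate and
#'   two genotype columns per locus.
#' @return A `consensus_set`: list with `genotypes` (samples x 2L
#'   integer matrix, `NA` at unresolved loci), `status` (samples x L
#'   character matrix), `info` (sample_id, type, year, occasion,
#'   snare_id, n_reps_used).
#' @export
consensus_set <- function(calls) {
  meta_cols <- intersect(c("sample_id", "type", "year", "occasion",
                           "snare_id", "replicate"), names(calls))
  gcols <- setdiff(names(calls), meta_cols)
  ids <- unique(calls$sample_id)
  L <- length(gcols) / 2
  geno <- matrix(NA_integer_, length(ids), length(gcols),
                 dimnames = list(ids, gcols))
  status <- matrix(NA_character_, length(ids), L,
                   dimnames = list(ids, unique(sub("\\.[12]$", "", gcols))))
  info <- calls[match(ids, calls$sample_id),
                setdiff(meta_cols, "replicate"), drop = FALSE]
  info$n_reps_used <- NA_integer_
  rownames(info) <- NULL
  for (i in seq_along(ids)) {
    rows <- calls$sample_id == ids[i]
    reps <- as.matrix(calls[rows, gcols, drop = FALSE])
    storage.mode(reps) <- "integer"
    cg <- call_consensus(reps, sample_type = info$type[i])
    geno[i, ] <- cg$genotype
    status[i, ] <- cg$status
    info$n_reps_used[i] <- cg$n_reps_used
  }
  structure(list(genotypes = geno, status = status, info = info),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus genotypes: %d samples, %d loci (%.1f%% confirmed)\n",
              nrow(x$genotypes), ncol(x$status),
              100 * mean(x$status == "confirmed")))
  invisible(x)
}
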