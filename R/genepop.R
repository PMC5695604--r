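## Genepop file reading/writing (2- and 3-digit allele codes) and a
## STRUCTURE-format matrix writer for interoperability.

#' Read a Genepop genotype file
#'
#' Supports both the 2-digit and 3-digit allele-code dialects, locus
#' names on one comma-separated line or one per line, and `Pop` blocks.
#' `00`/`000` codes decode to missing.  Population labels default to
#' the last sample id of each block (the Genepop convention) unless
#' `pop_names` overrides them.
#'
#' @param path Path to the Genepop file.
#' @param pop_names Optional character vector of population labels.
#' @return Named list of genotype matrices (individuals x two columns
#'   per locus), rownames = sample ids.
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too short")
  body <- lines[-1]                       # drop title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no Pop line found")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  L <- length(loci)

  sample_idx <- setdiff(seq_along(body), c(seq_len(pop_idx[1] - 1), pop_idx))
  blocks <- split(sample_idx, findInterval(sample_idx, pop_idx))

  out <- lapply(seq_along(blocks), function(b) {
    rows <- body[blocks[[b]]]
    ids <- character(length(rows))
    geno <- matrix(NA_integer_, length(rows), 2 * L,
                   dimnames = list(NULL, paste0(rep(loci, each = 2),
                                                ".", 1:2)))
    for (r in seq_along(rows)) {
      parts <- strsplit(rows[r], ",")[[1]]
      if (length(parts) < 2)
        stop("malformed Genepop line (no comma): ", rows[r])
      ids[r] <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                        "\\s+")[[1]]
      if (length(codes) != L)
        stop(sprintf("line %d of block %d: %d genotype fields, expected %d",
                     r, b, length(codes), L))
      w <- nchar(codes) / 2
      if (any(w != floor(w)))
        stop("odd-width allele code in: ", rows[r])
      a1 <- as.integer(substr(codes, 1, w))
      a2 <- as.integer(substr(codes, w + 1, 2 * w))
      a1[a1 == 0L] <- NA_integer_
      a2[a2 == 0L] <- NA_integer_
      a1[is.na(a2)] <- NA_integer_
      a2[is.na(a1)] <- NA_integer_
      geno[r, seq(1, 2 * L, 2)] <- pmin(a1, a2)
      geno[r, seq(2, 2 * L, 2)] <- pmax(a1, a2)
    }
    rownames(geno) <- ids
    geno
  })
  names(out) <- if (!is.null(pop_names)) pop_names else
    vapply(out, function(g) rownames(g)[nrow(g)], character(1))
  out
}

#' Write genotypes to a Genepop file
#'
#' Fixed-width 3-digit allele codes (missing = `000`).  Allele values
#' above 999 are rejected with guidance to re-encode.
#'
#' @param geno_by_pop Named list of genotype matrices.
#' @param path Output path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno_by_pop, path,
                          title = "ngcmr genotype export") {
  if (is.matrix(geno_by_pop)) geno_by_pop <- list(pop1 = geno_by_pop)
  loci <- geno_loci(geno_by_pop[[1]])
  mx <- max(unlist(lapply(geno_by_pop, function(g) max(g, na.rm = TRUE))))
  if (mx > 999)
    stop("allele sizes > 999 cannot be encoded in Genepop 3-digit ",
         "codes; re-encode alleles (e.g. subtract a locus-wise offset)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (p in names(geno_by_pop)) {
    writeLines("Pop", con)
    g <- geno_by_pop[[p]]
    ids <- rownames(g)
    if (is.null(ids)) ids <- sprintf("%s_%03d", p, seq_len(nrow(g)))
    for (r in seq_len(nrow(g))) {
      codes <- vapply(loci, function(l) {
        a <- g[r, paste0(l, ".1")]; b <- g[r, paste0(l, ".2")]
        if (is.na(a) || is.na(b)) "000000" else sprintf("%03d%03d", a, b)
      }, character(1))
      writeLines(paste0(ids[r], " ,  ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write genotypes as a STRUCTURE two-row-per-individual matrix
#'
#' @param geno_by_pop Named list of genotype matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(geno_by_pop, path) {
  if (is.matrix(geno_by_pop)) geno_by_pop <- list(pop1 = geno_by_pop)
  loci <- geno_loci(geno_by_pop[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(loci, collapse = "\t"), con)
  for (pi in seq_along(geno_by_pop)) {
    g <- geno_by_pop[[pi]]
    ids <- rownames(g)
    if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(g)))
    for (r in seq_len(nrow(g))) {
      for (al in 1:2) {
        v <- g[r, paste0(loci, ".", al)]
        v[is.na(v)] <- -9L
        writeLines(paste(c(ids[r], pi, v), collapse = "\t"), con)
      }
    }
  }
  invisible(path)
}
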