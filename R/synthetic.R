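## Synthetic-data generator: structured allele frequencies, populations,
## hair-snare surveys and replicate genotyping errors, with a truth table
## so every downstream stage of the pipeline can be checked against known
## truth.

#' Genotyping error model
#'
#' Per-replicate, per-locus error process for noninvasive samples.
#'
#' @param dropout Probability `e_D` in `[0,1]` that one allele of a true
#'   heterozygote fails to amplify in a single replicate (the replicate
#'   then looks homozygous).
#' @param false_allele Probability `e_F` in `[0,1]` that a replicate call
#'   gains a spurious allele; the spurious allele replaces one of the
#'   called alleles, preferring a size-shifted neighbour of a true
#'   allele.
#' @param failure Probability `e_A` in `[0,1]` that a locus yields no
#'   call at all in a replicate.
#' @return An object of class `error_model`.
#' @examples
#' error_model(dropout = 0.1, false_allele = 0.01, failure = 0.05)
#' @export
error_model <- function(dropout = 0, false_allele = 0, failure = 0) {
  rates <- c(dropout = dropout, false_allele = false_allele,
             failure = failure)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("error rates must be in [0, 1]")
  if (dropout + false_allele > 1)
    stop("dropout + false_allele must be <= 1 (per-replicate event model)")
  structure(as.list(rates), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("genotyping error model: e_D=%.3g e_F=%.3g e_A=%.3g\n",
              x$dropout, x$false_allele, x$failure))
  invisible(x)
}

## Dirichlet draw via independent gammas; alpha of 0 gives a fixed 0.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate structured allele frequencies (Balding-Nichols)
#'
#' Draws per-population allele frequencies around shared ancestral
#' frequencies using the Balding-Nichols Dirichlet construction, with the
#' concentration calibrated so that the pairwise/multi-population Nei Gst
#' measured by [pairwise_differentiation()] has expectation `target_fst`.
#'
#' Under a Balding-Nichols draw with parameter `F`, the expected Nei Gst
#' among `k` sampled populations is `F(1-1/k)/(1-F/k)`, which is smaller
#' than `F` (the classical attenuation of Gst with few subpopulations).
#' Because this package measures differentiation as Gst, the generator
#' inverts that map (`F = k*target/(k-1+target)`) so the *measured*
#' differentiation matches the requested target.  Set
#' `calibrate = FALSE` to use `target_fst` as the raw Balding-Nichols
#' parameter instead.
#'
#' @param n_loci Number of loci (>= 1).
#' @param n_alleles Alleles per locus, recycled to `n_loci`.
#' @param target_fst Differentiation target in `[0, 1)`.
#' @param n_pops Number of populations.
#' @param seed Optional integer seed.
#' @param ancestral Optional list of per-locus ancestral frequency
#'   vectors (named by allele size); overrides random ancestral draws.
#' @param ancestral_alpha Dirichlet concentration for random ancestral
#'   frequencies (larger = more even).
#' @param calibrate Calibrate the Balding-Nichols parameter to the Gst
#'   scale (default `TRUE`).
#' @return An `allele_freqs` object: a list with one element per
#'   population, each a list of per-locus named frequency vectors.
#'   Allele names are integer fragment sizes.
#' @examples
#' af <- simulate_allele_frequencies(4, 4, target_fst = 0.1, n_pops = 2,
#'                                   seed = 1)
#' af$pop1$L01
#' @export
simulate_allele_frequencies <- function(n_loci, n_alleles, target_fst,
                                        n_pops = 2, seed = NULL,
                                        ancestral = NULL,
                                        ancestral_alpha = 1.5,
                                        calibrate = TRUE) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (any(n_alleles < 1)) stop("n_alleles must be >= 1")
  if (target_fst < 0 || target_fst >= 1)
    stop("target_fst must be in [0, 1) (1 is a degenerate Dirichlet)")
  if (!is.null(seed)) set.seed(seed)
  n_alleles <- rep_len(n_alleles, n_loci)
  loci <- sprintf("L%02d", seq_len(n_loci))

  if (is.null(ancestral)) {
    ancestral <- lapply(seq_len(n_loci), function(l) {
      k <- n_alleles[l]
      p <- if (k == 1) 1 else sort(rdirichlet1(rep(ancestral_alpha, k)),
                                   decreasing = TRUE)
      names(p) <- as.character(100 + 2 * (seq_len(k) - 1))  # dinucleotide sizes
      p
    })
  }
  names(ancestral) <- loci

  f_bn <- if (target_fst == 0) 0 else if (calibrate)
    n_pops * target_fst / (n_pops - 1 + target_fst) else target_fst

  pops <- lapply(seq_len(n_pops), function(i) {
    lapply(ancestral, function(p) {
      if (f_bn == 0 || length(p) == 1) return(p)
      q <- rdirichlet1(p * (1 - f_bn) / f_bn)
      names(q) <- names(p)
      q
    })
  })
  names(pops) <- paste0("pop", seq_len(n_pops))
  structure(pops, ancestral = ancestral, target_fst = target_fst,
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("allele frequencies: %d population(s), %d loci\n",
              length(x), length(x[[1]])))
  invisible(x)
}

## Locus names of a genotype matrix (2 adjacent columns per locus,
## named "<locus>.1"/"<locus>.2").
geno_loci <- function(geno) unique(sub("\\.[12]$", "", colnames(geno)))

## Draw n HWE genotypes from per-locus frequency list -> matrix n x 2L.
draw_genotypes <- function(freqs, n) {
  cols <- unlist(lapply(names(freqs), function(l) paste0(l, ".", 1:2)))
  g <- matrix(NA_integer_, n, length(cols), dimnames = list(NULL, cols))
  for (l in names(freqs)) {
    p <- freqs[[l]]
    a <- as.integer(names(p))
    a1 <- sample(a, n, TRUE, p); a2 <- sample(a, n, TRUE, p)
    g[, paste0(l, ".", 1:2)] <- cbind(pmin(a1, a2), pmax(a1, a2))
  }
  g
}

## Mendelian offspring of two parent genotype rows (vectors length 2L).
mendel_offspring <- function(mother, father, n) {
  L <- length(mother) / 2
  out <- matrix(NA_integer_, n, length(mother),
                dimnames = list(NULL, names(mother)))
  for (l in seq_len(L)) {
    i <- c(2 * l - 1, 2 * l)
    m <- mother[i][sample.int(2, n, TRUE)]
    f <- father[i][sample.int(2, n, TRUE)]
    out[, i[1]] <- pmin(m, f)
    out[, i[2]] <- pmax(m, f)
  }
  out
}

#' Simulate a true population with known genotypes
#'
#' Draws individuals with HWE multilocus genotypes from one population's
#' allele frequencies, assigns sexes and planar home-range centres, and
#' realizes a year-by-year abundance trajectory by survival followed by
#' recruitment of new genotypes from the same frequencies.  Optional
#' full-sib families replace independent draws for PIDsib stress tests.
#' A sex marker locus (`sex`, alleles 1 = X, 2 = Y) is appended to every
#' genotype.
#'
#' @param freqs Per-locus list of allele frequency vectors (one
#'   population's element of an `allele_freqs` object).
#' @param N_by_year Integer vector of within-year population sizes.
#' @param sex_ratio Proportion of females in `(0,1)`.
#' @param sibship Optional list `list(n_families=, size=)` requesting
#'   full-sib families of the given size among the founders.
#' @param region Numeric `c(xmin, xmax, ymin, ymax)` in km for
#'   home-range centres.
#' @param survival Annual apparent survival used when realizing the
#'   trajectory (individuals removed at random; recruits are appended to
#'   reach the target `N_t`).
#' @param seed Optional integer seed.
#' @return A `true_population`: list with `individuals` (data frame:
#'   id, sex, x, y, family), `genotypes` (integer matrix, two columns
#'   per locus incl. the `sex` marker), `alive` (logical matrix
#'   individuals x years), `N_by_year`, and the generating `freqs`.
#' @export
simulate_population <- function(freqs, N_by_year, sex_ratio = 0.5,
                                sibship = NULL,
                                region = c(0, 40, 0, 40),
                                survival = 0.9, seed = NULL) {
  if (any(N_by_year < 1)) stop("N_by_year must be positive")
  if (sex_ratio <= 0 || sex_ratio >= 1) stop("sex_ratio must be in (0,1)")
  if (!is.null(seed)) set.seed(seed)
  n_years <- length(N_by_year)
  n1 <- N_by_year[1]

  new_genos <- function(n) draw_genotypes(freqs, n)
  geno <- new_genos(n1)
  family <- rep(NA_integer_, n1)
  if (!is.null(sibship) && sibship$n_families > 0) {
    if (sibship$n_families * sibship$size > n1)
      stop("sibship configuration exceeds population size")
    idx <- 1L
    for (f in seq_len(sibship$n_families)) {
      par <- draw_genotypes(freqs, 2)
      rows <- idx:(idx + sibship$size - 1)
      geno[rows, ] <- mendel_offspring(par[1, ], par[2, ], sibship$size)
      family[rows] <- f
      idx <- idx + sibship$size
    }
  }

  total_cap <- n1 + sum(pmax(0, diff(N_by_year))) + sum(N_by_year)  # generous
  geno <- rbind(geno, matrix(NA_integer_, total_cap - n1, ncol(geno),
                             dimnames = list(NULL, colnames(geno))))
  family <- c(family, rep(NA_integer_, total_cap - n1))
  sexes <- ifelse(runif(total_cap) < sex_ratio, "F", "M")
  alive <- matrix(FALSE, total_cap, n_years)
  alive[seq_len(n1), 1] <- TRUE
  n_created <- n1

  for (t in seq_len(n_years - 1)) {
    cur <- which(alive[, t])
    surv <- cur[runif(length(cur)) < survival]
    target <- N_by_year[t + 1]
    if (length(surv) > target) surv <- sample(surv, target)
    alive[surv, t + 1] <- TRUE
    need <- target - length(surv)
    if (need > 0) {
      rows <- n_created + seq_len(need)
      geno[rows, ] <- new_genos(need)
      alive[rows, t + 1] <- TRUE
      n_created <- n_created + need
    }
  }

  keep <- seq_len(n_created)
  geno <- geno[keep, , drop = FALSE]
  alive <- alive[keep, , drop = FALSE]
  sexes <- sexes[keep]
  family <- family[keep]

  ## sex marker locus: females X/X (1/1), males X/Y (1/2)
  sx <- cbind(sex.1 = rep(1L, n_created),
              sex.2 = ifelse(sexes == "M", 2L, 1L))
  geno <- cbind(geno, sx)

  ind <- data.frame(
    id = sprintf("ind%03d", keep),
    sex = sexes,
    x = runif(n_created, region[1], region[2]),
    y = runif(n_created, region[3], region[4]),
    family = family,
    stringsAsFactors = FALSE)
  rownames(geno) <- ind$id

  structure(list(individuals = ind, genotypes = geno, alive = alive,
                 N_by_year = as.integer(N_by_year), freqs = freqs),
            class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  cat(sprintf("true population: %d individuals over %d year(s), N_t = %s\n",
              nrow(x$individuals), length(x$N_by_year),
              paste(x$N_by_year, collapse = ", ")))
  invisible(x)
}

#' Hair-snare survey design
#'
#' Lays out snares on a square grid of cells (one or more snares per
#' cell, snares jittered within the cell) and fixes the occasion
#' calendar.  Cells default to 8 x 8 km (64 km^2), matching a male black
#' bear home range.
#'
#' @param n_cells_x,n_cells_y Grid dimensions in cells.
#' @param cell_km Cell edge length in km.
#' @param snares_per_cell Snares per cell.
#' @param occasions Snare-check occasions per year (>= 2); one occasion
#'   corresponds to one 6-8 day check interval.
#' @param years Number of annual sampling seasons.
#' @param jitter Uniform jitter (km) of each snare around its cell
#'   centre; 0 places snares exactly at centres.
#' @param seed Optional integer seed.
#' @return A `survey_design`: list with `snares` (data frame snare_id,
#'   x_km, y_km, cell_id), `occasions`, `years`, `cell_km`.
#' @export
survey_design <- function(n_cells_x = 5, n_cells_y = 5, cell_km = 8,
                          snares_per_cell = 1, occasions = 10, years = 1,
                          jitter = 2, seed = NULL) {
  if (occasions < 2) stop("need >= 2 occasions per year")
  if (years < 1) stop("years must be >= 1")
  if (snares_per_cell < 1) stop("need >= 1 snare per cell")
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(cx = seq_len(n_cells_x), cy = seq_len(n_cells_y))
  rows <- cells[rep(seq_len(nrow(cells)), each = snares_per_cell), ]
  n <- nrow(rows)
  x <- (rows$cx - 0.5) * cell_km + runif(n, -jitter, jitter)
  y <- (rows$cy - 0.5) * cell_km + runif(n, -jitter, jitter)
  snares <- data.frame(
    snare_id = sprintf("S%03d", seq_len(n)),
    x_km = x, y_km = y,
    cell_id = sprintf("C%02d_%02d", rows$cx, rows$cy),
    stringsAsFactors = FALSE)
  structure(list(snares = snares, occasions = as.integer(occasions),
                 years = as.integer(years), cell_km = cell_km),
            class = "survey_design")
}

#' Simulate a hair-snare survey over a true population
#'
#' Each occasion, individual `i` alive in year `t` deposits a hair
#' sample at snare `s` with probability `p0 * exp(-d(i,s)^2 / (2
#' sigma^2))`, a half-normal function of the distance from its home
#' range centre (sigma = `Inf` gives distance-free detection `p0`).
#'
#' @param population A `true_population`.
#' @param design A `survey_design` with `years` matching the population
#'   trajectory length.
#' @param p0 Baseline per-snare, per-occasion detection probability.
#' @param sigma Half-normal detection scale in km (may be `Inf`).
#' @param seed Optional integer seed.
#' @return List with `samples` (data frame: sample_id, type, year,
#'   occasion, snare_id) and `truth` (list: `sample_map` mapping
#'   sample_id -> individual id, `captures` (individual, year, occasion,
#'   snare_id), `N_by_year`).
#' @export
simulate_survey <- function(population, design, p0, sigma, seed = NULL) {
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  if (!(sigma > 0)) stop("sigma must be > 0")
  if (nrow(design$snares) == 0) stop("survey design has no snares")
  if (design$years != length(population$N_by_year))
    stop("design years != population trajectory length")
  if (!is.null(seed)) set.seed(seed)

  ind <- population$individuals
  sn <- design$snares
  d2 <- outer(ind$x, sn$x_km, "-")^2 + outer(ind$y, sn$y_km, "-")^2
  pdet <- if (is.infinite(sigma)) matrix(p0, nrow(d2), ncol(d2)) else
    p0 * exp(-d2 / (2 * sigma^2))

  caps <- vector("list", 64); k <- 0L
  for (t in seq_len(design$years)) {
    live <- which(population$alive[, t])
    if (!length(live)) next
    for (occ in seq_len(design$occasions)) {
      hit <- which(matrix(runif(length(live) * nrow(sn)), length(live)) <
                   pdet[live, , drop = FALSE], arr.ind = TRUE)
      if (nrow(hit)) {
        k <- k + 1L
        if (k > length(caps)) caps <- c(caps, vector("list", length(caps)))
        caps[[k]] <- data.frame(
          individual = ind$id[live[hit[, 1]]],
          year = t, occasion = occ,
          snare_id = sn$snare_id[hit[, 2]],
          stringsAsFactors = FALSE)
      }
    }
  }
  captures <- if (k) do.call(rbind, caps[seq_len(k)]) else
    data.frame(individual = character(), year = integer(),
               occasion = integer(), snare_id = character())
  ## canonical order, then one hair sample per capture event
  captures <- captures[order(captures$year, captures$occasion,
                             captures$snare_id, captures$individual), ]
  rownames(captures) <- NULL
  n_s <- nrow(captures)
  samples <- data.frame(
    sample_id = sprintf("H%05d", seq_len(n_s)),
    type = rep("hair", n_s),
    year = captures$year, occasion = captures$occasion,
    snare_id = captures$snare_id, stringsAsFactors = FALSE)
  sample_map <- data.frame(sample_id = samples$sample_id,
                           individual = captures$individual,
                           stringsAsFactors = FALSE)
  list(samples = samples,
       truth = list(sample_map = sample_map, captures = captures,
                    N_by_year = population$N_by_year))
}

#' Apply replicate genotyping errors to a true genotype
#'
#' Generates `n_replicates` independent amplification attempts of one
#' multilocus genotype.  Per replicate and locus: with probability `e_A`
#' the locus fails (no call); otherwise a heterozygote loses one allele
#' (chosen uniformly) with probability `e_D`; with probability `e_F` one
#' spurious allele replaces a uniformly chosen allele of the call,
#' preferring the size-shifted (+/- one repeat unit) neighbour of a true
#' allele when it exists in the locus allele pool.
#'
#' @param true_genotype Integer vector of length `2 * n_loci` (adjacent
#'   pairs per locus) with names `<locus>.1/<locus>.2`, or a 1-row
#'   matrix.
#' @param em An [error_model()].
#' @param n_replicates Number of replicates (>= 1).
#' @param allele_pool Optional list of per-locus allele size vectors
#'   used for spurious alleles; defaults to the alleles of the true
#'   genotype itself.
#' @param seed Optional integer seed.
#' @return Integer matrix `n_replicates x (2*n_loci)`; failed loci are
#'   `NA`, dropout replicates show the remaining allele twice.
#' @export
apply_genotyping_errors <- function(true_genotype, em, n_replicates,
                                    allele_pool = NULL, seed = NULL) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!inherits(em, "error_model")) stop("em must be an error_model")
  if (!is.null(seed)) set.seed(seed)
  g <- as.integer(true_genotype)
  nm <- if (is.matrix(true_genotype)) colnames(true_genotype) else
    names(true_genotype)
  L <- length(g) / 2
  loci <- unique(sub("\\.[12]$", "", nm))
  out <- matrix(rep(g, each = n_replicates), n_replicates,
                dimnames = list(NULL, nm))
  for (l in seq_len(L)) {
    i1 <- 2 * l - 1; i2 <- 2 * l
    a <- g[i1]; b <- g[i2]
    pool <- if (!is.null(allele_pool)) allele_pool[[loci[l]]] else
      unique(c(a, b))
    for (r in seq_len(n_replicates)) {
      if (runif(1) < em$failure) { out[r, c(i1, i2)] <- NA_integer_; next }
      call <- c(a, b)
      if (a != b && runif(1) < em$dropout) {
        keep <- call[sample.int(2, 1)]
        call <- c(keep, keep)
      }
      if (runif(1) < em$false_allele) {
        src <- call[sample.int(2, 1)]
        shift <- src + sample(c(-2L, 2L), 1)
        spur <- if (shift %in% pool) shift else
          if (length(pool) > 1) sample(rep(setdiff(pool, src), 2), 1) else shift
        call[sample.int(2, 1)] <- spur
      }
      out[r, c(i1, i2)] <- sort(call)
    }
  }
  out
}

#' Generate replicate-call sheets for survey samples
#'
#' Looks up each sample's true individual, applies the genotyping error
#' model independently to every replicate, and emits the replicate-call
#' table used by the genotyping stage (one row per sample x replicate).
#'
#' @param survey Output of [simulate_survey()].
#' @param population The `true_population` the survey was drawn from.
#' @param em An [error_model()].
#' @param n_replicates Replicates amplified per sample (the consensus
#'   caller may consume fewer; extra rows emulate re-amplification).
#' @param seed Optional integer seed.
#' @return Data frame: sample_id, type, year, occasion, snare_id,
#'   replicate, then two columns per locus.
#' @export
genotype_samples <- function(survey, population, em, n_replicates = 4,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  smp <- survey$samples
  map <- survey$truth$sample_map
  geno <- population$genotypes
  pool <- lapply(population$freqs, function(p) as.integer(names(p)))
  pool$sex <- c(1L, 2L)
  rows <- vector("list", nrow(smp))
  for (i in seq_len(nrow(smp))) {
    ind <- map$individual[match(smp$sample_id[i], map$sample_id)]
    reps <- apply_genotyping_errors(geno[ind, ], em, n_replicates,
                                    allele_pool = pool)
    rows[[i]] <- data.frame(smp[i, , drop = FALSE],
                            replicate = seq_len(n_replicates), reps,
                            row.names = NULL, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
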