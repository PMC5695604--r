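# Shared fixtures: tiny genotype builders, a Wright-Fisher forward
# simulator, and the matching-error tally used by the identification
# checks.

# genotype matrix from a list of allele pairs at one locus
geno1 <- function(pairs, locus = "L01") {
  m <- do.call(rbind, lapply(pairs, function(p) sort(p)))
  colnames(m) <- paste0(locus, ".", 1:2)
  storage.mode(m) <- "integer"
  m
}

# n HWE genotypes from per-locus freq list (uses the package generator)
hwe_geno <- function(freqs, n) ngcmr:::draw_genotypes(freqs, n)

# equal-frequency locus
eqfreq <- function(k, locus_sizes = 100 + 2 * (0:(k - 1)))
  setNames(rep(1 / k, k), as.character(locus_sizes))

# forward Wright-Fisher population: ne diploids, shared parents across
# loci each generation (builds up genuine multi-locus LD at rate 1/2Ne)
wright_fisher <- function(ne, n_loci, generations = 30, n_alleles = 8,
                          seed = 1) {
  set.seed(seed)
  geno <- array(sample.int(n_alleles, ne * n_loci * 2, TRUE),
                c(ne, n_loci, 2))
  for (g in seq_len(generations)) {
    mom <- sample.int(ne, ne, TRUE)
    dad <- sample.int(ne, ne, TRUE)
    nxt <- array(0L, c(ne, n_loci, 2))
    for (l in seq_len(n_loci)) {
      nxt[, l, 1] <- geno[cbind(mom, l, sample.int(2, ne, TRUE))]
      nxt[, l, 2] <- geno[cbind(dad, l, sample.int(2, ne, TRUE))]
    }
    geno <- nxt
  }
  m <- do.call(cbind, lapply(seq_len(n_loci), function(l)
    cbind(pmin(geno[, l, 1], geno[, l, 2]),
          pmax(geno[, l, 1], geno[, l, 2]))))
  colnames(m) <- paste0(rep(sprintf("L%02d", seq_len(n_loci)), each = 2),
                        ".", 1:2)
  m
}

# over-splits and mis-merges of an individual_set against a truth map
matching_errors <- function(inds, sample_map) {
  members <- inds$members
  mis_merge <- sum(vapply(members, function(s)
    length(unique(sample_map$individual[match(s, sample_map$sample_id)])) > 1,
    logical(1)))
  assign <- rep(names(members), lengths(members))
  names(assign) <- unlist(members)
  by_ind <- split(assign[sample_map$sample_id], sample_map$individual)
  over_split <- sum(vapply(by_ind, function(x)
    length(unique(x[!is.na(x)])) > 1, logical(1)))
  c(mis_merge = mis_merge, over_split = over_split,
    n_true = length(by_ind))
}

# one simulated identification scenario: survey 50 individuals, apply
# errors, call consensus, match; returns error tally
run_identification <- function(n_ind = 50, e_d = 0.05, e_f = 0.01,
                               e_a = 0.05, n_reps = 3, n_loci = 8,
                               seed = 1) {
  af <- simulate_allele_frequencies(n_loci, 4, 0, 1, seed = seed)
  pop <- simulate_population(af[[1]], n_ind, seed = seed + 1)
  des <- survey_design(5, 5, occasions = 8, years = 1, seed = seed + 2)
  sv <- simulate_survey(pop, des, p0 = 0.3, sigma = 5, seed = seed + 3)
  em <- error_model(e_d, e_f, e_a)
  calls <- genotype_samples(sv, pop, em, n_replicates = n_reps,
                            seed = seed + 4)
  cs <- consensus_set(calls)
  fe <- allele_frequencies(list(all = cs$genotypes))$all
  pan <- pidsib_panel(fe)
  inds <- match_samples(cs, pan$table$locus, freqs = fe, em = em)
  matching_errors(inds, sv$truth$sample_map)
}
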