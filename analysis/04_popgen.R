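#!/usr/bin/env Rscript
# Stage 4: population-genetic summaries of the identified individuals:
# diversity (Ho, unbiased He, rarefied richness) with Kruskal-Wallis /
# Nemenyi comparison across scenarios, pairwise Gst / G''st with
# permutation tests, HWE and linkage-equilibrium screens, LD-Ne, and
# ML relatedness with a least-related subset for clustering runs.
# (The Evanno delta-K statistic consumes replicate log-likelihoods from
# an external clustering program and is therefore not exercised here;
# see the methods vignette.)
# Reads results/analysis/id/, writes results/analysis/popgen/.

library(ngcmr)

idd <- "results/analysis/id"
out <- "results/analysis/popgen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pops <- lapply(c(nal = "nal", mrb = "mrb"), function(p)
  read_genepop(file.path(idd, paste0(p, ".genepop.txt")),
               pop_names = "study")$study)
shared <- intersect(ngcmr:::geno_loci(pops$nal),
                    ngcmr:::geno_loci(pops$mrb))
cols <- as.vector(rbind(paste0(shared, ".1"), paste0(shared, ".2")))
pops <- lapply(pops, function(g) g[, cols])

div <- diversity_stats(pops)
write.csv(div$per_locus, file.path(out, "diversity_per_locus.csv"),
          row.names = FALSE)
write.csv(div$summary, file.path(out, "diversity_summary.csv"),
          row.names = FALSE)
print(div$summary)

cmp <- compare_diversity(split(div$per_locus$He, div$per_locus$pop))
cat(sprintf("He comparison: Kruskal-Wallis H = %.2f, P = %.4f\n",
            cmp$H, cmp$p))
write.csv(as.data.frame(cmp$nemenyi), file.path(out, "nemenyi_He.csv"))

pd <- pairwise_differentiation(pops, n_perm = 999, seed = 441)
write.csv(pd$fst, file.path(out, "fst.csv"))
write.csv(pd$gst, file.path(out, "gst.csv"))
cat(sprintf("Fst(nal, mrb) = %.3f (P = %.3f); G''st = %.3f (P = %.3f)\n",
            pd$fst[1, 2], pd$p_fst[1, 2], pd$gst[1, 2], pd$p_gst[1, 2]))

hwe <- do.call(rbind, lapply(names(pops), function(p) {
  data.frame(pop = p, locus = shared,
             p_hwe = vapply(shared, function(l)
               tryCatch(hwe_test(pops[[p]], l, seed = 442),
                        error = function(e) NA_real_), numeric(1)))
}))
write.csv(hwe, file.path(out, "hwe.csv"), row.names = FALSE)
cat(sprintf("HWE: %d of %d locus tests significant at 0.05\n",
            sum(hwe$p_hwe <= 0.05, na.rm = TRUE), sum(!is.na(hwe$p_hwe))))

le <- do.call(rbind, lapply(names(pops), function(p) {
  prs <- combn(shared[1:min(6, length(shared))], 2)
  data.frame(pop = p, locus1 = prs[1, ], locus2 = prs[2, ],
             p_le = vapply(seq_len(ncol(prs)), function(q)
               tryCatch(ld_test(pops[[p]], prs[, q], n_perm = 199,
                                seed = 443 + q),
                        error = function(e) NA_real_), numeric(1)))
}))
write.csv(le, file.path(out, "linkage_equilibrium.csv"),
          row.names = FALSE)

for (p in names(pops)) {
  ne <- tryCatch(ne_ld(pops[[p]]), error = function(e) NULL)
  if (!is.null(ne))
    cat(sprintf("[%s] LD-Ne = %.1f (95%% CI %.1f-%.1f), S = %.1f\n",
                p, ne$Ne, ne$ci[1], ne$ci[2], ne$S))
}

fr <- allele_frequencies(pops["mrb"])$mrb
rel <- pairwise_relatedness(pops$mrb, fr,
                            subset_size = min(30, nrow(pops$mrb)))
write.csv(rel$pairs, file.path(out, "relatedness_mrb.csv"),
          row.names = FALSE)
writeLines(rel$subset, file.path(out, "least_related_subset.txt"))
cat(sprintf("mrb mean pairwise r = %.3f; least-related subset of %d written\n",
            mean(rel$pairs$r, na.rm = TRUE), length(rel$subset)))
cat("stage 4 complete -> ", out, "\n")
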