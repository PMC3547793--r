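#!/usr/bin/env Rscript
# Step 1: simulate the study population.
#
# Builds a desk-scale intermated-RIL population (105 RILs, five chromosomes,
# 2-cM marker grid) and an RPKM expression matrix with a fully known planted
# architecture: cis- and trans-eQTL, one trans-hotspot regulator with 50
# targets, paramutation-like genes, presence/absence genes of every type,
# CNV dosage genes and fragment/ancestral coupled pairs, plus a non-genic
# background vector for detection-threshold calibration.

suppressMessages({ library(rilexpr); library(jsonlite) })
seed <- 20260924
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_ibm_genotypes(chrom_lengths_cm = rep(100, 5),
                              marker_spacing_cm = 2, n_rils = 105,
                              seed = seed)
cat(sprintf("population: %d RILs x %d markers on %d chromosomes\n",
            ncol(sim$genotypes), nrow(sim$map), length(unique(sim$map$chrom))))
cat(sprintf("residual heterozygosity: %.3f%%; empirical map expansion: %.2fx\n",
            100 * mean(sim$genotypes == "H", na.rm = TRUE),
            map_expansion(sim$genotypes, sim$map)))

arch <- sim_architecture(
  n_cis = 40, cis_effect = seq(0.3, 1.5, length.out = 40),
  n_trans = 20, trans_effect = seq(0.4, 1.2, length.out = 20),
  hotspot_targets = 50, hotspot_effect = 0.8, hotspot_sign_prob = 0.75,
  n_paramutation = 8,
  pa_counts = c(I = 5, II = 5, IIIA = 5, IIIB = 5, mendelian_50 = 10),
  n_cnv = 6, n_fragment_pairs = 6)
se <- simulate_expression(sim$genotypes, sim$map, arch, n_genes = 400,
                          seed = seed + 1)
cat(sprintf("expression: %d genes x %d samples; %d planted eQTL, %d hotspot targets\n",
            nrow(se$expr$values), ncol(se$expr$values),
            nrow(se$truth$eqtl), nrow(se$truth$hotspot$targets)))

bg <- simulate_nongenic_background(10000, seed = seed + 2)
cat(sprintf("background: %d non-genic fragments, %.0f%% zeros\n",
            length(bg), 100 * mean(bg == 0)))

write_expression(se$expr, file.path(out, "expression.tsv"),
                 file.path(out, "roles.tsv"))
write_genetics(sim$genotypes, sim$map, file.path(out, "genotypes.tsv"),
               file.path(out, "map.tsv"))
write_results(se$annotation, file.path(out, "annotation.tsv"))
write_results(data.frame(rpkm = bg), file.path(out, "background.tsv"))
write_json(se$truth[c("eqtl", "paramutation", "pa", "cnv", "fragment_pairs")],
           file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
write_json(list(hotspot = se$truth$hotspot), file.path(out, "truth_hotspot.json"),
           auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
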