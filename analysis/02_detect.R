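#!/usr/bin/env Rscript
# Step 2: detection thresholds and presence/absence calls.
#
# Calibrates RPKM cutoffs from the simulated non-genic background at the
# standard FDR grid, compares them with the published maize shoot-apex
# reference cutoffs, makes three-state presence calls at the FDR 0.01 cutoff
# and derives the detected / core expressed gene sets at FDR 0.05.

suppressMessages({ library(rilexpr); library(jsonlite) })
sim_dir <- "results/sim"; out <- "results/detect"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression(file.path(sim_dir, "expression.tsv"),
                        file.path(sim_dir, "roles.tsv"))
bg <- read_results(file.path(sim_dir, "background.tsv"))$rpkm

th <- calibrate_thresholds(bg)
ref <- reference_thresholds()
cat("calibrated cutoffs (this background):\n"); print(round(th$cutoffs, 3))
cat("published reference cutoffs:\n"); print(ref$cutoffs)

calls <- call_presence(expr, th$cutoffs[["0.01"]])
tab <- table(calls[, attr(calls, "roles") == "RIL"])
cat(sprintf("RIL calls at FDR 0.01: %.1f%% present, %.1f%% absent, %.1f%% ambiguous\n",
            100 * tab[["present"]] / sum(tab), 100 * tab[["absent"]] / sum(tab),
            100 * tab[["ambiguous"]] / sum(tab)))

sets <- expressed_gene_sets(expr, th)
cat(sprintf("detected genes (>=10%% RILs or a parent): %d; core genes (both parents, >=90%% RILs): %d\n",
            length(sets$detected_set), length(sets$core_set)))

df <- data.frame(gene = rownames(calls),
                 as.data.frame(unclass(calls), stringsAsFactors = FALSE),
                 check.names = FALSE)
write_results(df, file.path(out, "calls.tsv"))
write_json(list(calibrated = as.list(th$cutoffs), reference = as.list(ref$cutoffs)),
           file.path(out, "thresholds.json"), auto_unbox = TRUE, digits = NA)
write_json(sets, file.path(out, "gene_sets.json"), auto_unbox = FALSE)
cat("wrote", out, "\n")
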