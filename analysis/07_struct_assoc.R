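#!/usr/bin/env Rscript
# Step 7: structural variants, fragment coupling, and gene-set enrichments.
#
# Builds CGH-like segments around the planted CNV genes, relates all genes to
# those segments, filters genes eligible for CNV-expression association,
# tests the local-genotype dosage association, compares the cis-eQTL
# proportion of CNV genes with all mapped genes, correlates transposed
# fragments with their ancestral genes, and runs gene-set permutation tests
# on exon counts and family sizes of the unexpected-pattern genes.

suppressMessages({ library(rilexpr); library(jsonlite) })
seed <- 20261003
sim_dir <- "results/sim"; out <- "results/struct"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression(file.path(sim_dir, "expression.tsv"),
                        file.path(sim_dir, "roles.tsv"))
gen <- read_genetics(file.path(sim_dir, "genotypes.tsv"),
                     file.path(sim_dir, "map.tsv"))
ann_df <- read_results(file.path(sim_dir, "annotation.tsv"))
annot <- gene_annotation(ann_df$gene, ann_df$chrom, ann_df$start, ann_df$end,
                         ann_df$strand, ann_df$exon_count, ann_df$syntenic,
                         ann_df$family_size)
truth <- read_json(file.path(sim_dir, "truth.json"), simplifyVector = TRUE)
eq <- read_results("results/eqtl/eqtl.tsv")

# CGH-like segments: one copy-gain segment around each planted CNV gene
cnv_ann <- annot[annot$gene %in% truth$cnv$gene, ]
segments <- data.frame(chrom = cnv_ann$chrom,
                       start = pmax(1, cnv_ann$start - 20e3),
                       end = cnv_ann$end + 20e3, cgh_class = "B>M_CNV")
class(segments) <- c("cnv_segments", "data.frame")
rel <- relate_genes_segments(annot[annot$gene %in% rownames(expr$values), ],
                             segments)
cat("gene/segment relations:\n"); print(table(rel$relation))

elig <- cnv_expression_filter(expr, cnv_ann, gen$genotypes, gen$map)
cat(sprintf("CNV genes eligible for association: %d/%d\n",
            sum(elig$eligible), nrow(elig)))
assoc <- lapply(elig$gene[elig$eligible], function(g) {
  mk <- truth$cnv$marker[truth$cnv$gene == g]
  res <- genotype_expression_association(ril_values(expr)[g, ],
                                         unclass(gen$genotypes)[mk, ])
  data.frame(gene = g, direction = res$direction, t = res$t, p = res$p)
})
assoc <- do.call(rbind, assoc)
if (!is.null(assoc)) {
  cat(sprintf("dosage association: %d/%d positive direction, median p %.2e\n",
              sum(assoc$direction == "positive"), nrow(assoc),
              median(assoc$p)))
  write_results(assoc, file.path(out, "cnv_assoc.tsv"))
}

# cis-eQTL enrichment of CNV genes vs all mapped genes
cis_of <- function(genes) {
  sub <- eq[eq$trait %in% genes, ]
  c(cis = sum(sub$reg_type == "cis"), tot = nrow(sub))
}
cnv_counts <- cis_of(truth$cnv$gene)
all_counts <- c(cis = sum(eq$reg_type == "cis"), tot = nrow(eq))
enr <- cis_enrichment_test(cnv_counts["cis"], cnv_counts["tot"],
                           all_counts["cis"], all_counts["tot"])
cat(sprintf("cis proportion: CNV genes %d/%d vs all %d/%d; %s p = %.3g\n",
            cnv_counts["cis"], cnv_counts["tot"], all_counts["cis"],
            all_counts["tot"], enr$method, enr$p))

# fragment / ancestral coupling
fp <- fragment_ancestral_correlation(truth$fragment_pairs, expr, annot)
cat(sprintf("fragment pairs: %d tested, %d significant, %d negative coupling\n",
            nrow(fp), sum(fp$significant),
            sum(fp$coupling == "negative" & fp$significant)))
write_results(fp, file.path(out, "fragment_pairs.tsv"))

# gene-set permutation tests on the unexpected-pattern (inserted) genes
uep <- truth$pa$gene
features_exon <- data.frame(gene = annot$gene, value = annot$exon_count)
exon_test <- geneset_permutation_test(uep, features_exon, "mean",
                                      n_perm = 10000, alternative = "less",
                                      seed = seed)
features_fam <- data.frame(gene = annot$gene, value = annot$family_size)
fam_test <- geneset_permutation_test(uep, features_fam, "mean",
                                     n_perm = 10000, alternative = "less",
                                     seed = seed + 1)
cat(sprintf("unexpected-pattern genes: mean exon count %.2f vs %.2f genome-wide (p = %.4f)\n",
            exon_test$observed, exon_test$null_mean, exon_test$p))
cat(sprintf("mean family size %.2f vs %.2f genome-wide (p = %.4f)\n",
            fam_test$observed, fam_test$null_mean, fam_test$p))
write_json(list(cis_enrichment = enr,
                exon_deficit = exon_test, family_deficit = fam_test),
           file.path(out, "enrichment.json"), auto_unbox = TRUE, digits = NA)
write_results(rel, file.path(out, "relations.tsv"))
cat("wrote", out, "\n")
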