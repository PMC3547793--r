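seg_fix <- data.frame(chrom = "chr1",
                      start = c(50, 1000, 2000, 5000),
                      end = c(500, 1500, 2600, 6000),
                      cgh_class = c("B>M_PAV", "B>M_CNV", "M>B_CNV", "B=M"))
class(seg_fix) <- c("cnv_segments", "data.frame")

test_that("gene/segment relations follow the containment rules", {
  ann <- gene_annotation(c("in", "span", "part", "plain", "nonfocal"),
                         "chr1",
                         start = c(100, 1200, 400, 3000, 5100),
                         end = c(200, 2300, 700, 3500, 5200))
  rel <- relate_genes_segments(ann, seg_fix)
  expect_identical(rel$relation[rel$gene == "in"], "entirely_within")
  expect_identical(rel$relation[rel$gene == "span"], "multiple_segments")
  expect_identical(rel$relation[rel$gene == "part"], "intersecting")
  expect_identical(rel$relation[rel$gene == "plain"], "other")
  # B=M is not a focal class
  expect_identical(rel$relation[rel$gene == "nonfocal"], "other")
})

test_that("random gene/segment fixtures match a brute-force overlap oracle", {
  set.seed(171)
  seg_start <- sort(sample(seq(1, 1e5, by = 500), 20))
  segs <- data.frame(chrom = "chr1", start = seg_start,
                     end = seg_start + sample(200:1500, 20, TRUE),
                     cgh_class = "B>M_CNV")
  class(segs) <- c("cnv_segments", "data.frame")
  gene_start <- sample(seq(1, 1e5, by = 97), 50)
  ann <- gene_annotation(sprintf("g%02d", 1:50), "chr1",
                         start = gene_start,
                         end = gene_start + sample(100:2000, 50, TRUE))
  rel <- relate_genes_segments(ann, segs)
  for (i in seq_len(nrow(ann))) {
    ov <- which(segs$start <= ann$end[i] & segs$end >= ann$start[i])
    manual <- if (length(ov) == 0) "other"
    else if (length(ov) >= 2) "multiple_segments"
    else if (ann$start[i] >= segs$start[ov] && ann$end[i] <= segs$end[ov])
      "entirely_within" else "intersecting"
    expect_identical(rel$relation[i], manual)
  }
})

make_cnv_expr <- function(n_ril = 105, seed = 181) {
  sim <- simulate_ibm_genotypes(c(60), 5, n_ril, seed = seed)
  arch <- sim_architecture(n_cis = 0, n_trans = 0, n_cnv = 2,
                           cnv_multiplier = 2, noise_sd = 0.05,
                           base_log2_mean = 5, base_log2_sd = 0)
  se <- simulate_expression(sim$genotypes, sim$map, arch, n_genes = 6,
                            seed = seed + 1)
  list(sim = sim, se = se)
}

test_that("CNV eligibility filter applies both stated criteria", {
  w <- make_cnv_expr()
  ann <- w$se$annotation[w$se$annotation$gene %in% rownames(w$se$expr$values), ]
  elig <- cnv_expression_filter(w$se$expr, ann, w$sim$genotypes, w$sim$map)
  # constitutively expressed simulated genes pass both filters
  expect_true(all(elig$eligible[elig$gene %in% w$se$truth$cnv$gene]))
  # a gene expressed in under 40% of samples is excluded
  x <- w$se$expr
  gidx <- which(rownames(x$values) == w$se$truth$cnv$gene[1])
  x$values[gidx, seq_len(ceiling(ncol(x$values) * 0.65))] <- 0
  elig2 <- cnv_expression_filter(x, ann, w$sim$genotypes, w$sim$map)
  expect_false(elig2$eligible[elig2$gene == w$se$truth$cnv$gene[1]])
  expect_identical(elig2$reason[elig2$gene == w$se$truth$cnv$gene[1]],
                   "low-expressed-fraction")
})

test_that("genotype-expression association matches a closed-form t-test", {
  w <- make_cnv_expr()
  g1 <- w$se$truth$cnv$gene[1]
  mk <- w$se$truth$cnv$marker[1]
  vals <- ril_values(w$se$expr)[g1, ]
  cls <- unclass(w$sim$genotypes)[mk, ]
  res <- genotype_expression_association(vals, cls)
  expect_identical(res$direction, "positive")   # B73 carries the gain
  expect_lt(res$p, 1e-10)
  # formula oracle on a random fixture
  set.seed(191)
  v2 <- rexp(80); cl2 <- rep(c("A", "B"), 40)
  r2 <- genotype_expression_association(v2, cl2)
  o <- t.test(log2(v2[cl2 == "A"] + 1), log2(v2[cl2 == "B"] + 1))
  expect_equal(r2$p, o$p.value)
  expect_equal(r2$t, unname(o$statistic))
  expect_error(genotype_expression_association(v2, rep("A", 80)),
               class = "rilexpr_degenerate")
})

test_that("cis-enrichment test distinguishes printed-scale proportions", {
  same <- cis_enrichment_test(50, 100, 500, 1000)
  expect_gt(same$p, 0.95)
  big <- cis_enrichment_test(704, 1009, 7142, 19304)  # 70% vs 37%
  expect_lt(big$p, 1e-10)
  small <- cis_enrichment_test(3, 5, 10, 100)
  expect_identical(small$method, "fisher")
  expect_equal(small$p, fisher.test(rbind(c(3, 2), c(10, 90)))$p.value)
  expect_error(cis_enrichment_test(0, 0, 1, 10), class = "rilexpr_empty")
})

test_that("fragment/ancestral correlation: exact anchors and planted recovery", {
  n <- 60
  set.seed(201)
  anc <- 10 - seq_len(n) / 10
  frag <- 12 - anc                      # perfect complement
  vals <- rbind(frag = frag, anc = anc, noise = rexp(n))
  colnames(vals) <- paste0("R", seq_len(n))
  vals <- cbind(B73 = c(1, 2, 3), Mo17 = c(2, 1, 3), vals)
  rownames(vals) <- c("frag", "anc", "noise")
  roles <- setNames(c("B73_parent", "Mo17_parent", rep("RIL", n)),
                    colnames(vals))
  x <- expression_matrix(abs(vals), roles)
  out <- fragment_ancestral_correlation(
    data.frame(fragment = "frag", ancestral = "anc"), x)
  expect_equal(out$r, -1)
  expect_identical(out$coupling, "negative")
  # r(x, a x + b) has exactly the sign of a
  out2 <- fragment_ancestral_correlation(
    data.frame(fragment = "anc", ancestral = "anc"), x)
  expect_equal(out2$r, 1)

  # independent noise stays non-significant in most seeded draws
  set.seed(202)
  sig <- vapply(1:40, function(i) {
    v <- matrix(rexp(2 * n), 2, dimnames = list(c("a", "b"), paste0("R", 1:n)))
    v <- cbind(B73 = c(1, 1), Mo17 = c(2, 2), v)
    xx <- expression_matrix(v, setNames(c("B73_parent", "Mo17_parent",
                                          rep("RIL", n)), colnames(v)))
    fragment_ancestral_correlation(data.frame(fragment = "a", ancestral = "b"),
                                   xx, alpha = 0.05)$significant
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("planted negatively coupled pairs are recovered with high sensitivity", {
  hits <- 0; total <- 0
  for (s in 1:50) {
    sim <- simulate_ibm_genotypes(c(60, 60), 10, 105, seed = 2000 + s)
    arch <- sim_architecture(n_cis = 0, n_trans = 0, n_fragment_pairs = 2)
    se <- simulate_expression(sim$genotypes, sim$map, arch, n_genes = 8,
                              seed = 2100 + s)
    out <- fragment_ancestral_correlation(se$truth$fragment_pairs, se$expr,
                                          se$annotation)
    total <- total + nrow(se$truth$fragment_pairs)
    hits <- hits + sum(out$significant & out$coupling == "negative")
  }
  expect_gte(hits / total, 0.9)
})

test_that("gene-set permutation test: bounds, degenerate case, planted signal", {
  universe <- data.frame(gene = sprintf("g%03d", 1:300),
                         value = c(rep(TRUE, 30), rep(FALSE, 270)))
  # focal set = whole universe is degenerate: p = 1
  full <- geneset_permutation_test(universe$gene, universe,
                                   statistic = "proportion", n_perm = 200,
                                   seed = 1)
  expect_equal(full$p, 1)
  expect_error(geneset_permutation_test(c(universe$gene, "zzz"), universe),
               class = "rilexpr_size")
  # 10x enrichment of the flag
  focal <- universe$gene[1:25]   # 100% flagged vs 10% baseline
  enr <- geneset_permutation_test(focal, universe, statistic = "proportion",
                                  n_perm = 10000, alternative = "greater",
                                  seed = 2)
  expect_lte(enr$p, 0.001)
  expect_gte(enr$p, 1 / 10001)   # add-one lower bound
  # exon-count deficit, mean statistic
  set.seed(3)
  exo <- data.frame(gene = sprintf("e%03d", 1:500),
                    value = c(rpois(60, 3.2), rpois(440, 4.9)) + 1)
  def <- geneset_permutation_test(exo$gene[1:60], exo, statistic = "mean",
                                  n_perm = 5000, alternative = "less",
                                  seed = 4)
  expect_lt(def$p, 0.01)
})
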