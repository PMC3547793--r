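test_that("LRT to LOD conversion is linear with the right anchors", {
  expect_equal(lrt_to_lod(0), 0)
  expect_equal(lrt_to_lod(2 * log(10)), 1.0)
  expect_equal(lrt_to_lod(c(1, 2, 4)), c(1, 2, 4) / (2 * log(10)))
  expect_error(lrt_to_lod(-1), class = "rilexpr_domain")
})

test_that("noise-free planted QTL is recovered exactly at its marker", {
  sim <- simulate_ibm_genotypes(c(80), 4, 80, seed = 81)
  arch <- sim_architecture(n_cis = 1, cis_effect = 0.7, n_trans = 0,
                           noise_sd = 0, base_log2_mean = 6, base_log2_sd = 0)
  se <- simulate_expression(sim$genotypes, sim$map, arch, n_genes = 3, seed = 82)
  tg <- se$truth$eqtl$gene[1]
  y <- log2(ril_values(se$expr)[tg, ])
  prof <- cim_scan(y, sim$genotypes, sim$map)
  pk <- which.max(prof$lod)
  expect_equal(prof$cm[pk], se$truth$eqtl$cm[1])
  expect_equal(abs(prof$additive[pk]), 0.7, tolerance = 1e-6)
  expect_true(all(prof$lod >= 0))
})

test_that("stepwise cofactor selection finds planted markers and stays quiet under the null", {
  sim <- small_population(seed = 91, chroms = c(80, 80), n_rils = 105)
  g <- sim$genotypes; map <- sim$map
  x <- geno_numeric(unclass(g))
  # deterministic single-marker trait: that marker is selected first
  mk <- map$marker[10]
  y0 <- x[10, ]; y0[is.na(y0)] <- 0
  expect_identical(select_cofactors(y0, g, map)[1], mk)
  # two additive planted markers beat all null markers in most seeded runs
  m2 <- c(12, 60)
  near_planted <- function(sel_mk, true_idx) {
    i <- match(sel_mk, map$marker)
    any(map$chrom[i] == map$chrom[true_idx] &
          abs(map$cm[i] - map$cm[true_idx]) <= 10)
  }
  hit <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    y <- colSums(x[m2, ] * 0.9, na.rm = TRUE) + rnorm(ncol(g), 0, 1)
    sel <- select_cofactors(y, g, map, max_cofactors = 2)
    both_found <- all(vapply(m2, function(t)
      any(vapply(sel, near_planted, logical(1), true_idx = t)), logical(1)))
    no_null <- all(vapply(sel, function(mk)
      any(vapply(m2, function(t) near_planted(mk, t), logical(1))), logical(1)))
    if (both_found && no_null) hit <- hit + 1
  }
  expect_gte(hit / 20, 0.95)
  # pure-noise traits pick at most an occasional cofactor
  set.seed(77)
  n_cof <- vapply(1:20, function(i)
    length(select_cofactors(rnorm(ncol(g)), g, map)), numeric(1))
  expect_lte(mean(n_cof), 1)
  expect_error(select_cofactors(rep(1, ncol(g)), g, map),
               class = "rilexpr_degenerate")
})

test_that("peak calling, support intervals and merging follow the rules", {
  # flat profile below threshold -> nothing
  flat <- data.frame(chrom = "chr1", cm = 0:50, bp = (0:50) * 1e6 + 1,
                     lrt = 0, lod = 1, additive = 0, r2 = 0)
  expect_equal(nrow(call_eqtl(flat, 4)), 0)

  # two sharp triangular peaks: 8 cM apart merge, 15 cM apart stay separate
  tri <- function(center, height, cm) pmax(0, height - abs(cm - center) * 2)
  mk_prof <- function(centers) {
    cm <- 0:60
    lod <- pmax(tri(centers[1], 8, cm), tri(centers[2], 8, cm))
    data.frame(chrom = "chr1", cm = cm, bp = cm * 1e6 + 1,
               lrt = lod * 2 * log(10), lod = lod, additive = 1, r2 = 0.2)
  }
  expect_equal(nrow(call_eqtl(mk_prof(c(20, 28)), 4)), 1)
  expect_equal(nrow(call_eqtl(mk_prof(c(20, 35)), 4)), 2)

  # support interval bounds equal the brute-force crossing scan
  set.seed(55)
  lod <- pmax(0, 6 - abs(0:80 - 33) * 0.35) + runif(81, 0, 0.1)
  prof <- data.frame(chrom = "chr1", cm = 0:80, bp = (0:80) * 1e6 + 1,
                     lrt = lod * 2 * log(10), lod = lod, additive = 1, r2 = 0.2)
  rec <- call_eqtl(prof, 4)
  pk <- which.max(lod)
  expect_equal(rec$peak_cm, prof$cm[pk])
  oracle <- oracle_support(lod, pk, 1)
  expect_equal(rec$ci_lo_cm, prof$cm[oracle[1]])
  expect_equal(rec$ci_hi_cm, prof$cm[oracle[2]])
  expect_true(rec$ci_lo_cm <= rec$peak_cm && rec$peak_cm <= rec$ci_hi_cm)

  # merging is idempotent
  again <- call_eqtl(prof, 4)
  expect_identical(rec, again)
})

test_that("cis/trans classification uses the support interval plus margin", {
  rec <- data.frame(chrom = "chr1", peak_cm = 30, peak_bp = 30e6, lod = 6,
                    lrt = 27, additive = 1, r2 = 0.3,
                    ci_lo_cm = 25, ci_hi_cm = 35,
                    ci_lo_bp = 25e6, ci_hi_bp = 35e6)
  gene_at <- function(chrom, mid) data.frame(gene = "g", chrom = chrom,
                                             start = mid - 500, end = mid + 500)
  expect_identical(classify_cis_trans(rec, gene_at("chr1", 30e6)), "cis")
  expect_identical(classify_cis_trans(rec, gene_at("chr2", 30e6)), "trans")
  expect_identical(classify_cis_trans(rec, gene_at("chr1", 35.5e6)), "cis")   # 0.5 Mb out
  expect_identical(classify_cis_trans(rec, gene_at("chr1", 36.5e6)), "trans") # 1.5 Mb out
  expect_warning(out <- classify_cis_trans(rec, NULL))
  expect_true(is.na(out))
})

test_that("permutation threshold: quantile edge and Monte-Carlo stability", {
  sim <- simulate_ibm_genotypes(c(60, 60), 4, 60, seed = 121)
  set.seed(122)
  Y <- matrix(rnorm(20 * 60), 20, 60)
  pt_min <- permutation_threshold(Y, sim$genotypes, sim$map, n_traits = 3,
                                  n_perm = 100, alpha = 1, seed = 1)
  expect_equal(pt_min$lrt_threshold, min(pt_min$null_max))
  t1 <- permutation_threshold(Y, sim$genotypes, sim$map, n_traits = 10,
                              n_perm = 200, seed = 10)$lod_threshold
  t2 <- permutation_threshold(Y, sim$genotypes, sim$map, n_traits = 10,
                              n_perm = 200, seed = 20)$lod_threshold
  expect_lt(abs(t1 - t2) / t1, 0.05)
})

test_that("planted r2 is recovered and grows toward truth with n", {
  arch <- sim_architecture(n_cis = 1, cis_effect = sqrt(0.4 / 0.6),
                           n_trans = 0, noise_sd = log(2),
                           base_log2_mean = 6, base_log2_sd = 0)
  r2_at_n <- function(n, seed) {
    sim <- simulate_ibm_genotypes(c(80), 4, n, seed = seed)
    se <- simulate_expression(sim$genotypes, sim$map, arch, n_genes = 2,
                              seed = seed + 1)
    tg <- se$truth$eqtl$gene[1]
    y <- log2(pmax(ril_values(se$expr)[tg, ], 0.05))
    prof <- cim_scan(y, sim$genotypes, sim$map)
    max(prof$r2)
  }
  set.seed(131)
  r2_big <- mean(vapply(1:8, function(i) r2_at_n(400, 1300 + i), numeric(1)))
  expect_lt(abs(r2_big - 0.4), 0.06)
})
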