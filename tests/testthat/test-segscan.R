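test_that("segregation chi-square matches expectation and a tail oracle", {
  for (k in c(1, 10, 50)) expect_equal(segregation_chisq(k, k), 1.0)
  expect_equal(segregation_chisq(25, 75, c(1, 3)), 1.0)
  expect_error(segregation_chisq(0, 0), class = "rilexpr_empty")
  # closed-form oracle: the chi-square(1) upper tail is 2 * Phi(-sqrt(x))
  stat <- (28 - 52.5)^2 / 52.5 + (77 - 52.5)^2 / 52.5
  expect_equal(segregation_chisq(28, 77), 2 * pnorm(-sqrt(stat)),
               tolerance = 1e-12)
})

test_that("presence-pattern classification follows the stated rules", {
  mk <- function(np, na, namb = 0)
    c(rep("present", np), rep("absent", na), rep("ambiguous", namb))
  both <- c(B73 = "present", Mo17 = "present")
  neither <- c(B73 = "absent", Mo17 = "absent")
  b_only <- c(B73 = "present", Mo17 = "absent")

  expect_identical(classify_presence_pattern(both, mk(85, 15))$seg_class, "I")
  expect_identical(classify_presence_pattern(both, mk(95, 5))$seg_class, "none")
  expect_identical(classify_presence_pattern(neither, mk(15, 85))$seg_class, "II")
  expect_identical(classify_presence_pattern(neither, mk(5, 95))$seg_class, "none")
  r <- classify_presence_pattern(b_only, mk(52, 53))
  expect_identical(r$seg_class, "mendelian_50")
  expect_identical(classify_presence_pattern(b_only, mk(20, 85))$seg_class, "IIIA")
  expect_identical(classify_presence_pattern(b_only, mk(85, 20))$seg_class, "IIIB")
  expect_warning(out <- classify_presence_pattern(
    c(B73 = "ambiguous", Mo17 = "present"), mk(50, 50)))
  expect_null(out)
  # counts add up with ambiguous calls excluded from the test
  r2 <- classify_presence_pattern(b_only, mk(40, 40, 25))
  expect_equal(r2$n_present + r2$n_absent + r2$n_ambiguous, 105)
  expect_equal(r2$p_1to1, segregation_chisq(40, 40))
})

test_that("classification is exhaustive and exclusive over random inputs", {
  set.seed(88)
  for (i in 1:50) {
    pat <- sample(c("present", "absent"), 2, replace = TRUE)
    calls <- sample(c("present", "absent", "ambiguous"), 105, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
    r <- classify_presence_pattern(c(B73 = pat[1], Mo17 = pat[2]), calls)
    expect_true(r$seg_class %in% c("I", "II", "IIIA", "IIIB", "mendelian_50",
                                   "none"))
    expect_length(r$seg_class, 1)
  }
})

test_that("ratio candidates pick the quarter and three-quarter genes", {
  types <- rbind(
    cbind(data.frame(gene = "q1"),
          classify_presence_pattern(c(B73 = "absent", Mo17 = "absent"),
                                    c(rep("present", 26), rep("absent", 78)))),
    cbind(data.frame(gene = "h1"),
          classify_presence_pattern(c(B73 = "present", Mo17 = "absent"),
                                    c(rep("present", 52), rep("absent", 52)))))
  rc <- ratio_candidates(types)
  expect_identical(rc$quarter_set, "q1")
  expect_length(rc$three_quarter_set, 0)
})

test_that("block collapsing equals a brute-force distinct-run count", {
  map <- genetic_map(paste0("m", 1:6), rep(c("chr1", "chr2"), each = 3),
                     rep(c(0, 5, 10), 2), rep(c(1, 5e6, 10e6), 2))
  calls <- rbind(c("A", "B", "A"), c("A", "B", "A"), c("B", "B", "A"),
                 c("A", "A", "B"), c("A", "A", "B"), c("A", "A", "B"))
  dimnames(calls) <- list(map$marker, c("R1", "R2", "R3"))
  g <- genotype_matrix(calls, map)
  cb <- collapse_blocks(g, map)
  expect_equal(cb$n_blocks, 3)   # chr1: {m1,m2},{m3}; chr2: {m4,m5,m6}
  expect_identical(cb$representatives, c("m1", "m3", "m4"))
  # all-distinct markers give one block each
  set.seed(5)
  calls2 <- matrix(sample(c("A", "B"), 6 * 40, TRUE), 6, 40,
                   dimnames = list(map$marker, paste0("R", 1:40)))
  g2 <- genotype_matrix(calls2, map)
  manual <- 0
  key <- apply(calls2, 1, paste, collapse = "")
  for (i in 1:6) if (i == 1 || map$chrom[i] != map$chrom[i - 1] ||
                     key[i] != key[i - 1]) manual <- manual + 1
  expect_equal(collapse_blocks(g2, map)$n_blocks, manual)
})

test_that("epistasis scan: deterministic complementation, null calibration, symmetry", {
  sim <- small_population(seed = 141, chroms = c(60, 60), spacing = 10)
  g <- sim$genotypes; map <- sim$map
  x <- geno_numeric(unclass(g))
  blocks <- collapse_blocks(g, map)
  bid <- function(mk) blocks$block_id[match(mk, map$marker)]
  # perfect complementation: expressed only when AA at one locus, BB at other
  la <- 2; lb <- 10
  pres <- as.numeric(x[la, ] == -1 & x[lb, ] == 1)
  pres[is.na(pres)] <- 0
  ep <- epistasis_scan(pres, g, map)
  expect_true(ep$passes_alpha)
  expect_setequal(unname(c(bid(ep$marker_a), bid(ep$marker_b))),
                  unname(c(bid(map$marker[la]), bid(map$marker[lb]))))
  expect_equal(ep$alpha_adj, 0.05 / (ep$n_blocks * (ep$n_blocks - 1) / 2))

  # additive-only traits rarely show a significant interaction term
  set.seed(151)
  int_sig <- vapply(1:20, function(i) {
    y <- 0.8 * ifelse(is.na(x[3, ]), 0, x[3, ]) + rnorm(ncol(g))
    e <- epistasis_scan(y, g, map)
    e$interaction_p < e$alpha_adj
  }, logical(1))
  expect_gte(mean(!int_sig), 0.95)

  # family-wise error on pure-noise traits stays at or below alpha
  set.seed(161)
  fw <- vapply(1:30, function(i)
    epistasis_scan(rnorm(ncol(g)), g, map)$passes_alpha, logical(1))
  expect_lte(mean(fw), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))

  # scan result invariant to marker order
  rev_ord <- rev(seq_len(nrow(map)))
  map_r <- genetic_map(map$marker[rev_ord], map$chrom[rev_ord],
                       map$cm[rev_ord], map$bp[rev_ord])
  g_r <- genotype_matrix(unclass(g)[map_r$marker, ], map_r)
  ep_r <- epistasis_scan(pres, g_r, map_r)
  expect_equal(ep_r$model_p, ep$model_p)
  expect_setequal(c(ep_r$marker_a, ep_r$marker_b), c(ep$marker_a, ep$marker_b))
})

test_that("block-pair Bonferroni reproduces the printed threshold's order of magnitude", {
  B <- 218
  alpha_adj <- 0.05 / (B * (B - 1) / 2)
  expect_equal(alpha_adj, 0.05 / 23653)
  expect_lt(abs(log10(alpha_adj) - log10(2.1e-6)), 0.31)
})
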