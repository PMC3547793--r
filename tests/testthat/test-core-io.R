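test_that("expression TSV round-trips and rejects invariant violations", {
  dir <- withr::local_tempdir()
  vals <- matrix(round(runif(25, 0, 50), 3), 5, 5,
                 dimnames = list(paste0("g", 1:5), c("B73", "Mo17", paste0("RIL", 1:3))))
  roles <- setNames(c("B73_parent", "Mo17_parent", rep("RIL", 3)), colnames(vals))
  x <- expression_matrix(vals, roles)
  ep <- file.path(dir, "expr.tsv"); rp <- file.path(dir, "roles.tsv")
  write_expression(x, ep, rp)
  y <- read_expression(ep, rp)
  expect_equal(y$values, x$values, tolerance = 1e-9)
  expect_identical(y$roles, x$roles)

  # header + zero data rows -> zero genes
  writeLines("gene\tB73\tMo17\tRIL1\tRIL2\tRIL3", file.path(dir, "empty.tsv"))
  e0 <- read_expression(file.path(dir, "empty.tsv"), rp)
  expect_equal(nrow(e0$values), 0)

  # negative value -> format error
  bad <- vals; bad[1, 1] <- -1
  df <- data.frame(gene = rownames(bad), bad, check.names = FALSE)
  bp <- file.path(dir, "bad.tsv")
  write.table(df, bp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(bp, rp), class = "rilexpr_format")

  # missing parent role
  roles2 <- roles; roles2["Mo17"] <- "RIL"
  expect_error(expression_matrix(vals, roles2), class = "rilexpr_parents-missing")

  # ragged rows
  writeLines(c("gene\tB73\tMo17", "g1\t1\t2\t3"), file.path(dir, "ragged.tsv"))
  expect_error(read_expression(file.path(dir, "ragged.tsv"), rp),
               class = "rilexpr_format")
})

test_that("genetics reader validates codes, sorts by map, round-trips", {
  dir <- withr::local_tempdir()
  map <- genetic_map(c("m1", "m2", "m3"), "chr1", c(0, 10, 20), c(1, 2e6, 4e6))
  calls <- matrix(c("A", "B", "B", "B", NA, "A"), 3, 2,
                  dimnames = list(map$marker, c("RIL1", "RIL2")))
  g <- genotype_matrix(calls, map)
  gp <- file.path(dir, "geno.tsv"); mp <- file.path(dir, "map.tsv")
  write_genetics(g, map, gp, mp)
  back <- read_genetics(gp, mp)
  expect_equal(dim(back$genotypes), c(3, 2))
  expect_identical(unclass(back$genotypes)[, ], unclass(g)[, ])

  # unsorted map input comes back sorted by (chrom, cm)
  mp2 <- file.path(dir, "map2.tsv")
  write.table(data.frame(marker = c("m3", "m1", "m2"), chrom = "chr1",
                         cm = c(20, 0, 10), bp = c(4e6, 1, 2e6)),
              mp2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_genetics(gp, mp2)
  expect_identical(back2$map$marker, c("m1", "m2", "m3"))
  expect_true(!is.unsorted(back2$map$cm))

  # unknown code
  calls_bad <- calls; calls_bad[1, 1] <- "C"
  df <- data.frame(marker = rownames(calls_bad), calls_bad, check.names = FALSE)
  gpb <- file.path(dir, "genob.tsv")
  write.table(df, gpb, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genetics(gpb, mp), class = "rilexpr_format")

  # marker mismatch
  mp3 <- file.path(dir, "map3.tsv")
  write.table(data.frame(marker = c("m1", "m2", "mX"), chrom = "chr1",
                         cm = c(0, 10, 20), bp = c(1, 2e6, 4e6)),
              mp3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genetics(gp, mp3), class = "rilexpr_marker-mismatch")
})

test_that("GFF3 annotation: canonical-transcript exon counts and edge cases", {
  dir <- withr::local_tempdir()
  gff <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=geneA",
    "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=tA1;Parent=geneA",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=tA1",
    "chr1\tsrc\texon\t300\t400\t.\t+\t.\tParent=tA1",
    "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=tA2;Parent=geneA",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=tA2",
    "chr1\tsrc\texon\t300\t400\t.\t+\t.\tParent=tA2",
    "chr1\tsrc\texon\t500\t600\t.\t+\t.\tParent=tA2",
    "chr1\tsrc\texon\t700\t800\t.\t+\t.\tParent=tA2",
    "chr2\tsrc\tgene\t1000\t2000\t.\t-\t.\tID=geneB",
    "chr2\tsrc\tmRNA\t1000\t2000\t.\t-\t.\tID=tB1;Parent=geneB",
    "chr2\tsrc\texon\t1000\t1100\t.\t-\t.\tParent=tB1",
    "chr2\tsrc\texon\t1200\t1300\t.\t-\t.\tParent=tB1",
    "chr2\tsrc\texon\t1400\t2000\t.\t-\t.\tParent=tB1")
  p <- file.path(dir, "genes.gff3")
  writeLines(gff, p)
  ann <- read_annotation(p)
  expect_equal(ann$exon_count[ann$gene == "geneA"], 4L)  # max over transcripts
  expect_equal(ann$exon_count[ann$gene == "geneB"], 3L)
  expect_equal(ann$start[ann$gene == "geneA"], 100)      # 1-based inclusive

  # empty GFF3 -> 0 genes
  pe <- file.path(dir, "empty.gff3")
  writeLines("##gff-version 3", pe)
  expect_equal(nrow(read_annotation(pe)), 0)

  # end < start -> format error
  pb <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t900\t100\t.\t+\t.\tID=geneX"), pb)
  expect_error(read_annotation(pb), class = "rilexpr_format")
})

test_that("BED segments convert to 1-based inclusive and validate classes", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "seg.bed")
  writeLines(c("chr1\t0\t1000\tB>M_PAV", "chr1\t5000\t6000\tM>B_CNV"), p)
  seg <- read_segments(p)
  expect_equal(seg$start, c(1, 5001))
  expect_equal(seg$end, c(1000, 6000))
  writeLines("chr1\t0\t100\tnot_a_class", p)
  expect_error(read_segments(p), class = "rilexpr_format")
})

test_that("write_results keeps column order, handles empty tables, round-trips", {
  dir <- withr::local_tempdir()
  df <- data.frame(b = c(1.23456789012, 2), a = c("x", "y"), z = c(3L, 4L))
  p <- file.path(dir, "res.tsv")
  write_results(df, p)
  back <- read_results(p)
  expect_identical(names(back), c("b", "a", "z"))
  expect_equal(back$b, df$b, tolerance = 1e-9)
  # empty table -> header-only file
  write_results(df[0, ], p)
  expect_identical(readLines(p), "b\ta\tz")
  expect_error(write_results(NULL, p), class = "rilexpr_format")
  expect_error(write_results(df, file.path(dir, "no/such/dir/x.tsv")),
               class = "rilexpr_io")
})

test_that("genotype matrix rejects excess heterozygosity; config validates", {
  map <- genetic_map(c("m1", "m2"), "chr1", c(0, 10), c(1, 2e6))
  calls <- matrix("H", 2, 10, dimnames = list(map$marker, paste0("R", 1:10)))
  expect_error(genotype_matrix(calls, map), class = "rilexpr_format")
  expect_error(pipeline_config(detect_fraction = 1.5), class = "rilexpr_format")
  expect_error(pipeline_config(nonsense = 1), class = "rilexpr_format")
  cfg <- pipeline_config(merge_cm = 5)
  expect_equal(cfg$merge_cm, 5)
  expect_equal(cfg$density_cutoff, 1.25)
})
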