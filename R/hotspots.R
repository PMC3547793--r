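#' Count trans-eQTL peaks in 1-Mb windows
#'
#' Windows are non-overlapping half-open tiles `[k Mb, (k+1) Mb)` per
#' chromosome; every peak falls in exactly one window (a peak at exactly
#' 1,000,000 bp is counted in the `[1, 2)` Mb window).
#'
#' @param eqtls Data frame of trans-eQTL records with `chrom` and `peak_bp`.
#' @param genome Data frame with columns `chrom` and `length_bp`.
#' @param window_mb Window size in Mb (default 1).
#' @return Data frame: `chrom`, `start_mb`, `end_mb`, `n_trans`.
#' @export
window_counts <- function(eqtls, genome, window_mb = 1) {
  w <- window_mb * 1e6
  out <- lapply(seq_len(nrow(genome)), function(i) {
    cc <- genome$chrom[i]
    nw <- ceiling(genome$length_bp[i] / w)
    starts <- (seq_len(nw) - 1) * window_mb
    peaks <- eqtls$peak_bp[eqtls$chrom == cc]
    if (any(peaks > genome$length_bp[i]))
      ril_abort("coordinate", "eQTL peak beyond chromosome length")
    idx <- floor(peaks / w) + 1
    counts <- tabulate(idx, nbins = nw)
    data.frame(chrom = cc, start_mb = starts, end_mb = starts + window_mb,
               n_trans = counts)
  })
  do.call(rbind, out)
}

#' Permutation threshold for hotspot window counts
#'
#' Places `n_trans_total` peaks uniformly over the mapped genome in each
#' permutation and records the maximum window count; the threshold is the
#' `1 - alpha` empirical quantile of those maxima (the maximum number of
#' trans-eQTL expected to fall into any window at genome-wide level `alpha`).
#'
#' @param n_trans_total Total number of trans-eQTLs (`>= 1`).
#' @param genome Data frame with `chrom`, `length_bp`.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Genome-wide level (default 0.01).
#' @param window_mb Window size in Mb.
#' @param seed Optional RNG seed.
#' @return Integer count threshold.
#' @export
hotspot_threshold <- function(n_trans_total, genome, n_perm = 1000,
                              alpha = 0.01, window_mb = 1, seed = NULL) {
  if (n_trans_total < 1) ril_abort("format", "need at least one trans-eQTL")
  if (!is.null(seed)) set.seed(seed)
  w <- window_mb * 1e6
  nw_per <- ceiling(genome$length_bp / w)
  offsets <- c(0, cumsum(nw_per))[seq_len(nrow(genome))]
  total_bp <- sum(genome$length_bp)
  cum_bp <- c(0, cumsum(genome$length_bp))
  nbins <- sum(nw_per)
  maxima <- vapply(seq_len(n_perm), function(i) {
    pos <- stats::runif(n_trans_total, 0, total_bp)
    ci <- findInterval(pos, cum_bp, rightmost.closed = TRUE)
    within <- pos - cum_bp[ci]
    bins <- offsets[ci] + floor(within / w) + 1
    max(tabulate(bins, nbins = nbins))
  }, numeric(1))
  as.integer(stats::quantile(maxima, 1 - alpha, type = 1, names = FALSE))
}

#' Haplotype-bias test of hotspot targets
#'
#' Chi-square goodness-of-fit of the B73-up / Mo17-up target counts against a
#' 1:1 expectation (df = 1, no continuity correction); the p-value is the
#' upper tail.
#'
#' @param n_b73_up,n_mo17_up Counts of targets whose expression is raised by
#'   the B73 / Mo17 haplotype.
#' @return The p-value.
#' @export
haplotype_bias <- function(n_b73_up, n_mo17_up) {
  tot <- n_b73_up + n_mo17_up
  if (tot < 1) ril_abort("empty", "no targets to test")
  stat <- (n_b73_up - n_mo17_up)^2 / tot
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Call trans-eQTL hotspots
#'
#' Windows whose trans-eQTL count reaches the permutation threshold *and*
#' whose gene-density-corrected statistic
#' `n_trans / (window Mb x genes in window)` reaches `density_cutoff` are
#' significant; adjacent significant windows merge into one named hotspot.
#' Over each merged span the cis/trans counts, the haplotype-bias test (by
#' the sign of the additive effect: positive = Mo17 raises the target) and
#' the target list are recomputed. Windows without annotated genes are
#' excluded with a warning.
#'
#' @param counts Window counts from [window_counts()].
#' @param threshold Count threshold from [hotspot_threshold()].
#' @param eqtls Full eQTL record table (with `reg_type`, `additive`,
#'   `trait`).
#' @param annot A [gene_annotation()] (gene midpoints define window gene
#'   counts).
#' @param density_cutoff Density statistic cutoff (default 1.25).
#' @param window_mb Window size in Mb.
#' @return Data frame of hotspots: `name`, `chrom`, `start_mb`, `end_mb`,
#'   `n_cis`, `n_trans`, `density_stat`, `n_b73_up`, `n_mo17_up`, `bias_p`;
#'   the per-hotspot target gene lists are attached as the `targets`
#'   attribute.
#' @export
call_hotspots <- function(counts, threshold, eqtls, annot,
                          density_cutoff = 1.25, window_mb = 1) {
  mid <- (annot$start + annot$end) / 2
  genes_in <- function(cc, lo_mb, hi_mb)
    sum(annot$chrom == cc & mid >= lo_mb * 1e6 & mid < hi_mb * 1e6)
  n_genes <- mapply(genes_in, counts$chrom, counts$start_mb, counts$end_mb)
  dens <- counts$n_trans / ((counts$end_mb - counts$start_mb) * n_genes)
  empty_sig <- counts$n_trans >= threshold & n_genes == 0
  if (any(empty_sig))
    warning(sum(empty_sig), " window(s) above threshold had no annotated genes and were excluded")
  sig <- counts$n_trans >= threshold & n_genes > 0 & dens >= density_cutoff
  out <- data.frame(name = character(0), chrom = character(0),
                    start_mb = numeric(0), end_mb = numeric(0),
                    n_cis = integer(0), n_trans = integer(0),
                    density_stat = numeric(0), n_b73_up = integer(0),
                    n_mo17_up = integer(0), bias_p = numeric(0))
  targets <- list()
  if (!any(sig)) { attr(out, "targets") <- targets; return(out) }
  sw <- counts[sig, , drop = FALSE]
  sw <- sw[order(sw$chrom, sw$start_mb), , drop = FALSE]
  run <- cumsum(c(TRUE, !(sw$chrom[-1] == sw$chrom[-nrow(sw)] &
                            sw$start_mb[-1] == sw$end_mb[-nrow(sw)])))
  k <- 0
  trans <- eqtls[eqtls$reg_type %in% "trans", , drop = FALSE]
  cis <- eqtls[eqtls$reg_type %in% "cis", , drop = FALSE]
  rows <- list()
  for (g in unique(run)) {
    blk <- sw[run == g, , drop = FALSE]
    k <- k + 1
    cc <- blk$chrom[1]
    lo <- min(blk$start_mb); hi <- max(blk$end_mb)
    in_span <- function(df) df$chrom == cc & df$peak_bp >= lo * 1e6 &
      df$peak_bp < hi * 1e6
    tsub <- trans[in_span(trans), , drop = FALSE]
    n_tr <- nrow(tsub)
    n_ci <- sum(in_span(cis))
    ngen <- genes_in(cc, lo, hi)
    up_mo17 <- sum(tsub$additive > 0)
    up_b73 <- n_tr - up_mo17
    name <- sprintf("HS%02d", k)
    rows[[k]] <- data.frame(name = name, chrom = cc, start_mb = lo,
                            end_mb = hi, n_cis = n_ci, n_trans = n_tr,
                            density_stat = n_tr / ((hi - lo) * max(ngen, 1)),
                            n_b73_up = up_b73, n_mo17_up = up_mo17,
                            bias_p = if (n_tr >= 1)
                              haplotype_bias(up_b73, up_mo17) else NA_real_)
    targets[[name]] <- unique(tsub$trait)
  }
  out <- do.call(rbind, rows)
  attr(out, "targets") <- targets
  out
}

#' Proportional expression changes of hotspot targets
#'
#' The additive effect of the Mo17 allele divided by the target gene's
#' population mean, sign preserved. Targets with zero population mean are
#' skipped with a warning.
#'
#' @param target_eqtls eQTL records of the hotspot's targets (with `trait`
#'   and `additive`).
#' @param pop_means Named vector of population mean expression per gene.
#' @return Named numeric vector of ratios.
#' @export
proportional_changes <- function(target_eqtls, pop_means) {
  pm <- pop_means[target_eqtls$trait]
  bad <- is.na(pm) | pm == 0
  if (any(bad)) {
    warning(sum(bad), " target(s) with zero population mean skipped")
  }
  stats::setNames(target_eqtls$additive[!bad] / pm[!bad],
                  target_eqtls$trait[!bad])
}
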