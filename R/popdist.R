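# --- two-component Gaussian mixture EM, vectorised across replicates -------
#
# Rows of X are independent samples. Each restart initialises component means
# at two random data points per row and runs a fixed number of EM iterations;
# the best restart by log-likelihood wins. Rows are standardised first (the
# bimodality score tau is location/scale invariant).
tau_em_matrix <- function(X, restarts = 10, iters = 60) {
  R <- nrow(X); n <- ncol(X)
  mu <- rowMeans(X); sdv <- sqrt(pmax(rowSums((X - mu)^2) / (n - 1), 1e-12))
  Z <- (X - mu) / sdv
  s_floor <- 1e-3
  best_ll <- rep(-Inf, R)
  best_tau <- rep(0, R)
  for (r in seq_len(restarts)) {
    j1 <- sample.int(n, R, replace = TRUE)
    j2 <- sample.int(n, R, replace = TRUE)
    mu1 <- Z[cbind(seq_len(R), j1)]
    mu2 <- Z[cbind(seq_len(R), j2)]
    bump <- abs(mu1 - mu2) < 1e-6
    mu2[bump] <- mu2[bump] + 0.5
    s1 <- rep(0.5, R); s2 <- rep(0.5, R); p <- rep(0.5, R)
    ll <- rep(-Inf, R); ll_old <- ll
    for (it in seq_len(iters)) {
      w1 <- p * stats::dnorm(Z, mu1, s1)
      w2 <- (1 - p) * stats::dnorm(Z, mu2, s2)
      tot <- w1 + w2
      tot[tot < 1e-300] <- 1e-300
      g <- w1 / tot
      n1 <- rowSums(g); n2 <- n - n1
      n1 <- pmax(n1, 1e-8); n2 <- pmax(n2, 1e-8)
      mu1 <- rowSums(g * Z) / n1
      mu2 <- rowSums((1 - g) * Z) / n2
      s1 <- pmax(sqrt(rowSums(g * (Z - mu1)^2) / n1), s_floor)
      s2 <- pmax(sqrt(rowSums((1 - g) * (Z - mu2)^2) / n2), s_floor)
      p <- pmin(pmax(n1 / n, 1e-6), 1 - 1e-6)
      ll <- rowSums(log(tot))
      if (it %% 5 == 0) {
        if (max(abs(ll - ll_old)) < 1e-7) break
        ll_old <- ll
      }
    }
    tau_r <- abs(mu1 - mu2) / (s1 + s2)
    upd <- ll > best_ll
    best_ll[upd] <- ll[upd]
    best_tau[upd] <- tau_r[upd]
  }
  best_tau
}

#' Bimodality score tau of a sample
#'
#' Fits a two-component Gaussian mixture by EM (with random restarts) and
#' returns `tau = |mu1 - mu2| / (sigma1 + sigma2)`, a location- and
#' scale-invariant separation score. Large tau indicates a bimodal
#' distribution.
#'
#' @param x Numeric vector (length >= 10, positive variance).
#' @param restarts Number of EM restarts (default 10).
#' @return The tau score (non-negative scalar).
#' @export
tau_statistic <- function(x, restarts = 10) {
  if (length(x) < 10) ril_abort("degenerate", "need at least 10 values")
  if (stats::sd(x) == 0) ril_abort("degenerate", "zero variance")
  tau_em_matrix(matrix(x, nrow = 1), restarts = restarts)
}

#' Calibrate the genome-wide tau threshold by simulation
#'
#' Draws `reps` standard-normal samples of size `n`, computes tau for each,
#' and returns the `1 - alpha` quantile: the tau value exceeded by a fraction
#' `alpha` of unimodal normal samples.
#'
#' @param n Sample size per replicate (default 105, the RIL population size).
#' @param reps Number of replicates (default 10000, >= 1000 recommended).
#' @param alpha Significance level (default 0.01).
#' @param restarts EM restarts per replicate.
#' @param seed Optional RNG seed.
#' @return The tau threshold (scalar).
#' @export
calibrate_tau_threshold <- function(n = 105, reps = 10000, alpha = 0.01,
                                    restarts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(reps * n), reps, n)
  taus <- tau_em_matrix(X, restarts = restarts)
  emp_quantile(taus, 1 - alpha)
}

#' Classify the RIL expression distribution of one gene
#'
#' Bimodal when tau reaches the calibrated threshold; otherwise normal when a
#' Lilliefors-corrected Kolmogorov-Smirnov test (parameters estimated from the
#' data) does not reject normality at `ks_alpha`; otherwise unclassified.
#' Precedence is bimodal > normal > unclassified.
#'
#' @param x Numeric vector of RIL expression values (length >= 10, positive
#'   variance).
#' @param tau_threshold Threshold from [calibrate_tau_threshold()].
#' @param ks_alpha Significance level of the normality test (default 0.05).
#' @param restarts EM restarts for the tau fit.
#' @return A list with `dist_class` (`"bimodal"`, `"normal"` or
#'   `"unclassified"`), `tau` and `ks_p`.
#' @export
classify_distribution <- function(x, tau_threshold, ks_alpha = 0.05,
                                  restarts = 10) {
  if (stats::sd(x) == 0) ril_abort("degenerate", "zero variance")
  tau <- tau_statistic(x, restarts = restarts)
  ks_p <- tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA_real_)
  cls <- if (tau >= tau_threshold) "bimodal"
  else if (!is.na(ks_p) && ks_p >= ks_alpha) "normal"
  else "unclassified"
  list(dist_class = cls, tau = tau, ks_p = ks_p)
}

#' Per-gene population summary
#'
#' Population mean, sample SD, coefficient of variation, mid-parent deviation
#' `log2(pop_mean / midparent)` and absolute parental log2 fold change
#' `|log2(B73/Mo17)|`. Parent-derived fields are `NA` unless both parents are
#' positive.
#'
#' @param ril_values Numeric vector of RIL RPKM values (length >= 10).
#' @param b73,mo17 Parental RPKM values.
#' @return A one-row data frame with fields `pop_mean`, `pop_sd`, `cv`,
#'   `midparent`, `midparent_dev`, `parental_lfc`.
#' @export
summarize_gene <- function(ril_values, b73, mo17) {
  if (length(ril_values) < 10) ril_abort("degenerate", "need at least 10 RIL values")
  m <- mean(ril_values); s <- stats::sd(ril_values)
  if (m == 0 && s == 0) ril_abort("degenerate", "all values are zero")
  ok <- b73 > 0 && mo17 > 0
  midp <- if (ok) (b73 + mo17) / 2 else NA_real_
  data.frame(pop_mean = m, pop_sd = s, cv = s / m,
             midparent = midp,
             midparent_dev = if (ok && m > 0) log2(m / midp) else NA_real_,
             parental_lfc = if (ok) abs(log2(b73 / mo17)) else NA_real_)
}

#' Transgressive segregation flag
#'
#' TRUE when at least a fraction `frac` of RILs lie strictly outside the
#' parental range.
#'
#' @param ril_values Numeric vector of RIL values (length >= 10).
#' @param b73,mo17 Parental values.
#' @param frac Required fraction (default 0.10).
#' @return Logical scalar.
#' @export
flag_transgressive <- function(ril_values, b73, mo17, frac = 0.10) {
  lo <- min(b73, mo17); hi <- max(b73, mo17)
  mean(ril_values < lo | ril_values > hi) >= frac
}

#' Detect a paramutation-like expression pattern
#'
#' A gene is eligible when the parents differ at least `fold_min`-fold (a
#' zero-expressed parent makes the gene eligible when the other parent reaches
#' the detection cutoff). The pattern fires when exactly one parent lies
#' within `near_sd` population SDs of the RIL mean while the other lies at
#' least `far_sd` SDs away: all RILs track one parent and the other parent is
#' an outlier.
#'
#' @param ril_values Numeric vector of RIL RPKM values.
#' @param b73,mo17 Parental RPKM values.
#' @param fold_min Minimum parental fold change (default 2).
#' @param near_sd,far_sd z-rules (defaults 2 and 3).
#' @param detect_cutoff RPKM cutoff used as fold baseline when one parent is
#'   zero (default 1.03).
#' @return A list: `z_b73`, `z_mo17`, `pattern` (`"none"`,
#'   `"ril_like_low_parent"`, `"ril_like_high_parent"`), `outlier_parent`.
#' @export
detect_paramutation_like <- function(ril_values, b73, mo17, fold_min = 2,
                                     near_sd = 2, far_sd = 3,
                                     detect_cutoff = 1.03) {
  s <- stats::sd(ril_values)
  if (s == 0) ril_abort("degenerate", "zero population SD")
  eligible <- if (b73 > 0 && mo17 > 0) {
    max(b73, mo17) / min(b73, mo17) >= fold_min
  } else {
    max(b73, mo17) >= detect_cutoff
  }
  m <- mean(ril_values)
  z_b73 <- (b73 - m) / s
  z_mo17 <- (mo17 - m) / s
  pattern <- "none"; outlier <- "none"
  if (eligible) {
    b_near <- abs(z_b73) <= near_sd; b_far <- abs(z_b73) >= far_sd
    m_near <- abs(z_mo17) <= near_sd; m_far <- abs(z_mo17) >= far_sd
    if (b_near && m_far) {
      outlier <- "Mo17"
      pattern <- if (b73 <= mo17) "ril_like_low_parent" else "ril_like_high_parent"
    } else if (m_near && b_far) {
      outlier <- "B73"
      pattern <- if (mo17 <= b73) "ril_like_low_parent" else "ril_like_high_parent"
    }
  }
  list(z_b73 = z_b73, z_mo17 = z_mo17, pattern = pattern,
       outlier_parent = outlier)
}

#' Dominance/additivity ratio of an F1
#'
#' `d = F1 - midparent`, `a = |B73 - Mo17| / 2`; `d/a` is 0 under additivity,
#' +1 at complete dominance of the high parent, -1 at complete dominance of
#' the low parent.
#'
#' @param f1,b73,mo17 Expression values; `b73 != mo17` required.
#' @return A list with `d`, `a`, `d_over_a`.
#' @export
dominance_ratio <- function(f1, b73, mo17) {
  if (b73 == mo17) ril_abort("undefined-ratio", "parents are equal; d/a undefined")
  d <- f1 - (b73 + mo17) / 2
  a <- abs(b73 - mo17) / 2
  list(d = d, a = a, d_over_a = d / a)
}

#' Population-distribution table for all genes
#'
#' Convenience wrapper running [summarize_gene()], [classify_distribution()],
#' [flag_transgressive()] and [detect_paramutation_like()] across the genes of
#' an expression matrix.
#'
#' @param expr An [expression_matrix()].
#' @param tau_threshold Calibrated tau threshold.
#' @param genes Optional subset of gene ids (default all genes).
#' @param config A [pipeline_config()] supplying the z-rules and fold change.
#' @param detect_cutoff RPKM baseline for zero-parent fold eligibility.
#' @return A data frame, one row per gene.
#' @export
popdist_table <- function(expr, tau_threshold, genes = NULL,
                          config = pipeline_config(), detect_cutoff = 1.03) {
  rv <- ril_values(expr)
  if (is.null(genes)) genes <- rownames(rv)
  b73 <- parent_values(expr, "B73")
  mo17 <- parent_values(expr, "Mo17")
  rows <- lapply(genes, function(g) {
    x <- rv[g, ]
    if (stats::sd(x) == 0) return(NULL)
    sm <- summarize_gene(x, b73[g], mo17[g])
    dc <- classify_distribution(x, tau_threshold)
    pm <- detect_paramutation_like(x, b73[g], mo17[g],
                                   fold_min = config$fold_change_min,
                                   near_sd = config$near_sd,
                                   far_sd = config$far_sd,
                                   detect_cutoff = detect_cutoff)
    cbind(data.frame(gene = g), sm,
          data.frame(tau = dc$tau, ks_p = dc$ks_p, dist_class = dc$dist_class,
                     transgressive = flag_transgressive(x, b73[g], mo17[g]),
                     z_b73 = pm$z_b73, z_mo17 = pm$z_mo17,
                     pattern = pm$pattern, outlier_parent = pm$outlier_parent))
  })
  do.call(rbind, rows)
}
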