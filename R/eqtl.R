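#' Convert a likelihood-ratio statistic to a LOD score
#'
#' `LOD = LRT / (2 ln 10)`; e.g. an LRT of 19.23 corresponds to LOD 4.17.
#'
#' @param lrt Likelihood-ratio test statistic (`>= 0`, vectorised).
#' @return LOD score(s).
#' @export
lrt_to_lod <- function(lrt) {
  if (any(lrt < 0)) ril_abort("domain", "LRT must be non-negative")
  lrt / (2 * log(10))
}

#' Scan grid over the genetic map
#'
#' Positions every `step_cm` cM along each chromosome (the walking speed),
#' with physical positions linearly interpolated from the map.
#'
#' @param map A [genetic_map()].
#' @param step_cm Grid step in cM (default 1).
#' @return Data frame with columns `chrom`, `cm`, `bp`.
#' @export
qtl_grid <- function(map, step_cm = 1) {
  out <- lapply(unique(map$chrom), function(cc) {
    sub <- map[map$chrom == cc, , drop = FALSE]
    cm <- seq(min(sub$cm), max(sub$cm), by = step_cm)
    if (cm[length(cm)] < max(sub$cm)) cm <- c(cm, max(sub$cm))
    bp <- if (nrow(sub) > 1)
      stats::approx(sub$cm, sub$bp, xout = cm, ties = "ordered")$y
    else rep(sub$bp, length(cm))
    data.frame(chrom = cc, cm = cm, bp = bp)
  })
  do.call(rbind, out)
}

# expected +/-1 genotype from flanking values and Haldane distances;
# single-flank fallback E[q|m] = m (1 - 2r); no information -> 0
.expect_flanks <- function(lval, ld, rval, rd) {
  n <- length(lval)
  out <- numeric(n)
  rL <- haldane(ld); rR <- haldane(rd)
  both <- !is.na(lval) & !is.na(rval)
  if (any(both)) {
    tlp <- ifelse(lval[both] == 1, 1 - rL[both], rL[both])
    tlm <- ifelse(lval[both] == -1, 1 - rL[both], rL[both])
    trp <- ifelse(rval[both] == 1, 1 - rR[both], rR[both])
    trm <- ifelse(rval[both] == -1, 1 - rR[both], rR[both])
    wp <- tlp * trp; wm <- tlm * trm
    out[both] <- (wp - wm) / (wp + wm)
  }
  lonly <- !is.na(lval) & is.na(rval)
  out[lonly] <- lval[lonly] * (1 - 2 * rL[lonly])
  ronly <- is.na(lval) & !is.na(rval)
  out[ronly] <- rval[ronly] * (1 - 2 * rR[ronly])
  out
}

#' Expected QTL genotypes on a grid
#'
#' For every grid position and RIL, the conditional expectation of the +/-1
#' genotype given the nearest informative flanking markers, using Haldane
#' recombination fractions. Heterozygous calls are treated as missing; a
#' missing flank falls back to the nearest informative marker on that side,
#' and a fully uninformative chromosome contributes 0.
#'
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @param grid Data frame from [qtl_grid()] (defaults to a 1-cM grid).
#' @return Numeric matrix, RILs x grid positions.
#' @export
genotype_expectation <- function(genotypes, map, grid = qtl_grid(map)) {
  g <- geno_numeric(genotypes)
  n <- ncol(g)
  Q <- matrix(0, n, nrow(grid))
  for (cc in unique(grid$chrom)) {
    mrows <- which(map$chrom == cc)
    grows <- which(grid$chrom == cc)
    if (length(mrows) == 0) next
    gm <- g[mrows, , drop = FALSE]
    cm <- map$cm[mrows]
    m <- length(mrows)
    # nearest informative marker index at/below and at/above each row, per RIL
    li <- matrix(NA_integer_, m, n); ri <- matrix(NA_integer_, m, n)
    for (i in seq_len(m)) {
      inf <- !is.na(gm[i, ])
      li[i, ] <- ifelse(inf, i, if (i > 1) li[i - 1, ] else NA_integer_)
    }
    for (i in rev(seq_len(m))) {
      inf <- !is.na(gm[i, ])
      ri[i, ] <- ifelse(inf, i, if (i < m) ri[i + 1, ] else NA_integer_)
    }
    cols <- seq_len(n)
    for (jj in grows) {
      p <- grid$cm[jj]
      k <- findInterval(p, cm)
      lidx <- if (k >= 1) li[k, ] else rep(NA_integer_, n)
      ridx <- if (k < m) ri[k + 1, ] else {
        # at/after the last marker: a marker exactly at p can serve as left
        rep(NA_integer_, n)
      }
      # a marker exactly at p is its own (zero-distance) flank
      lval <- ifelse(is.na(lidx), NA_real_, gm[cbind(lidx, cols)])
      rval <- ifelse(is.na(ridx), NA_real_, gm[cbind(ridx, cols)])
      ld <- ifelse(is.na(lidx), Inf, p - cm[lidx])
      rd <- ifelse(is.na(ridx), Inf, cm[ridx] - p)
      Q[, jj] <- .expect_flanks(lval, ld, rval, rd)
    }
  }
  Q
}

# residual sum of squares of y ~ X (X includes the intercept column)
.rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Forward stepwise cofactor selection
#'
#' Selects background markers for composite interval mapping by forward
#' stepwise regression of the trait on (expectation-imputed) marker genotypes,
#' adding the marker with the largest residual-sum-of-squares reduction until
#' `max_cofactors` are chosen or the partial F-test p-value exceeds
#' `p_enter`.
#'
#' @param trait Numeric trait vector aligned with the RIL columns.
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @param max_cofactors Maximum number of cofactors (default 5).
#' @param p_enter Partial F-test entry threshold (default 0.01).
#' @return Character vector of selected marker ids (possibly empty).
#' @export
select_cofactors <- function(trait, genotypes, map, max_cofactors = 5,
                             p_enter = 0.01) {
  keep <- !is.na(trait)
  y <- trait[keep]
  n <- length(y)
  if (n < 20) ril_abort("degenerate", "need >= 20 RILs with trait data")
  if (stats::sd(y) == 0) ril_abort("degenerate", "constant trait")
  Xm <- genotype_expectation(genotypes, map,
                             grid = data.frame(chrom = map$chrom, cm = map$cm,
                                               bp = map$bp))[keep, , drop = FALSE]
  colnames(Xm) <- map$marker
  chosen <- integer(0)
  X <- matrix(1, n, 1)
  rss_cur <- .rss(X, y)
  repeat {
    if (length(chosen) >= max_cofactors) break
    cand <- setdiff(seq_len(ncol(Xm)), chosen)
    rss_new <- vapply(cand, function(j) {
      xj <- Xm[, j]
      if (stats::sd(xj) == 0) return(Inf)
      .rss(cbind(X, xj), y)
    }, numeric(1))
    j_best <- cand[which.min(rss_new)]
    rss_best <- min(rss_new)
    if (!is.finite(rss_best)) break
    df2 <- n - (ncol(X) + 1)
    f <- (rss_cur - rss_best) / (rss_best / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
    if (is.na(p) || p > p_enter) break
    chosen <- c(chosen, j_best)
    X <- cbind(X, Xm[, j_best])
    rss_cur <- rss_best
  }
  map$marker[chosen]
}

#' Composite interval mapping scan for one trait
#'
#' Haley-Knott regression at every grid position: the trait is regressed on
#' the expected QTL genotype plus the selected cofactors, excluding cofactors
#' within `window_cm` of the test position. The statistic is
#' `LRT = n ln(RSS0/RSS1)` (model without vs with the QTL term),
#' `LOD = LRT / (2 ln 10)`. The additive effect is half the difference
#' between the fitted genotype-class means, signed so that a positive value
#' means the Mo17 allele increases the trait. `r2 = (RSS0 - RSS1)/TSS`.
#'
#' @param trait Numeric vector aligned with the RIL columns (NAs dropped).
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @param cofactors Character vector of cofactor marker ids (possibly empty).
#' @param step_cm Walking speed (default 1 cM).
#' @param window_cm Cofactor exclusion window around the test position
#'   (default 10 cM).
#' @return A `scan_profile` data frame: `chrom`, `cm`, `bp`, `lod`, `lrt`,
#'   `additive`, `r2`; the cofactors used are stored as an attribute.
#' @export
cim_scan <- function(trait, genotypes, map, cofactors = NULL, step_cm = 1,
                     window_cm = 10) {
  keep <- !is.na(trait)
  y <- trait[keep]
  n <- length(y)
  if (stats::sd(y) == 0) ril_abort("degenerate", "constant trait")
  grid <- qtl_grid(map, step_cm)
  # skip chromosomes with no genotype information at all
  ok_chrom <- vapply(unique(map$chrom), function(cc)
    any(!is.na(genotypes[map$chrom == cc, , drop = FALSE])), logical(1))
  bad <- unique(map$chrom)[!ok_chrom]
  if (length(bad)) {
    warning("skipping chromosome(s) with all-missing genotypes: ",
            paste(bad, collapse = ", "))
    grid <- grid[!(grid$chrom %in% bad), , drop = FALSE]
  }
  Q <- genotype_expectation(genotypes, map, grid)[keep, , drop = FALSE]
  cof_idx <- match(cofactors, map$marker)
  cof_idx <- cof_idx[!is.na(cof_idx)]
  C <- if (length(cof_idx))
    genotype_expectation(genotypes, map,
                         grid = data.frame(chrom = map$chrom[cof_idx],
                                           cm = map$cm[cof_idx],
                                           bp = map$bp[cof_idx]))[keep, , drop = FALSE]
  else NULL
  tss <- sum((y - mean(y))^2)
  P <- nrow(grid)
  lrt <- additive <- r2 <- numeric(P)
  # cache the null RSS per distinct active-cofactor set
  rss0_cache <- new.env(parent = emptyenv())
  for (j in seq_len(P)) {
    active <- if (length(cof_idx)) {
      which(!(map$chrom[cof_idx] == grid$chrom[j] &
                abs(map$cm[cof_idx] - grid$cm[j]) < window_cm))
    } else integer(0)
    key <- paste0("k", paste(active, collapse = ","))
    X0 <- if (length(active)) cbind(1, C[, active, drop = FALSE]) else
      matrix(1, n, 1)
    rss0 <- if (!is.null(rss0_cache[[key]])) rss0_cache[[key]] else {
      v <- .rss(X0, y); rss0_cache[[key]] <- v; v
    }
    q <- Q[, j]
    if (stats::sd(q) == 0) next
    fit1 <- stats::lm.fit(cbind(X0, q), y)
    rss1 <- sum(fit1$residuals^2)
    lrt[j] <- max(0, n * log(rss0 / rss1))
    additive[j] <- fit1$coefficients[length(fit1$coefficients)]
    r2[j] <- max(0, (rss0 - rss1) / tss)
  }
  out <- data.frame(chrom = grid$chrom, cm = grid$cm, bp = grid$bp,
                    lrt = lrt, lod = lrt_to_lod(lrt),
                    additive = additive, r2 = r2)
  attr(out, "cofactors") <- cofactors
  class(out) <- c("scan_profile", "data.frame")
  out
}

# interval-mapping scan of many traits at once (no cofactors): for a single
# regressor, LRT = -n ln(1 - r^2) with r the trait/expected-genotype
# correlation, so the whole scan is one cross-product.
im_scan_many <- function(Y, Q) {
  n <- ncol(Y)
  Yc <- Y - rowMeans(Y)
  Qc <- sweep(Q, 2, colMeans(Q))
  cs_q <- colSums(Qc^2)
  cs_y <- rowSums(Yc^2)
  CP <- crossprod(Qc, t(Yc))                 # positions x traits
  r2 <- CP^2 / outer(cs_q, cs_y)
  r2[!is.finite(r2)] <- 0
  r2 <- pmin(r2, 1 - 1e-12)
  beta <- CP / cs_q
  beta[!is.finite(beta)] <- 0
  list(lrt = -n * log(1 - r2), additive = beta, r2 = r2)
}

#' Genome-wide permutation LOD threshold
#'
#' Pools, over `n_traits` randomly selected traits and `n_perm` permutations
#' each, the genome-wide maximum interval-mapping LRT after shuffling RIL
#' labels, and returns the `1 - alpha` quantile as one representative null
#' threshold (in both LRT and LOD units).
#'
#' @param Y Numeric trait matrix, traits x RILs (already transformed).
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @param n_traits Number of traits to sample (default 50; capped at
#'   `nrow(Y)`).
#' @param n_perm Permutations per trait (default 200, `>= 100`).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param step_cm Scan grid step.
#' @param seed Optional RNG seed.
#' @return A list with `lrt_threshold`, `lod_threshold` and the pooled
#'   `null_max` LRT values.
#' @export
permutation_threshold <- function(Y, genotypes, map, n_traits = 50,
                                  n_perm = 200, alpha = 0.05, step_cm = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 100) ril_abort("format", "n_perm must be >= 100")
  n_traits <- min(n_traits, nrow(Y))
  pick <- sample.int(nrow(Y), n_traits)
  grid <- qtl_grid(map, step_cm)
  Q <- genotype_expectation(genotypes, map, grid)
  n <- ncol(Y)
  maxima <- numeric(0)
  for (t in pick) {
    y <- Y[t, ]
    Yp <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
    sc <- im_scan_many(t(Yp), Q)
    maxima <- c(maxima, apply(sc$lrt, 2, max))
  }
  thr <- emp_quantile(maxima, 1 - alpha)
  list(lrt_threshold = thr, lod_threshold = lrt_to_lod(thr),
       null_max = maxima)
}

#' Call eQTL peaks from a scan profile
#'
#' Local maxima with LOD at or above the threshold become candidate peaks.
#' The support interval extends on each side to the nearest grid position
#' where LOD drops to `peak - lod_drop` (or the chromosome end). Candidate
#' peaks on one chromosome whose support intervals come within `merge_cm` cM
#' are merged, keeping the higher peak and the union of the intervals.
#'
#' @param profile A `scan_profile` from [cim_scan()].
#' @param lod_threshold Genome-wide LOD threshold.
#' @param lod_drop Support-interval drop (default 1).
#' @param merge_cm Merge distance between support intervals (default 10 cM).
#' @return Data frame of eQTL records: `chrom`, `peak_cm`, `peak_bp`, `lod`,
#'   `lrt`, `additive`, `r2`, `ci_lo_cm`, `ci_hi_cm`, `ci_lo_bp`, `ci_hi_bp`.
#' @export
call_eqtl <- function(profile, lod_threshold, lod_drop = 1.0, merge_cm = 10) {
  empty <- data.frame(chrom = character(0), peak_cm = numeric(0),
                      peak_bp = numeric(0), lod = numeric(0), lrt = numeric(0),
                      additive = numeric(0), r2 = numeric(0),
                      ci_lo_cm = numeric(0), ci_hi_cm = numeric(0),
                      ci_lo_bp = numeric(0), ci_hi_bp = numeric(0))
  if (nrow(profile) == 0) return(empty)
  recs <- list()
  for (cc in unique(profile$chrom)) {
    sub <- profile[profile$chrom == cc, , drop = FALSE]
    m <- nrow(sub)
    lod <- sub$lod
    if (m == 1) {
      cand <- if (lod[1] >= lod_threshold) 1L else integer(0)
    } else {
      left_ok <- c(TRUE, lod[-1] > lod[-m])       # strictly above the left run
      right_ok <- c(lod[-m] >= lod[-1], TRUE)
      cand <- which(left_ok & right_ok & lod >= lod_threshold)
    }
    for (i in cand) {
      cut <- lod[i] - lod_drop
      lo <- 1
      if (i > 1) for (j in (i - 1):1) if (lod[j] <= cut) { lo <- j; break }
      hi <- m
      if (i < m) for (j in (i + 1):m) if (lod[j] <= cut) { hi <- j; break }
      recs[[length(recs) + 1]] <- data.frame(
        chrom = cc, peak_cm = sub$cm[i], peak_bp = sub$bp[i], lod = lod[i],
        lrt = sub$lrt[i], additive = sub$additive[i], r2 = sub$r2[i],
        ci_lo_cm = sub$cm[lo], ci_hi_cm = sub$cm[hi],
        ci_lo_bp = sub$bp[lo], ci_hi_bp = sub$bp[hi])
    }
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  out <- out[order(out$chrom, out$peak_cm), , drop = FALSE]
  # merge support intervals that come within merge_cm on one chromosome
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(out)) {
      if (out$chrom[i] == out$chrom[i + 1] &&
          out$ci_lo_cm[i + 1] - out$ci_hi_cm[i] < merge_cm) {
        keep <- if (out$lod[i] >= out$lod[i + 1]) i else i + 1
        row <- out[keep, , drop = FALSE]
        row$ci_lo_cm <- min(out$ci_lo_cm[i:(i + 1)])
        row$ci_hi_cm <- max(out$ci_hi_cm[i:(i + 1)])
        row$ci_lo_bp <- min(out$ci_lo_bp[i:(i + 1)])
        row$ci_hi_bp <- max(out$ci_hi_bp[i:(i + 1)])
        out <- rbind(if (i > 1) out[seq_len(i - 1), ], row,
                     if (i + 1 < nrow(out)) out[seq(i + 2, nrow(out)), ])
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  rownames(out) <- NULL
  out
}

#' Classify an eQTL as cis or trans
#'
#' An eQTL is cis when the regulated gene's midpoint lies on the same
#' chromosome within the support interval widened by `cis_margin_mb`;
#' otherwise trans. Unplaced genes leave the record unclassified (`NA`) with
#' a warning.
#'
#' @param eqtls Data frame from [call_eqtl()] (any number of rows).
#' @param gene_row One row of a [gene_annotation()] for the regulated gene, or
#'   `NULL` if unplaced.
#' @param cis_margin_mb Margin around the support interval (default 1 Mb).
#' @return Character vector `"cis"`/`"trans"` (or `NA`), one per record.
#' @export
classify_cis_trans <- function(eqtls, gene_row, cis_margin_mb = 1) {
  if (is.null(gene_row) || nrow(gene_row) == 0) {
    warning("unmapped-gene: record left unclassified")
    return(rep(NA_character_, nrow(eqtls)))
  }
  mid <- (gene_row$start + gene_row$end) / 2
  margin <- cis_margin_mb * 1e6
  ifelse(eqtls$chrom == gene_row$chrom &
           mid >= eqtls$ci_lo_bp - margin &
           mid <= eqtls$ci_hi_bp + margin, "cis", "trans")
}

#' eQTL scan across all traits of an expression matrix
#'
#' Maps every (or a subset of) gene's expression trait: optional cofactor
#' selection, CIM scan, peak calling and cis/trans classification. With
#' `use_cofactors = FALSE` the scan is plain interval mapping vectorised
#' across traits, which is considerably faster.
#'
#' @param expr An [expression_matrix()].
#' @param genotypes,map Genotypes and genetic map.
#' @param annot A [gene_annotation()] for cis/trans classification.
#' @param lod_threshold Genome-wide LOD threshold.
#' @param genes Optional subset of gene ids.
#' @param transform Function applied to RIL RPKM rows before mapping
#'   (default `log2(x + 1)`).
#' @param use_cofactors Run full CIM with stepwise cofactors (default TRUE).
#' @param step_cm,window_cm,lod_drop,merge_cm,cis_margin_mb Scan parameters.
#' @return Data frame of eQTL records with `trait` and `reg_type` columns.
#' @export
eqtl_scan_population <- function(expr, genotypes, map, annot, lod_threshold,
                                 genes = NULL,
                                 transform = function(x) log2(x + 1),
                                 use_cofactors = TRUE, step_cm = 1,
                                 window_cm = 10, lod_drop = 1.0,
                                 merge_cm = 10, cis_margin_mb = 1) {
  rv <- ril_values(expr)
  if (is.null(genes)) genes <- rownames(rv)
  Y <- t(apply(rv[genes, , drop = FALSE], 1, transform))
  keep <- apply(Y, 1, stats::sd) > 0
  genes <- genes[keep]
  Y <- Y[keep, , drop = FALSE]
  out <- list()
  if (use_cofactors) {
    for (i in seq_along(genes)) {
      cof <- select_cofactors(Y[i, ], genotypes, map)
      prof <- cim_scan(Y[i, ], genotypes, map, cofactors = cof,
                       step_cm = step_cm, window_cm = window_cm)
      recs <- call_eqtl(prof, lod_threshold, lod_drop, merge_cm)
      if (nrow(recs)) out[[length(out) + 1]] <- cbind(trait = genes[i], recs)
    }
  } else {
    grid <- qtl_grid(map, step_cm)
    Q <- genotype_expectation(genotypes, map, grid)
    sc <- im_scan_many(Y, Q)
    for (i in seq_along(genes)) {
      prof <- data.frame(chrom = grid$chrom, cm = grid$cm, bp = grid$bp,
                         lrt = sc$lrt[, i], lod = lrt_to_lod(sc$lrt[, i]),
                         additive = sc$additive[, i], r2 = sc$r2[, i])
      class(prof) <- c("scan_profile", "data.frame")
      recs <- call_eqtl(prof, lod_threshold, lod_drop, merge_cm)
      if (nrow(recs)) out[[length(out) + 1]] <- cbind(trait = genes[i], recs)
    }
  }
  if (!length(out)) {
    return(cbind(trait = character(0),
                 call_eqtl(data.frame(chrom = character(0), cm = numeric(0),
                                      bp = numeric(0), lod = numeric(0),
                                      lrt = numeric(0), additive = numeric(0),
                                      r2 = numeric(0)), Inf),
                 reg_type = character(0)))
  }
  res <- do.call(rbind, out)
  res$reg_type <- NA_character_
  for (g in unique(res$trait)) {
    rows <- res$trait == g
    grow <- annot[annot$gene == g, , drop = FALSE]
    res$reg_type[rows] <- suppressWarnings(
      classify_cis_trans(res[rows, , drop = FALSE], grow, cis_margin_mb))
  }
  rownames(res) <- NULL
  res
}
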