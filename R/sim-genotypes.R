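# Meiosis at marker resolution. Under Haldane's model (Poisson crossovers,
# no interference) the founder-origin process along a gamete is Markov at the
# marker positions, with switch probability haldane(d) between adjacent
# markers. h1/h2 are M x N haplotype matrices (founder allele 0 = B73,
# 1 = Mo17), r the length-(M-1) vector of between-marker recombination
# fractions (0.5 across chromosome boundaries). Returns one gamete per column.
meiosis_gametes <- function(h1, h2, r) {
  m <- nrow(h1); n <- ncol(h1)
  start <- sample(c(0L, 1L), n, replace = TRUE)
  if (m == 1) {
    state <- matrix(start, 1, n)
  } else {
    sw <- matrix(stats::runif((m - 1) * n) < r, m - 1, n)
    cs <- matrix(apply(sw, 2, cumsum), m - 1, n)
    state <- rbind(start, sweep(cs, 2, start, `+`) %% 2)
    state <- matrix(as.integer(state) %% 2L, m, n)
  }
  ifelse(state == 0L, h1, h2)
}

#' Simulate intermated-RIL genotypes
#'
#' Forward simulation of the intermated RIL breeding design: an F1 between two
#' fully homozygous inbreds, one round of F1 selfing to the F2, `n_intermating`
#' generations of random pair mating, then single-seed-descent selfing for up
#' to `n_selfing` generations (residual heterozygosity is retained and coded
#' `H`). Meiosis follows Haldane's map function (no interference). Physical
#' positions follow a monotone cM to bp map (`mb_per_cm` Mb per cM).
#'
#' @param chrom_lengths_cm Numeric vector of chromosome lengths in cM.
#' @param marker_spacing_cm Marker spacing in cM (markers at
#'   `seq(0, length, by = spacing)`).
#' @param n_rils Number of RILs (`>= 2`).
#' @param n_intermating Generations of random intermating after the F2
#'   (default 4, as in the IBM population).
#' @param n_base Size of the base population carried through intermating
#'   (default 250, mirroring the scale of real intermated-RIL construction);
#'   the RILs are drawn from it. Must be `>= n_rils`.
#' @param n_selfing Maximum selfing generations (default 8).
#' @param mb_per_cm Mb of physical sequence per cM (default 1).
#' @param positions_cm Optional list of explicit marker positions (cM) per
#'   chromosome, overriding the regular grid.
#' @param seed Optional RNG seed.
#' @return A list with `genotypes` (a [genotype_matrix()]) and `map` (a
#'   [genetic_map()]).
#' @export
simulate_ibm_genotypes <- function(chrom_lengths_cm, marker_spacing_cm = 2,
                                   n_rils = 105, n_intermating = 4,
                                   n_base = 250, n_selfing = 8, mb_per_cm = 1,
                                   positions_cm = NULL, seed = NULL) {
  if (n_rils < 2) ril_abort("degenerate", "need at least 2 RILs")
  n_base <- max(n_base, n_rils)
  if (is.null(positions_cm)) {
    if (any(chrom_lengths_cm <= 0)) ril_abort("degenerate", "chromosome lengths must be > 0")
    positions_cm <- lapply(chrom_lengths_cm, function(L) seq(0, L, by = marker_spacing_cm))
  }
  if (!is.null(seed)) set.seed(seed)
  n_chr <- length(positions_cm)
  chrom <- rep(paste0("chr", seq_len(n_chr)), lengths(positions_cm))
  cm <- unlist(positions_cm, use.names = FALSE)
  marker <- unlist(lapply(seq_len(n_chr), function(i)
    sprintf("c%dm%03d", i, seq_along(positions_cm[[i]]))), use.names = FALSE)
  bp <- round(cm * mb_per_cm * 1e6) + 1
  map <- genetic_map(marker, chrom, cm, bp)

  m <- nrow(map)
  # recombination fraction between adjacent rows; 0.5 across chromosomes
  r <- if (m > 1) {
    d <- diff(map$cm)
    same <- map$chrom[-m] == map$chrom[-1]
    ifelse(same, haldane(d), 0.5)
  } else numeric(0)

  n <- n_base
  h1 <- matrix(0L, m, n); h2 <- matrix(1L, m, n)          # F1 individuals
  h1n <- meiosis_gametes(h1, h2, r)                        # F2 = F1 selfed
  h2n <- meiosis_gametes(h1, h2, r)
  h1 <- h1n; h2 <- h2n
  for (g in seq_len(n_intermating)) {                      # random pair mating
    mothers <- sample.int(n, n, replace = TRUE)
    fathers <- sample.int(n, n, replace = TRUE)
    clash <- fathers == mothers
    while (any(clash)) {
      fathers[clash] <- sample.int(n, sum(clash), replace = TRUE)
      clash <- fathers == mothers
    }
    g1 <- meiosis_gametes(h1[, mothers, drop = FALSE], h2[, mothers, drop = FALSE], r)
    g2 <- meiosis_gametes(h1[, fathers, drop = FALSE], h2[, fathers, drop = FALSE], r)
    h1 <- g1; h2 <- g2
  }
  for (g in seq_len(n_selfing)) {                          # SSD selfing
    g1 <- meiosis_gametes(h1, h2, r)
    g2 <- meiosis_gametes(h1, h2, r)
    h1 <- g1; h2 <- g2
    if (all(h1 == h2)) break
  }
  keep <- sample.int(n, n_rils)                            # lineages kept as RILs
  tot <- h1[, keep, drop = FALSE] + h2[, keep, drop = FALSE]
  calls <- matrix(NA_character_, m, n_rils,
                  dimnames = list(map$marker, sprintf("RIL%03d", seq_len(n_rils))))
  calls[tot == 0L] <- "A"
  calls[tot == 2L] <- "B"
  calls[tot == 1L] <- "H"
  list(genotypes = genotype_matrix(calls, map), map = map)
}

#' Empirical map expansion of a RIL genotype matrix
#'
#' Compares observed recombinant fractions between adjacent markers with the
#' single-meiosis (Haldane) expectation from the map distances and reports the
#' implied expansion factor (observed Haldane-inverse cM over meiotic cM),
#' averaged over intervals. Intermating plus selfing expands the realised map
#' relative to a single meiosis; the factor is reported empirically rather
#' than targeted.
#'
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @return A single numeric expansion factor.
#' @export
map_expansion <- function(genotypes, map) {
  g <- geno_numeric(genotypes)
  m <- nrow(map)
  fac <- c()
  for (i in seq_len(m - 1)) {
    if (map$chrom[i] != map$chrom[i + 1]) next
    d <- map$cm[i + 1] - map$cm[i]
    if (d <= 0) next
    a <- g[i, ]; b <- g[i + 1, ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 10) next
    rf <- mean(a[ok] != b[ok])
    rf <- min(rf, 0.499)
    implied_cm <- -50 * log(1 - 2 * rf)   # inverse Haldane
    fac <- c(fac, implied_cm / d)
  }
  mean(fac)
}
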