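# Independent oracles used across tests. These deliberately avoid the
# package's own machinery (scalar loops instead of the vectorised Markov
# construction) so that agreement is informative.

# forward Monte-Carlo of the intermated-RIL breeding design at two loci a
# genetic distance d_cm apart; returns the per-line genotype pairs of fully
# homozygous lines (each line a string like "AB")
oracle_two_locus_rils <- function(d_cm, n_lines, n_intermating = 4,
                                  n_base = 250, n_selfing = 8) {
  r <- 0.5 * (1 - exp(-2 * d_cm / 100))
  gamete <- function(ind) {  # ind = list(h1 = c(x, y), h2 = c(x, y))
    pick <- sample(1:2, 1)
    first <- ind[[pick]][1]
    second <- if (runif(1) < r) ind[[3 - pick]][2] else ind[[pick]][2]
    c(first, second)
  }
  f1 <- list(h1 = c(0L, 0L), h2 = c(1L, 1L))
  pop <- replicate(n_base, list(h1 = gamete(f1), h2 = gamete(f1)),
                   simplify = FALSE)
  for (g in seq_len(n_intermating)) {
    pop <- lapply(seq_len(n_base), function(i) {
      mo <- sample.int(n_base, 1)
      fa <- sample.int(n_base, 1)
      while (fa == mo) fa <- sample.int(n_base, 1)
      list(h1 = gamete(pop[[mo]]), h2 = gamete(pop[[fa]]))
    })
  }
  # each line descends by independent single-seed selfing from a random
  # intermated individual
  lineages <- pop[sample.int(n_base, n_lines, replace = n_lines > n_base)]
  pop <- lapply(lineages, function(ind) {
    for (g in seq_len(n_selfing)) ind <- list(h1 = gamete(ind), h2 = gamete(ind))
    ind
  })
  vapply(pop, function(ind) {
    tot <- ind$h1 + ind$h2
    if (any(tot == 1L)) return(NA_character_)   # still heterozygous
    paste(c("A", "B")[tot / 2 + 1], collapse = "")
  }, character(1))
}

# recombinant fraction among homozygous two-locus lines
oracle_recomb_fraction <- function(lines) {
  lines <- lines[!is.na(lines)]
  mean(lines %in% c("AB", "BA"))
}

# brute-force 1-LOD support interval: scan outward from the peak index for
# the nearest position at or below peak - drop
oracle_support <- function(lod, peak, drop = 1) {
  cut <- lod[peak] - drop
  lo <- 1
  if (peak > 1) for (j in (peak - 1):1) if (lod[j] <= cut) { lo <- j; break }
  hi <- length(lod)
  if (peak < length(lod)) for (j in (peak + 1):length(lod)) if (lod[j] <= cut) { hi <- j; break }
  c(lo, hi)
}

# small ready-made population shared by several tests
small_population <- function(seed = 42, chroms = c(80, 80, 80), spacing = 2,
                             n_rils = 105) {
  simulate_ibm_genotypes(chroms, spacing, n_rils, seed = seed)
}
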