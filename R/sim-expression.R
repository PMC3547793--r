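#' Planted expression architecture
#'
#' Describes the ground-truth regulatory architecture that
#' [simulate_expression()] plants into a synthetic RIL expression matrix:
#' additive cis- and trans-eQTL on the log2 scale, a trans-acting hotspot
#' regulator with many targets, paramutation-like genes (all RILs at one
#' parent's level), presence/absence genes built from one- and two-locus
#' logic (Mendelian 1:1, complementation at 25%, loss at 75%), CNV dosage
#' genes, and fragment/ancestral gene pairs with negative expression coupling.
#'
#' Effects are additive allele effects `a` on the log2 scale (genotype class
#' means differ by `2a`; positive sign means the Mo17 allele increases
#' expression). Noise is multiplicative, `exp(N(0, noise_sd))`, applied last;
#' values below `floor` RPKM are clamped to zero so absence calls arise
#' naturally.
#'
#' @param n_cis,n_trans Numbers of single-eQTL genes (cis / trans).
#' @param cis_effect,trans_effect Additive effects (log2 scale); vectors are
#'   recycled over the planted genes.
#' @param hotspot_targets Number of targets of the planted hotspot regulator
#'   (0 disables the hotspot).
#' @param hotspot_effect Additive effect for hotspot targets (log2).
#' @param hotspot_sign_prob Probability that a target's effect is
#'   Mo17-positive (0.5 = no haplotype bias).
#' @param n_paramutation Number of paramutation-like genes.
#' @param paramutation_delta Log2 separation between the parents for
#'   paramutation-like genes.
#' @param pa_counts Named integer vector of presence/absence gene counts for
#'   types `I`, `II`, `IIIA`, `IIIB` and `mendelian_50`.
#' @param n_cnv Number of CNV dosage genes.
#' @param cnv_multiplier Copy-number dosage multiplier for the gain haplotype.
#' @param n_fragment_pairs Number of fragment/ancestral coupled gene pairs.
#' @param fragment_coupling_delta Log2 reduction of the ancestral gene when
#'   the fragment is expressed (negative coupling).
#' @param base_log2_mean,base_log2_sd Log2-normal baseline expression.
#' @param noise_sd SD of the multiplicative log-normal noise (natural log
#'   scale).
#' @param floor RPKM floor below which values are clamped to 0.
#' @param annotation_density_per_mb Density of filler (unexpressed) gene
#'   annotations emulating genome-wide gene density, used by window
#'   statistics.
#' @return A `sim_architecture` list.
#' @export
sim_architecture <- function(n_cis = 20, n_trans = 10,
                             cis_effect = 1, trans_effect = 0.8,
                             hotspot_targets = 0, hotspot_effect = 0.8,
                             hotspot_sign_prob = 0.5,
                             n_paramutation = 0, paramutation_delta = 3,
                             pa_counts = c(I = 0, II = 0, IIIA = 0, IIIB = 0,
                                           mendelian_50 = 0),
                             n_cnv = 0, cnv_multiplier = 2,
                             n_fragment_pairs = 0,
                             fragment_coupling_delta = 1.5,
                             base_log2_mean = 4, base_log2_sd = 1.5,
                             noise_sd = 0.2, floor = 0.05,
                             annotation_density_per_mb = 15) {
  pa <- c(I = 0, II = 0, IIIA = 0, IIIB = 0, mendelian_50 = 0)
  pa[names(pa_counts)] <- pa_counts
  structure(list(n_cis = n_cis, n_trans = n_trans, cis_effect = cis_effect,
                 trans_effect = trans_effect, hotspot_targets = hotspot_targets,
                 hotspot_effect = hotspot_effect,
                 hotspot_sign_prob = hotspot_sign_prob,
                 n_paramutation = n_paramutation,
                 paramutation_delta = paramutation_delta, pa_counts = pa,
                 n_cnv = n_cnv, cnv_multiplier = cnv_multiplier,
                 n_fragment_pairs = n_fragment_pairs,
                 fragment_coupling_delta = fragment_coupling_delta,
                 base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
                 noise_sd = noise_sd, floor = floor,
                 annotation_density_per_mb = annotation_density_per_mb),
            class = "sim_architecture")
}

# allele-content helpers on character calls; H carries both alleles and NA is
# imputed at random (the transcript is still produced even if the genotype
# was not called)
.has_allele <- function(calls_row, allele) {
  out <- calls_row == allele | calls_row == "H"
  miss <- is.na(out)
  if (any(miss)) out[miss] <- stats::runif(sum(miss)) < 0.5
  out
}

#' Simulate an expression matrix with a known planted architecture
#'
#' Builds RPKM-like expression for two parents, one F1 and all RILs of a
#' simulated population. Baseline expression is log-normal; planted additive
#' eQTL effects act on the log2 scale; paramutation-like genes put all RILs at
#' one parent's level; presence/absence genes follow one- or two-locus logic
#' (see [sim_architecture()]); CNV genes are dosage-scaled; fragment genes
#' suppress their ancestral partner when expressed. Multiplicative log-normal
#' noise is applied last and values below the floor are clamped to zero.
#'
#' @param genotypes A [genotype_matrix()] from [simulate_ibm_genotypes()].
#' @param map The matching [genetic_map()].
#' @param architecture A [sim_architecture()].
#' @param n_genes Total number of genes (must cover all planted classes).
#' @param include_f1 Include one F1 sample (additive mid-parent expression).
#' @param seed Optional RNG seed.
#' @return A list with `expr` (an [expression_matrix()]), `truth` (a
#'   `sim_truth` list of planted effects), and `annotation` (a
#'   [gene_annotation()] including filler genes emulating genome gene
#'   density).
#' @export
simulate_expression <- function(genotypes, map, architecture = sim_architecture(),
                                n_genes = 300, include_f1 = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- architecture
  n_ril <- ncol(genotypes)
  n_special <- arch$n_cis + arch$n_trans + arch$hotspot_targets +
    arch$n_paramutation + sum(arch$pa_counts) + arch$n_cnv +
    2 * arch$n_fragment_pairs
  if (n_special > n_genes)
    ril_abort("truth-mismatch", "n_genes too small for the requested architecture")
  if (any(c(arch$n_cis, arch$n_trans) > 0) && nrow(map) < 2)
    ril_abort("truth-mismatch", "architecture references more markers than simulated")

  chroms <- unique(map$chrom)
  chr_len_bp <- vapply(chroms, function(cc) max(map$bp[map$chrom == cc]), numeric(1))
  genes <- sprintf("g%04d", seq_len(n_genes))
  base <- stats::rnorm(n_genes, arch$base_log2_mean, arch$base_log2_sd)

  samples <- c("B73", "Mo17", if (include_f1) "F1", sprintf("RIL%03d", seq_len(n_ril)))
  roles <- stats::setNames(c("B73_parent", "Mo17_parent", if (include_f1) "F1",
                             rep("RIL", n_ril)), samples)
  ncol_s <- length(samples)
  ril_cols <- which(roles == "RIL")
  L <- matrix(base, n_genes, ncol_s, dimnames = list(genes, samples))
  present <- matrix(TRUE, n_genes, ncol_s)   # FALSE forces a hard zero

  # gene physical placement: default random
  gene_chrom <- sample(chroms, n_genes, replace = TRUE)
  gene_bp <- floor(stats::runif(n_genes, 1, chr_len_bp[gene_chrom] - 3000))

  gnum <- geno_numeric(genotypes)            # markers x RILs, A=-1 B=+1
  x_at <- function(mi) {                     # effect covariate over samples
    x <- rep(0, ncol_s)
    x[roles == "B73_parent"] <- -1
    x[roles == "Mo17_parent"] <- 1
    xr <- gnum[mi, ]
    xr[is.na(xr)] <- 0                       # H / missing at the midpoint
    x[ril_cols] <- xr
    x
  }
  add_effect <- function(gi, mi, a) L[gi, ] <<- L[gi, ] + a * x_at(mi)

  idx <- 0
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }

  truth_eqtl <- NULL
  # cis eQTL: gene placed at its marker
  if (arch$n_cis > 0) {
    gi <- take(arch$n_cis)
    mi <- sample.int(nrow(map), arch$n_cis, replace = arch$n_cis > nrow(map))
    cis_eff <- rep_len(arch$cis_effect, arch$n_cis)
    for (k in seq_along(gi)) {
      a <- cis_eff[k] * sample(c(-1, 1), 1)
      add_effect(gi[k], mi[k], a)
      gene_chrom[gi[k]] <- map$chrom[mi[k]]
      gene_bp[gi[k]] <- map$bp[mi[k]]
      truth_eqtl <- rbind(truth_eqtl, data.frame(
        gene = genes[gi[k]], marker = map$marker[mi[k]], chrom = map$chrom[mi[k]],
        cm = map$cm[mi[k]], bp = map$bp[mi[k]], effect = a, tag = "cis"))
    }
  }
  # trans eQTL: effect marker on a different chromosome than the gene
  if (arch$n_trans > 0) {
    gi <- take(arch$n_trans)
    mi <- sample.int(nrow(map), arch$n_trans, replace = arch$n_trans > nrow(map))
    trans_eff <- rep_len(arch$trans_effect, arch$n_trans)
    for (k in seq_along(gi)) {
      a <- trans_eff[k] * sample(c(-1, 1), 1)
      add_effect(gi[k], mi[k], a)
      other <- setdiff(chroms, map$chrom[mi[k]])
      if (length(other)) {
        gene_chrom[gi[k]] <- sample(other, 1)
        gene_bp[gi[k]] <- floor(stats::runif(1, 1, chr_len_bp[gene_chrom[gi[k]]] - 3000))
      }
      truth_eqtl <- rbind(truth_eqtl, data.frame(
        gene = genes[gi[k]], marker = map$marker[mi[k]], chrom = map$chrom[mi[k]],
        cm = map$cm[mi[k]], bp = map$bp[mi[k]], effect = a, tag = "trans"))
    }
  }
  # hotspot: one regulator marker, many unlinked targets
  truth_hotspot <- NULL
  if (arch$hotspot_targets > 0) {
    reg_chrom <- chroms[1]
    cand <- which(map$chrom == reg_chrom)
    reg <- cand[ceiling(length(cand) / 2)]
    gi <- take(arch$hotspot_targets)
    signs <- ifelse(stats::runif(arch$hotspot_targets) < arch$hotspot_sign_prob, 1, -1)
    for (k in seq_along(gi)) {
      a <- arch$hotspot_effect * signs[k]
      add_effect(gi[k], reg, a)
      other <- setdiff(chroms, reg_chrom)
      if (length(other)) {
        gene_chrom[gi[k]] <- sample(other, 1)
        gene_bp[gi[k]] <- floor(stats::runif(1, 1, chr_len_bp[gene_chrom[gi[k]]] - 3000))
      }
    }
    truth_hotspot <- list(marker = map$marker[reg], chrom = map$chrom[reg],
                          cm = map$cm[reg], bp = map$bp[reg],
                          targets = data.frame(gene = genes[gi],
                                               effect = arch$hotspot_effect * signs))
  }
  # paramutation-like: parents split, all RILs at one parent's level
  truth_pm <- NULL
  if (arch$n_paramutation > 0) {
    gi <- take(arch$n_paramutation)
    for (k in seq_along(gi)) {
      g <- gi[k]
      hi_parent <- sample(c("B73", "Mo17"), 1)
      retained <- sample(c("B73", "Mo17"), 1)
      d <- arch$paramutation_delta / 2
      L[g, roles == "B73_parent"] <- base[g] + if (hi_parent == "B73") d else -d
      L[g, roles == "Mo17_parent"] <- base[g] + if (hi_parent == "Mo17") d else -d
      ret_level <- base[g] + if (retained == hi_parent) d else -d
      L[g, ril_cols] <- ret_level
      if (include_f1)   # additive F1: raw mid-parent
        L[g, roles == "F1"] <- log2((2^(base[g] + d) + 2^(base[g] - d)) / 2)
      truth_pm <- rbind(truth_pm, data.frame(
        gene = genes[g], retained_parent = retained,
        silenced_parent = setdiff(c("B73", "Mo17"), retained),
        high_parent = hi_parent))
    }
  }
  # presence/absence logic genes
  truth_pa <- NULL
  pick_two_unlinked <- function() {
    c1 <- sample(chroms, 1)
    c2 <- if (length(chroms) > 1) sample(setdiff(chroms, c1), 1) else c1
    c(sample(which(map$chrom == c1), 1), sample(which(map$chrom == c2), 1))
  }
  apply_pa <- function(g, type) {
    loci <- pick_two_unlinked()
    la <- loci[1]; lb <- loci[2]
    callsA <- genotypes[la, ]; callsB <- genotypes[lb, ]
    hasA1 <- .has_allele(callsA, "A"); hasB1 <- .has_allele(callsA, "B")
    hasA2 <- .has_allele(callsB, "A"); hasB2 <- .has_allele(callsB, "B")
    pres <- rep(TRUE, ncol_s)
    pb73 <- TRUE; pmo17 <- TRUE
    expressing_parent <- NA_character_
    if (type == "II") {          # complementation: B73 allele at A AND Mo17 at B
      ril_pres <- hasA1 & hasB2
      pb73 <- FALSE; pmo17 <- FALSE
    } else if (type == "IIIA") { # both loci from B73 required (~25%)
      ril_pres <- hasA1 & hasA2
      pmo17 <- FALSE; expressing_parent <- "B73"
    } else if (type == "IIIB") { # either locus from B73 suffices (~75%)
      ril_pres <- hasA1 | hasA2
      pmo17 <- FALSE; expressing_parent <- "B73"
    } else if (type == "I") {    # non-parental combination silences (~75% present)
      # loss requires homozygous A at locus 1 and homozygous B at locus 2
      ril_pres <- !(callsA == "A" & callsB == "B")
      ril_pres[is.na(ril_pres)] <- TRUE
    } else {                     # mendelian_50: single locus
      expressing_parent <- sample(c("B73", "Mo17"), 1)
      need <- if (expressing_parent == "B73") "A" else "B"
      ril_pres <- .has_allele(callsA, need)
      if (expressing_parent == "B73") pmo17 <- FALSE else pb73 <- FALSE
      lb <- NA_integer_
    }
    pres[roles == "B73_parent"] <- pb73
    pres[roles == "Mo17_parent"] <- pmo17
    pres[ril_cols] <- ril_pres
    if (include_f1) pres[roles == "F1"] <- TRUE   # heterozygote complements
    present[g, ] <<- pres
    # half of the two-locus genes sit in cis to their first controlling locus
    if (stats::runif(1) < 0.5) {
      gene_chrom[g] <<- map$chrom[la]
      gene_bp[g] <<- map$bp[la]
    }
    truth_pa <<- rbind(truth_pa, data.frame(
      gene = genes[g], type = type,
      locus_a = map$marker[la],
      locus_b = if (is.na(lb)) NA_character_ else map$marker[lb],
      expressing_parent = expressing_parent))
    la
  }
  for (type in names(arch$pa_counts)) {
    k <- arch$pa_counts[[type]]
    if (k > 0) for (g in take(k)) apply_pa(g, type)
  }
  # CNV dosage genes: B73 carries the copy gain at the gene's nearest marker
  truth_cnv <- NULL
  if (arch$n_cnv > 0) {
    gi <- take(arch$n_cnv)
    mi <- sample.int(nrow(map), arch$n_cnv, replace = arch$n_cnv > nrow(map))
    dl <- log2(arch$cnv_multiplier)
    for (k in seq_along(gi)) {
      g <- gi[k]
      gene_chrom[g] <- map$chrom[mi[k]]
      gene_bp[g] <- map$bp[mi[k]]
      carrier <- gnum[mi[k], ] == -1          # A = B73 haplotype
      carrier[is.na(carrier)] <- FALSE
      L[g, ril_cols][carrier] <- L[g, ril_cols][carrier] + dl
      L[g, roles == "B73_parent"] <- L[g, roles == "B73_parent"] + dl
      if (include_f1) L[g, roles == "F1"] <- L[g, roles == "F1"] + dl / 2
      truth_cnv <- rbind(truth_cnv, data.frame(
        gene = genes[g], marker = map$marker[mi[k]], gain_parent = "B73",
        multiplier = arch$cnv_multiplier))
    }
  }
  # fragment / ancestral coupled pairs
  truth_fp <- NULL
  if (arch$n_fragment_pairs > 0) {
    for (k in seq_len(arch$n_fragment_pairs)) {
      gf <- take(1); ga <- take(1)
      la <- apply_pa(gf, "mendelian_50")
      frag_present <- present[gf, ]
      L[ga, frag_present] <- L[ga, frag_present] - arch$fragment_coupling_delta
      other <- setdiff(chroms, map$chrom[la])
      if (length(other)) {
        gene_chrom[ga] <- sample(other, 1)
        gene_bp[ga] <- floor(stats::runif(1, 1, chr_len_bp[gene_chrom[ga]] - 3000))
      }
      gene_chrom[gf] <- map$chrom[la]
      gene_bp[gf] <- map$bp[la]
      truth_fp <- rbind(truth_fp, data.frame(
        fragment = genes[gf], ancestral = genes[ga], coupling = -1))
    }
  }

  raw <- 2^L
  raw[!present] <- 0
  if (arch$noise_sd > 0)
    raw <- raw * exp(stats::rnorm(length(raw), 0, arch$noise_sd))
  raw[raw < arch$floor] <- 0

  expr <- expression_matrix(raw, roles)

  # annotation: expressed genes plus filler genes emulating genome density
  is_frag <- genes %in% c(truth_pa$gene, truth_fp$fragment)
  exon_count <- 1L + stats::rpois(n_genes, ifelse(is_frag, 2.2, 3.9))
  syntenic <- ifelse(is_frag, "inserted", "syntenic")
  family_size <- 1L + stats::rpois(n_genes, ifelse(is_frag, 1, 6))
  ann_gene <- genes; ann_chrom <- gene_chrom; ann_bp <- gene_bp
  ann_exon <- exon_count; ann_syn <- syntenic; ann_fam <- family_size
  dens <- arch$annotation_density_per_mb
  if (dens > 0) {
    for (cc in chroms) {
      nb <- max(0, round(dens * chr_len_bp[cc] / 1e6) -
                  sum(gene_chrom == cc))
      if (nb > 0) {
        ann_gene <- c(ann_gene, sprintf("bg_%s_%04d", cc, seq_len(nb)))
        ann_chrom <- c(ann_chrom, rep(cc, nb))
        ann_bp <- c(ann_bp, floor(stats::runif(nb, 1, chr_len_bp[cc] - 3000)))
        ann_exon <- c(ann_exon, 1L + stats::rpois(nb, 3.9))
        ann_syn <- c(ann_syn, rep("syntenic", nb))
        ann_fam <- c(ann_fam, 1L + stats::rpois(nb, 6))
      }
    }
  }
  annotation <- gene_annotation(ann_gene, ann_chrom, ann_bp, ann_bp + 2999,
                                strand = "+", exon_count = ann_exon,
                                syntenic = ann_syn, family_size = ann_fam)

  truth <- structure(list(eqtl = truth_eqtl, hotspot = truth_hotspot,
                          paramutation = truth_pm, pa = truth_pa,
                          cnv = truth_cnv, fragment_pairs = truth_fp,
                          noise_sd = arch$noise_sd, floor = arch$floor,
                          seed = seed), class = "sim_truth")
  list(expr = expr, truth = truth, annotation = annotation)
}

#' Simulate a non-genic RPKM background
#'
#' Draws i.i.d. values from a mixture of a point mass at zero and an
#' exponential tail, emulating the RPKM distribution of randomly selected
#' non-genic genomic fragments used to calibrate detection thresholds.
#'
#' @param n Number of fragments (`>= 100`).
#' @param zero_prob Probability of a zero (no reads mapped).
#' @param exp_mean Mean of the exponential tail.
#' @param seed Optional RNG seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_nongenic_background <- function(n = 10000, zero_prob = 0.9,
                                         exp_mean = 1, seed = NULL) {
  if (n < 100) ril_abort("too-few", "need at least 100 background fragments")
  if (!is.null(seed)) set.seed(seed)
  nz <- stats::runif(n) >= zero_prob
  out <- numeric(n)
  out[nz] <- stats::rexp(sum(nz), rate = 1 / exp_mean)
  out
}
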