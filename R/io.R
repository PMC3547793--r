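#' Read an expression matrix from TSV
#'
#' The TSV has gene ids in the first column and sample ids in the header. The
#' roles sidecar (TSV, columns `sample_id`, `role`) assigns every sample one
#' of `B73_parent`, `Mo17_parent`, `F1`, `RIL`.
#'
#' @param path Path to the expression TSV.
#' @param roles_path Path to the roles sidecar TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, roles_path) {
  if (!file.exists(path)) ril_abort("io", paste("no such file:", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) ril_abort("format", "ragged rows in expression TSV")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  roles_df <- utils::read.delim(roles_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(roles_df)))
    ril_abort("format", "roles sidecar needs sample_id and role columns")
  if (nrow(df) == 0) {
    vals <- matrix(numeric(0), 0, ncol(df) - 1,
                   dimnames = list(character(0), names(df)[-1]))
  } else {
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) ril_abort("format", "non-numeric expression values")
    rownames(vals) <- df[[1]]
  }
  roles <- stats::setNames(roles_df$role, roles_df$sample_id)
  expression_matrix(vals, roles)
}

#' Write an expression matrix (and its roles sidecar) to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output TSV path.
#' @param roles_path Output path for the roles sidecar.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, roles_path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_results(df, path)
  write_results(data.frame(sample_id = names(x$roles), role = unname(x$roles)),
                roles_path)
  invisible(path)
}

#' Read genotypes and the genetic map
#'
#' @param genotype_path TSV with marker ids in the first column and RIL ids in
#'   the header; calls in `A`/`B`/`H`/`NA`.
#' @param map_path TSV with columns `marker`, `chrom`, `cm`, `bp`.
#' @return A list with elements `genotypes` (a [genotype_matrix()], rows in
#'   map order) and `map` (a [genetic_map()]).
#' @export
read_genetics <- function(genotype_path, map_path) {
  mp <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  if (!all(c("marker", "chrom", "cm", "bp") %in% names(mp)))
    ril_abort("format", "map needs marker/chrom/cm/bp columns")
  map <- genetic_map(mp$marker, mp$chrom, mp$cm, mp$bp)
  gt <- utils::read.delim(genotype_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  markers <- as.character(gt[[1]])
  if (!setequal(markers, map$marker))
    ril_abort("marker-mismatch", "markers differ between genotype file and map")
  calls <- as.matrix(gt[, -1, drop = FALSE])
  mode(calls) <- "character"
  calls[calls == "NA" | calls == ""] <- NA_character_
  rownames(calls) <- markers
  calls <- calls[map$marker, , drop = FALSE]
  list(genotypes = genotype_matrix(calls, map), map = map)
}

#' Write genotypes and map to TSV
#'
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @param genotype_path,map_path Output paths.
#' @return Invisibly, `genotype_path`.
#' @export
write_genetics <- function(genotypes, map, genotype_path, map_path) {
  g <- as.data.frame(unclass(genotypes), stringsAsFactors = FALSE)
  write_results(cbind(data.frame(marker = rownames(genotypes)), g), genotype_path)
  write_results(as.data.frame(map), map_path)
  invisible(genotype_path)
}

#' Read gene annotation from GFF3
#'
#' Gene coordinates are kept 1-based inclusive. The exon count of a gene is
#' the maximum exon count over its transcripts (the canonical transcript).
#' Optional `syntenic` and `family_size` attributes on the gene feature are
#' honoured; otherwise they default to `"unknown"` and 1.
#'
#' @param path Path to a GFF3 file with `gene` and `exon` features.
#' @return A [gene_annotation()] data frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) ril_abort("io", paste("no such file:", path))
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE,
                      col.names = c("seqid", "source", "type", "start",
                                    "end", "score", "strand", "phase",
                                    "attributes")),
    error = function(e) data.frame())
  if (nrow(raw) == 0)
    return(gene_annotation(character(0), character(0), numeric(0), numeric(0)))
  if (any(raw$end < raw$start)) ril_abort("format", "feature end < start in GFF3")
  gff <- as.data.frame(rtracklayer::readGFF(path))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0)
    return(gene_annotation(character(0), character(0), numeric(0), numeric(0)))
  exons <- gff[gff$type == "exon", , drop = FALSE]
  tx <- gff[!(gff$type %in% c("gene", "exon")) & lengths(gff$Parent) > 0, , drop = FALSE]
  tx_parent <- stats::setNames(vapply(tx$Parent, `[[`, "", 1), tx$ID)
  exon_count <- vapply(genes$ID, function(gid) {
    tx_ids <- names(tx_parent)[tx_parent == gid]
    if (length(tx_ids) == 0) {
      # exons attached directly to the gene
      n <- sum(vapply(exons$Parent, function(p) gid %in% p, logical(1)))
      return(max(1L, as.integer(n)))
    }
    per_tx <- vapply(tx_ids, function(t)
      sum(vapply(exons$Parent, function(p) t %in% p, logical(1))), integer(1))
    max(1L, max(per_tx))
  }, integer(1))
  synt <- if ("syntenic" %in% names(genes)) {
    s <- as.character(genes$syntenic)
    ifelse(is.na(s), "unknown", s)
  } else "unknown"
  fam <- if ("family_size" %in% names(genes)) {
    f <- suppressWarnings(as.integer(as.character(genes$family_size)))
    ifelse(is.na(f), 1L, f)
  } else 1L
  gene_annotation(gene = genes$ID, chrom = as.character(genes$seqid),
                  start = genes$start, end = genes$end,
                  strand = as.character(genes$strand),
                  exon_count = exon_count, syntenic = synt, family_size = fam)
}

#' Read CGH/CNV segments from a BED-like file
#'
#' BED coordinates (0-based, half-open) are converted to 1-based inclusive on
#' read. The fourth column carries the CGH class label.
#'
#' @param path Path to a tab-separated BED file: chrom, start, end, class.
#' @return A `cnv_segments` data frame with columns `chrom`, `start`, `end`,
#'   `cgh_class` (1-based inclusive coordinates).
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "cgh_class")
  vocab <- c("B=M", "B<M_SNP", "B=M_int", "M>B_CNV", "B>M_CNV", "B>M_int", "B>M_PAV")
  if (!all(df$cgh_class %in% vocab)) ril_abort("format", "unknown CGH class label")
  out <- data.frame(chrom = as.character(df$chrom),
                    start = as.numeric(df$start) + 1,
                    end = as.numeric(df$end),
                    cgh_class = df$cgh_class, stringsAsFactors = FALSE)
  if (any(out$end < out$start)) ril_abort("format", "segment end < start")
  class(out) <- c("cnv_segments", "data.frame")
  out
}

#' Write a result table to TSV
#'
#' Columns are written in their given (deterministic) order; floating point
#' values are serialised with 10 significant digits so that tables round-trip
#' through [read_results()].
#'
#' @param records A data frame (may have zero rows).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  if (is.null(records)) ril_abort("format", "records must not be NULL")
  records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 10, format = "g")
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ril_abort("io", paste("cannot write", path))
  invisible(path)
}

#' Read back a table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
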