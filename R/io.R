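# Readers and writers for the pipeline's TSV dialects.
#
# CNV tables (raw calls, consensus, CNVR, truth) use 1-based inclusive
# coordinates on disk, the dialect of array-CNV reports; gene annotations
# are accepted as BED (0-based half-open). Everything is converted to the
# internal 0-based half-open convention on read and back on write.

.sex_chrom_pattern <- "^(chr)?(X|Y|M|MT)$"

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stop_row <- function(path, rows, why) {
  stop(sprintf("%s: %s at line(s) %s", path, why,
               paste(utils::head(rows + 1L, 5), collapse = ", ")))
}

# Shared validation of a 1-based inclusive CNV-style table. Returns the df
# with internal coordinates, sex-chromosome rows dropped (count messaged).
.convert_cnv_coords <- function(df, path, chroms = NULL) {
  sex <- grepl(.sex_chrom_pattern, df$chrom, ignore.case = TRUE)
  if (any(sex)) {
    message(sum(sex), " non-autosomal record(s) dropped from ", basename(path))
    df <- df[!sex, , drop = FALSE]
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start > df$end |
                 df$start < 1)
  if (length(bad)) .stop_row(path, bad, "invalid coordinates (need 1 <= start <= end)")
  df$start <- df$start - 1  # 1-based inclusive -> 0-based half-open
  if (!is.null(chroms)) {
    chroms <- .assert_chrom_info(chroms)
    unk <- which(!df$chrom %in% chroms$chrom)
    if (length(unk)) .stop_row(path, unk, paste0(
      "unknown chromosome '", df$chrom[unk[1]], "'"))
    L <- chroms$length_bp[match(df$chrom, chroms$chrom)]
    over <- which(df$end > L)
    if (length(over)) .stop_row(path, over, "end beyond chromosome length")
  }
  rownames(df) <- NULL
  df
}

#' Read a chromosome info TSV
#'
#' Columns `chrom`, `length_bp`, `centromere_center_bp`; one row per
#' autosome analysed.
#'
#' @param path TSV file.
#' @return a [chrom_info()] table.
#' @export
read_chrom_info <- function(path) {
  df <- .read_tsv(path)
  .assert_cols(df, c("chrom", "length_bp", "centromere_center_bp"), path)
  chrom_info(df$chrom, df$length_bp, df$centromere_center_bp)
}

#' @rdname read_chrom_info
#' @param chroms table to write.
#' @export
write_chrom_info <- function(chroms, path) {
  .write_tsv(as.data.frame(.assert_chrom_info(chroms)), path)
}

#' Read raw per-caller CNV calls
#'
#' Expected columns: `sample_id`, `caller_id`, `chrom`, `start`, `end`
#' (1-based inclusive), `type` (`dup`/`del`), optional `confidence` (empty
#' allowed). Non-autosomal rows (X/Y/MT) are dropped with a message;
#' unknown chromosomes, invalid coordinates or types are errors reported
#' with their file line.
#'
#' @param path TSV file.
#' @param chroms optional [chrom_info()] table for bounds checking.
#' @return calls data.frame with internal 0-based half-open coordinates.
#' @export
read_cnv_calls <- function(path, chroms = NULL) {
  df <- .read_tsv(path)
  .assert_cols(df, c("sample_id", "caller_id", "chrom", "start", "end", "type"),
               path)
  bad <- which(!df$type %in% c("dup", "del"))
  if (length(bad)) .stop_row(path, bad, paste0("unknown CNV type '", df$type[bad[1]], "'"))
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_
  df$confidence <- suppressWarnings(as.numeric(df$confidence))
  .convert_cnv_coords(df, path, chroms)
}

#' Write a CNV-style table (1-based inclusive on disk)
#'
#' Works for raw calls, consensus CNVs and truth tables: any data.frame
#' with `chrom`, `start`, `end` in the internal convention.
#'
#' @param df table with internal coordinates.
#' @param path output TSV.
#' @export
write_cnv_table <- function(df, path) {
  out <- as.data.frame(df)
  out$start <- out$start + 1  # back to 1-based inclusive
  .write_tsv(out, path)
}

#' Read a CNV-style table written by [write_cnv_table()]
#'
#' @param path TSV file.
#' @param chroms optional bounds check.
#' @return data.frame with internal coordinates.
#' @export
read_cnv_table <- function(path, chroms = NULL) {
  df <- .read_tsv(path)
  .assert_cols(df, c("chrom", "start", "end"), path)
  .convert_cnv_coords(df, path, chroms)
}

#' Read sample metadata
#'
#' Columns `sample_id`, `group`, `tissue`, and optionally `family_id`,
#' `role`.
#'
#' @param path TSV file.
#' @return metadata data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- .read_tsv(path)
  .assert_cols(df, c("sample_id", "group", "tissue"), path)
  if (anyDuplicated(df$sample_id)) stop(path, ": duplicated sample_id")
  df
}

#' Read a gene annotation BED file
#'
#' BED dialect: tab-separated `chrom`, `start` (0-based), `end`, `name`;
#' no header. Coordinates are already half-open so no conversion is
#' applied. Non-autosomal genes are dropped with a message.
#'
#' @param path BED file.
#' @param chroms optional bounds check.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `length_bp`.
#' @export
read_gene_bed <- function(path, chroms = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop(path, ": BED needs chrom, start, end, name")
  names(df)[1:4] <- c("chrom", "start", "end", "gene_id")
  sex <- grepl(.sex_chrom_pattern, df$chrom, ignore.case = TRUE)
  if (any(sex)) {
    message(sum(sex), " non-autosomal gene(s) dropped from ", basename(path))
    df <- df[!sex, , drop = FALSE]
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$end <= df$start |
                 df$start < 0)
  if (length(bad)) .stop_row(path, bad - 1L, "invalid BED interval")
  if (!is.null(chroms)) {
    chroms <- .assert_chrom_info(chroms)
    unk <- which(!df$chrom %in% chroms$chrom)
    if (length(unk)) .stop_row(path, unk - 1L, "unknown chromosome")
  }
  df$length_bp <- df$end - df$start
  rownames(df) <- NULL
  df[, c("gene_id", "chrom", "start", "end", "length_bp")]
}

#' @rdname read_gene_bed
#' @param genes gene table to write (BED, no header).
#' @export
write_gene_bed <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix TSV
#'
#' First column `gene_id`, remaining columns one per sample; nonnegative
#' values (FPKM or raw counts).
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene_id") stop(path, ": first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  if (anyNA(m)) stop(path, ": non-numeric or missing expression values")
  if (any(m < 0)) stop(path, ": negative expression values")
  m
}

#' @rdname read_expression
#' @param mat matrix to write.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Write the full set of pipeline input files for a simulated cohort
#'
#' Materialises the exact TSV/BED inputs the pipeline reads -- raw calls,
#' chromosome info, sample metadata, gene BED, expression matrices -- plus
#' the truth table for evaluation.
#'
#' @param cohort a [generate_cohort()] result.
#' @param calls raw calls from [emulate_callers()].
#' @param dir output directory (created if needed).
#' @param expr optional `expr_set` from [generate_expression()].
#' @return named character vector of written paths.
#' @export
write_cohort_inputs <- function(cohort, calls, dir, expr = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    chrom_info = file.path(dir, "chrom_info.tsv"),
    meta = file.path(dir, "sample_meta.tsv"),
    calls = file.path(dir, "raw_calls.tsv"),
    truth = file.path(dir, "truth_cnvs.tsv")
  )
  write_chrom_info(cohort$chroms, paths["chrom_info"])
  .write_tsv(cohort$meta, paths["meta"])
  write_cnv_table(calls[, c("sample_id", "caller_id", "chrom", "start",
                            "end", "type", "confidence")], paths["calls"])
  write_cnv_table(cohort$truth, paths["truth"])
  if (!is.null(expr)) {
    paths <- c(paths,
               genes = file.path(dir, "genes.bed"),
               counts = file.path(dir, "expression_counts.tsv"),
               fpkm = file.path(dir, "expression_fpkm.tsv"))
    write_gene_bed(expr$genes, paths["genes"])
    write_expression(expr$counts, paths["counts"])
    write_expression(expr$fpkm, paths["fpkm"])
  }
  paths
}
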