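#' Chromosome information table
#'
#' Constructs and validates the chromosome table that anchors all coordinate
#' arithmetic: chromosome name, length in bp, and the centre of the centromere
#' in bp. Pericentromeric and subtelomeric windows are derived from these
#' three fields. Only autosomes belong in this table; every interval the
#' pipeline touches must live on one of its chromosomes.
#'
#' @param chrom character vector of unique chromosome labels.
#' @param length_bp integer vector of chromosome lengths (bp, > 0).
#' @param centromere_center_bp integer vector of centromere centre positions,
#'   each within `[0, length_bp]`.
#' @return a `data.frame` with columns `chrom`, `length_bp`,
#'   `centromere_center_bp`, of class `chrom_info`.
#' @examples
#' chrom_info(c("chr1", "chr2"), c(150e6, 120e6), c(60e6, 40e6))
#' @export
chrom_info <- function(chrom, length_bp, centromere_center_bp) {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  centromere_center_bp <- as.numeric(centromere_center_bp)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (any(centromere_center_bp < 0) || any(centromere_center_bp > length_bp)) {
    stop("centromere centre must lie within [0, length_bp]")
  }
  out <- data.frame(
    chrom = chrom,
    length_bp = length_bp,
    centromere_center_bp = centromere_center_bp,
    stringsAsFactors = FALSE
  )
  class(out) <- c("chrom_info", "data.frame")
  out
}

.assert_chrom_info <- function(chroms) {
  if (!inherits(chroms, "chrom_info")) {
    if (is.data.frame(chroms) &&
        all(c("chrom", "length_bp", "centromere_center_bp") %in% names(chroms))) {
      return(chrom_info(chroms$chrom, chroms$length_bp, chroms$centromere_center_bp))
    }
    stop("expected a chrom_info table (chrom, length_bp, centromere_center_bp)")
  }
  chroms
}

# Internal coordinates are 0-based half-open [start, end). All arithmetic in
# this file assumes that convention; conversion from the 1-based inclusive
# dialect of CNV tables happens at I/O.

.check_intervals <- function(start, end, what = "interval") {
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop(what, ": coordinates must be finite")
  }
  if (any(end <= start)) stop(what, ": end must exceed start (zero-length not allowed)")
  invisible(TRUE)
}

#' Overlap length of two genomic intervals
#'
#' Vectorised overlap in bp between intervals `a` and `b` (0-based
#' half-open). Intervals on different chromosomes overlap by 0.
#'
#' @param chrom_a,start_a,end_a first interval(s).
#' @param chrom_b,start_b,end_b second interval(s).
#' @return numeric vector of overlap lengths in bp (>= 0).
#' @export
overlap_bp <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ov[as.character(chrom_a) != as.character(chrom_b)] <- 0
  ov
}

#' Reciprocal overlap fraction
#'
#' `min(overlap/len(a), overlap/len(b))`: the mutual-coverage criterion used
#' to decide that two parallel calls identify the same event. Symmetric; 0
#' for disjoint intervals; 1 for identical ones.
#'
#' @inheritParams overlap_bp
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  .check_intervals(start_a, end_a, "a")
  .check_intervals(start_b, end_b, "b")
  ov <- overlap_bp(chrom_a, start_a, end_a, chrom_b, start_b, end_b)
  pmin(ov / (end_a - start_a), ov / (end_b - start_b))
}

#' Maximum-coverage overlap fraction
#'
#' `max(overlap/len(a), overlap/len(b))`: the "40% coverage of at least one
#' of the involved CNVs" criterion used for CNV-region clustering, where a
#' small CNV fully contained in a large one counts as overlapping.
#'
#' @inheritParams overlap_bp
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
max_fraction_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  .check_intervals(start_a, end_a, "a")
  .check_intervals(start_b, end_b, "b")
  ov <- overlap_bp(chrom_a, start_a, end_a, chrom_b, start_b, end_b)
  pmax(ov / (end_a - start_a), ov / (end_b - start_b))
}

#' Pericentromeric / subtelomeric context windows for one chromosome
#'
#' The subtelomeric windows are the proximal segments at both chromosome ends
#' covering `window_frac` of the chromosome length each; the pericentromeric
#' window extends to both sides of the centromere centre by `window_frac` of
#' the chromosome length (clipped at the chromosome boundaries, so an
#' acrocentric chromosome gets a one-sided window).
#'
#' @param chrom_row one row of a [chrom_info()] table.
#' @param window_frac window size as a fraction of chromosome length
#'   (default 0.05); must lie in (0, 0.5).
#' @return list with `w` (window size bp), `subtel` (2x2 matrix of windows),
#'   `peri` (length-2 window).
#' @keywords internal
.region_windows <- function(chrom_row, window_frac = 0.05) {
  if (window_frac <= 0 || window_frac >= 0.5) stop("window_frac must be in (0, 0.5)")
  L <- chrom_row$length_bp
  cc <- chrom_row$centromere_center_bp
  w <- round(window_frac * L)
  list(
    w = w,
    subtel = rbind(c(0, w), c(L - w, L)),
    peri = c(max(0, cc - w), min(L, cc + w))
  )
}

#' Classify genomic context of intervals
#'
#' Flags each interval as pericentromeric and/or subtelomeric by any-overlap
#' (>= 1 bp) with the context windows of its chromosome, and assigns a single
#' `primary_label` with pericentromeric > subtelomeric > interstitial
#' precedence (so a CNV touching both windows is counted once).
#'
#' @param chrom,start,end interval(s), 0-based half-open.
#' @param chroms a [chrom_info()] table covering every `chrom`.
#' @param window_frac fraction of chromosome length per window side
#'   (default 0.05).
#' @return data.frame with logical columns `pericentromeric`,
#'   `subtelomeric` and character `primary_label`.
#' @examples
#' ci <- chrom_info("chr1", 100e6, 40e6)
#' classify_region("chr1", 36e6, 37e6, ci)$primary_label  # pericentromeric
#' @export
classify_region <- function(chrom, start, end, chroms, window_frac = 0.05) {
  chroms <- .assert_chrom_info(chroms)
  .check_intervals(start, end)
  chrom <- as.character(chrom)
  idx <- match(chrom, chroms$chrom)
  if (anyNA(idx)) stop("unknown chromosome: ", paste(unique(chrom[is.na(idx)]), collapse = ", "))
  L <- chroms$length_bp[idx]
  if (any(start < 0) || any(end > L)) stop("interval extends beyond chromosome bounds")
  cc <- chroms$centromere_center_bp[idx]
  w <- round(window_frac * L)
  if (window_frac <= 0 || window_frac >= 0.5) stop("window_frac must be in (0, 0.5)")
  hit <- function(ws, we) pmin(end, we) - pmax(start, ws) > 0
  subtel <- hit(0, w) | hit(L - w, L)
  peri <- hit(pmax(0, cc - w), pmin(L, cc + w))
  data.frame(
    pericentromeric = peri,
    subtelomeric = subtel,
    primary_label = ifelse(peri, "pericentromeric",
                           ifelse(subtel, "subtelomeric", "interstitial")),
    stringsAsFactors = FALSE
  )
}
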