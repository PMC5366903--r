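#' Per-sample CNV burden summary
#'
#' Counts consensus CNVs and their cumulative genomic span (in Mb) overall
#' and by type (duplication / deletion) for one sample.
#'
#' @param cnvs consensus CNVs of one sample.
#' @param sample_id the sample; CNVs from another sample are an error.
#' @return 1-row data.frame: `sample_id`, `n_all`, `n_dup`, `n_del`,
#'   `span_all_mb`, `span_dup_mb`, `span_del_mb`.
#' @export
summarize_burden <- function(cnvs, sample_id) {
  if (nrow(cnvs) > 0) {
    .assert_cols(cnvs, c("sample_id", "start", "end", "type"), "cnvs")
    if (any(cnvs$sample_id != sample_id)) stop("cnvs from a different sample")
    .assert_type(cnvs$type)
  }
  len_mb <- if (nrow(cnvs)) (cnvs$end - cnvs$start) / 1e6 else numeric(0)
  dup <- if (nrow(cnvs)) cnvs$type == "dup" else logical(0)
  data.frame(
    sample_id = sample_id,
    n_all = nrow(cnvs),
    n_dup = sum(dup),
    n_del = sum(!dup),
    span_all_mb = sum(len_mb),
    span_dup_mb = sum(len_mb[dup]),
    span_del_mb = sum(len_mb[!dup]),
    stringsAsFactors = FALSE
  )
}

#' Burden table across samples
#'
#' One [summarize_burden()] row per sample. Samples listed in `sample_ids`
#' but absent from `cnvs` get all-zero rows (a genotyped sample with no
#' consensus CNVs still counts in group medians).
#'
#' @param cnvs consensus CNVs across samples.
#' @param sample_ids samples to summarise (default: those present in `cnvs`).
#' @return data.frame, one row per sample.
#' @export
burden_table <- function(cnvs, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sort(unique(as.character(cnvs$sample_id)))
  out <- do.call(rbind, lapply(sample_ids, function(s) {
    summarize_burden(cnvs[cnvs$sample_id == s, , drop = FALSE], s)
  }))
  rownames(out) <- NULL
  out
}

#' Percent change of a median relative to a reference
#'
#' `100 * (reference - comparison) / reference`, the reduction (positive) or
#' increase (negative) of `comparison_median` relative to
#' `reference_median`. Reported rounded to the nearest integer percent via
#' `round_pct = TRUE` (the display convention), raw otherwise.
#'
#' @param reference_median reference value (> 0).
#' @param comparison_median value compared against the reference.
#' @param round_pct round to integer percent (default `TRUE`).
#' @return percent change.
#' @examples
#' percent_change(15, 9)  # 40
#' percent_change(31, 9)  # 71
#' @export
percent_change <- function(reference_median, comparison_median, round_pct = TRUE) {
  if (!is.finite(reference_median) || reference_median <= 0) {
    stop("reference_median must be > 0")
  }
  pc <- 100 * (reference_median - comparison_median) / reference_median
  if (round_pct) round(pc) else pc
}

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk normality is assessed in each group; when both groups pass at
#' `alpha_normality` (and both have at least 3 non-constant values, the
#' smallest size Shapiro-Wilk accepts), the groups are compared by Welch's
#' two-sample t-test, otherwise by the two-sided Wilcoxon rank-sum test
#' (exact when both n < 50 with no ties, else normal approximation with tie
#' and continuity correction -- the standard `wilcox.test` behaviour).
#' Constant groups fall through to Wilcoxon.
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @param alpha_normality gate alpha (default 0.05).
#' @param labels length-2 character labels for reporting.
#' @return object of class `group_comparison`: list with per-group `n`,
#'   `median`, `range`, `shapiro_p`, plus `normal_gate` (logical per group),
#'   `test_used` ("welch_t" or "wilcoxon_rank_sum") and `p_value`.
#' @export
compare_groups <- function(values_a, values_b, alpha_normality = 0.05,
                           labels = c("A", "B")) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values")
  }
  shapiro_p <- function(x) {
    if (length(x) < 3 || length(x) > 5000 || length(unique(x)) < 2) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  sp <- c(shapiro_p(values_a), shapiro_p(values_b))
  gate <- !is.na(sp) & sp > alpha_normality
  use_welch <- all(gate) &&
    stats::sd(values_a) > 0 && stats::sd(values_b) > 0
  if (use_welch) {
    p <- stats::t.test(values_a, values_b)$p.value
    test_used <- "welch_t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(values_a, values_b))$p.value
    test_used <- "wilcoxon_rank_sum"
  }
  structure(list(
    labels = labels,
    n = c(length(values_a), length(values_b)),
    median = c(stats::median(values_a), stats::median(values_b)),
    range = rbind(range(values_a), range(values_b)),
    shapiro_p = sp,
    normal_gate = gate,
    test_used = test_used,
    p_value = p
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(i) sprintf("%s: n=%d, median %.3g (%.3g-%.3g)",
                             x$labels[i], x$n[i], x$median[i],
                             x$range[i, 1], x$range[i, 2])
  cat(fmt(1), "\n", fmt(2), "\n", sep = "")
  cat(sprintf("test: %s (normality gate %s), p = %.3g\n",
              x$test_used,
              if (all(x$normal_gate)) "passed" else "failed", x$p_value))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value for a 2x2 contingency table: with margins fixed,
#' the sum of hypergeometric probabilities of all tables whose point
#' probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(46, 7, 85, 124), nrow = 2))  # ~1.1e-9
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("entries must be nonnegative integers")
  }
  if (sum(table) == 0) stop("at least one margin must be positive")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Large-CNV genomic-context profile per group
#'
#' For each group's samples (by default the parental blood samples), counts
#' all CNVs, those longer than `size_threshold_bp`, and -- among the large
#' ones -- those whose primary genomic context is pericentromeric or
#' subtelomeric ([classify_region()] with pericentromeric precedence, so
#' each CNV is counted once). Reports per-genome rates and percentages.
#'
#' @param cnvs consensus CNVs across samples.
#' @param meta sample metadata (`sample_id`, `group`, `tissue`).
#' @param chroms a [chrom_info()] table.
#' @param groups groups to profile (default: all in `meta` after the tissue
#'   filter).
#' @param tissue restrict to this tissue (default "blood"; `NULL` for all).
#' @param size_threshold_bp large-CNV floor, exclusive (default 300000).
#' @param window_frac context window fraction (default 0.05).
#' @return data.frame, one row per group: `group`, `n_samples`, `n_all`,
#'   `rate_all` (CNVs per genome), `n_large`, `rate_large`, `percent_large`,
#'   `n_peri_large`, `rate_peri_large`, `n_subtel_large`, `rate_subtel_large`,
#'   `percent_peri_subtel_of_large`.
#' @export
large_cnv_profile <- function(cnvs, meta, chroms, groups = NULL,
                              tissue = "blood", size_threshold_bp = 300000,
                              window_frac = 0.05) {
  .assert_cols(meta, c("sample_id", "group"), "meta")
  if (!is.null(tissue)) {
    .assert_cols(meta, "tissue", "meta")
    meta <- meta[meta$tissue == tissue, , drop = FALSE]
  }
  if (is.null(groups)) groups <- unique(as.character(meta$group))
  if (length(groups) == 0) stop("no samples in any group")
  rows <- lapply(groups, function(g) {
    samp <- meta$sample_id[meta$group == g]
    if (length(samp) == 0) stop("no samples in group ", g)
    x <- cnvs[cnvs$sample_id %in% samp, , drop = FALSE]
    n_all <- nrow(x)
    large <- x[(x$end - x$start) > size_threshold_bp, , drop = FALSE]
    n_large <- nrow(large)
    if (n_large > 0) {
      rc <- classify_region(large$chrom, large$start, large$end, chroms,
                            window_frac)
      n_peri <- sum(rc$primary_label == "pericentromeric")
      n_subtel <- sum(rc$primary_label == "subtelomeric")
    } else {
      n_peri <- 0L; n_subtel <- 0L
    }
    ns <- length(samp)
    data.frame(
      group = g, n_samples = ns,
      n_all = n_all, rate_all = n_all / ns,
      n_large = n_large, rate_large = n_large / ns,
      percent_large = if (n_all) 100 * n_large / n_all else 0,
      n_peri_large = n_peri, rate_peri_large = n_peri / ns,
      n_subtel_large = n_subtel, rate_subtel_large = n_subtel / ns,
      percent_peri_subtel_of_large =
        if (n_large) 100 * (n_peri + n_subtel) / n_large else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
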