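#' Filter raw calls on a caller's confidence statistic
#'
#' Removes calls from one caller whose confidence (e.g. a log Bayes Factor)
#' falls strictly below `min_conf`. Only the named caller is filtered: calls
#' from other callers, and calls lacking a confidence value, pass unchanged.
#' Row order is preserved.
#'
#' @param calls data.frame of raw calls with columns `sample_id`, `caller_id`,
#'   `chrom`, `start`, `end`, `type` and optionally `confidence`.
#' @param caller_id the confidence-reporting caller.
#' @param min_conf confidence floor; calls with `confidence < min_conf` are
#'   dropped (default 5, the conventional log Bayes Factor cut-off).
#' @return the filtered calls data.frame.
#' @export
filter_by_confidence <- function(calls, caller_id, min_conf = 5) {
  .assert_cols(calls, c("sample_id", "caller_id", "chrom", "start", "end", "type"),
               "calls")
  if (!"confidence" %in% names(calls)) return(calls)
  drop <- calls$caller_id == caller_id &
    !is.na(calls$confidence) &
    calls$confidence < min_conf
  calls[!drop, , drop = FALSE]
}

#' Build per-sample consensus CNVs from parallel caller calls
#'
#' Two same-type calls on one sample are deemed to identify the same event
#' when their reciprocal overlap is at least `min_reciprocal`. Calls are
#' merged by single linkage over such pairs; every connected component backed
#' by at least `min_callers` distinct callers becomes one consensus CNV whose
#' interval is the union span of its members (the intersection span of the
#' pairwise-overlapping core is kept for diagnostics). Components supported
#' by fewer callers are discarded.
#'
#' @param calls data.frame of (already confidence-filtered) raw calls for one
#'   sample: `sample_id`, `caller_id`, `chrom`, `start`, `end`, `type`.
#' @param sample_id the sample the calls belong to; calls from any other
#'   sample are an error.
#' @param min_reciprocal reciprocal-overlap threshold (default 0.4,
#'   inclusive).
#' @param min_callers minimum number of distinct supporting callers
#'   (default 2).
#' @return data.frame of consensus CNVs ordered by (chrom, start, end, type):
#'   `sample_id`, `chrom`, `start`, `end`, `type`, `length_bp`, `n_callers`,
#'   `callers` (comma-joined, sorted), `n_members`, `intersect_start`,
#'   `intersect_end` (NA when members do not share a common core).
#' @export
build_consensus <- function(calls, sample_id, min_reciprocal = 0.4, min_callers = 2) {
  .assert_cols(calls, c("sample_id", "caller_id", "chrom", "start", "end", "type"),
               "calls")
  if (nrow(calls) > 0 && any(calls$sample_id != sample_id)) {
    stop("calls from a different sample than ", sample_id)
  }
  .assert_type(calls$type)
  empty <- data.frame(
    sample_id = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), type = character(0), length_bp = numeric(0),
    n_callers = integer(0), callers = character(0), n_members = integer(0),
    intersect_start = numeric(0), intersect_end = numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(calls) == 0) return(empty)
  .check_intervals(calls$start, calls$end, "calls")

  cl <- .cluster_intervals(calls, min_reciprocal, rule = "reciprocal")
  keep <- vapply(split(seq_len(nrow(calls)), cl), function(ix) {
    length(unique(calls$caller_id[ix])) >= min_callers
  }, logical(1))
  comp_ids <- as.integer(names(keep))[keep]
  if (length(comp_ids) == 0) return(empty)

  rows <- lapply(comp_ids, function(k) {
    ix <- which(cl == k)
    is_ <- max(calls$start[ix]); ie <- min(calls$end[ix])
    data.frame(
      sample_id = sample_id,
      chrom = calls$chrom[ix][1L],
      start = min(calls$start[ix]),
      end = max(calls$end[ix]),
      type = calls$type[ix][1L],
      length_bp = max(calls$end[ix]) - min(calls$start[ix]),
      n_callers = length(unique(calls$caller_id[ix])),
      callers = paste(sort(unique(as.character(calls$caller_id[ix]))), collapse = ","),
      n_members = length(ix),
      intersect_start = if (ie > is_) is_ else NA_real_,
      intersect_end = if (ie > is_) ie else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build consensus CNVs for every sample in a call table
#'
#' Convenience wrapper: applies [filter_by_confidence()] (when a
#' confidence-reporting caller is configured) and [build_consensus()] per
#' sample, then binds the results.
#'
#' @param calls raw call data.frame across samples.
#' @param min_reciprocal,min_callers passed to [build_consensus()].
#' @param confidence_caller caller whose calls are confidence-filtered, or
#'   `NULL` to skip filtering.
#' @param min_conf confidence floor for `confidence_caller`.
#' @return consensus data.frame across samples (see [build_consensus()]),
#'   ordered by (sample_id, chrom, start, end, type).
#' @export
consensus_all_samples <- function(calls, min_reciprocal = 0.4, min_callers = 2,
                                  confidence_caller = NULL, min_conf = 5) {
  if (!is.null(confidence_caller)) {
    calls <- filter_by_confidence(calls, confidence_caller, min_conf)
  }
  parts <- lapply(split(calls, calls$sample_id), function(df) {
    build_consensus(df, df$sample_id[1L], min_reciprocal, min_callers)
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0) {
    return(build_consensus(calls[0, , drop = FALSE], "none"))
  }
  out <- out[order(out$sample_id, out$chrom, out$start, out$end, out$type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
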