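#' Cluster consensus CNVs across samples into CNV regions (CNVRs)
#'
#' Same-type consensus CNVs from any samples are linked when they overlap by
#' at least `min_max_fraction` of **at least one** of the two intervals (the
#' maximum-coverage rule, so a small CNV inside a large one joins it). Every
#' connected component of this graph -- including singletons -- becomes one
#' CNVR spanning the union of its members. Each consensus CNV therefore
#' belongs to exactly one CNVR.
#'
#' @param cnvs consensus CNV data.frame (`sample_id`, `chrom`, `start`,
#'   `end`, `type`, ...), as from [consensus_all_samples()].
#' @param min_max_fraction coverage threshold (default 0.4, inclusive).
#' @param meta optional sample metadata (`sample_id`, `group`) used to fill
#'   per-CNVR group sets.
#' @param count_singletons keep single-member components as CNVRs
#'   (default `TRUE`); when `FALSE`, singletons are dropped from the region
#'   table (their members are reported with `cnvr_id` `NA`).
#' @return object of class `cnvr_set`: a list with `cnvrs` (one row per
#'   region: `cnvr_id`, `chrom`, `start`, `end`, `type`, `n_members`,
#'   `n_samples`, `groups`, `sample_ids`) and `members` (the input `cnvs`
#'   with a `cnvr_id` column).
#' @export
build_cnvrs <- function(cnvs, min_max_fraction = 0.4, meta = NULL,
                        count_singletons = TRUE) {
  .assert_cols(cnvs, c("sample_id", "chrom", "start", "end", "type"), "cnvs")
  .assert_type(cnvs$type)
  members <- as.data.frame(cnvs, stringsAsFactors = FALSE)
  if (nrow(members) == 0) {
    cnvrs <- data.frame(
      cnvr_id = character(0), chrom = character(0), start = numeric(0),
      end = numeric(0), type = character(0), n_members = integer(0),
      n_samples = integer(0), groups = character(0), sample_ids = character(0),
      stringsAsFactors = FALSE
    )
    members$cnvr_id <- character(0)
    return(structure(list(cnvrs = cnvrs, members = members), class = "cnvr_set"))
  }
  .check_intervals(members$start, members$end, "cnvs")
  cl <- .cluster_intervals(members, min_max_fraction, rule = "max")
  grp_of <- NULL
  if (!is.null(meta)) {
    .assert_cols(meta, c("sample_id", "group"), "meta")
    grp_of <- stats::setNames(as.character(meta$group), meta$sample_id)
  }
  ids <- sort(unique(cl))
  rows <- lapply(ids, function(k) {
    ix <- which(cl == k)
    samp <- sort(unique(as.character(members$sample_id[ix])))
    grps <- if (is.null(grp_of)) character(0) else sort(unique(grp_of[samp]))
    data.frame(
      cnvr_id = sprintf("CNVR%05d", k),
      chrom = members$chrom[ix][1L],
      start = min(members$start[ix]),
      end = max(members$end[ix]),
      type = members$type[ix][1L],
      n_members = length(ix),
      n_samples = length(samp),
      groups = paste(grps, collapse = ","),
      sample_ids = paste(samp, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  cnvrs <- do.call(rbind, rows)
  members$cnvr_id <- sprintf("CNVR%05d", cl)
  if (!count_singletons) {
    single <- cnvrs$cnvr_id[cnvrs$n_members < 2]
    members$cnvr_id[members$cnvr_id %in% single] <- NA_character_
    cnvrs <- cnvrs[cnvrs$n_members >= 2, , drop = FALSE]
  }
  rownames(cnvrs) <- NULL
  structure(list(cnvrs = cnvrs, members = members), class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat("cnvr_set:", nrow(x$cnvrs), "CNVRs from", nrow(x$members),
      "consensus CNVs across", length(unique(x$members$sample_id)), "samples\n")
  if (nrow(x$cnvrs)) {
    cat("  types:", paste(names(table(x$cnvrs$type)),
                          table(x$cnvrs$type), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cross-group CNVR sharing summary
#'
#' For a focal group, counts the CNVRs carried by at least one focal sample
#' (the group's CNVR pool), how many of those are co-carried by each other
#' group (co-membership in one CNVR, the Venn-diagram construction), how many
#' are unique to the focal group, and the per-sample CNVR rate
#' (pool size / number of focal samples).
#'
#' @param cnvr_set a [build_cnvrs()] result.
#' @param meta sample metadata with `sample_id`, `group`.
#' @param focal_group group whose pool is summarised.
#' @param other_groups groups to compute sharing against (default: all other
#'   groups present in `meta`).
#' @return list with `focal_group`, `n_samples`, `pool_size`,
#'   `per_sample_rate`, `shared` (named vector of shared counts per other
#'   group), `shared_fraction` (same, / pool), `n_unique` (CNVRs carried by
#'   no listed other group) and `unique_fraction`.
#' @export
sharing_summary <- function(cnvr_set, meta, focal_group, other_groups = NULL) {
  stopifnot(inherits(cnvr_set, "cnvr_set"))
  .assert_cols(meta, c("sample_id", "group"), "meta")
  if (is.null(other_groups)) {
    other_groups <- setdiff(unique(as.character(meta$group)), focal_group)
  }
  focal_samples <- meta$sample_id[meta$group == focal_group]
  if (length(focal_samples) == 0) stop("no samples in focal group ", focal_group)
  m <- cnvr_set$members[!is.na(cnvr_set$members$cnvr_id), , drop = FALSE]
  grp_of <- stats::setNames(as.character(meta$group), meta$sample_id)
  m$group <- grp_of[as.character(m$sample_id)]
  pool <- unique(m$cnvr_id[m$group %in% focal_group])
  shared <- vapply(other_groups, function(g) {
    length(intersect(pool, unique(m$cnvr_id[m$group == g])))
  }, integer(1))
  names(shared) <- other_groups
  any_other <- unique(m$cnvr_id[m$group %in% other_groups])
  n_unique <- length(setdiff(pool, any_other))
  list(
    focal_group = focal_group,
    n_samples = length(focal_samples),
    pool_size = length(pool),
    per_sample_rate = length(pool) / length(focal_samples),
    shared = shared,
    shared_fraction = if (length(pool)) shared / length(pool) else shared * NA_real_,
    n_unique = n_unique,
    unique_fraction = if (length(pool)) n_unique / length(pool) else NA_real_
  )
}

#' Assign inheritance status to a placental consensus CNV
#'
#' A placental CNV is labelled inherited when a same-type parental consensus
#' CNV from the same family matches it at reciprocal overlap at or above
#' `min_reciprocal` (the same threshold the consensus step uses). With both
#' parents genotyped and neither matching, the CNV is somatic; with one
#' parent missing the complement is disjunctive ("paternal_or_somatic" when
#' only the mother was profiled, and vice versa); with no family link the
#' status is unknown.
#'
#' @param cnv one placental consensus CNV (1-row data.frame or list with
#'   `chrom`, `start`, `end`, `type`).
#' @param family_meta metadata rows for the CNV's family (`sample_id`,
#'   `role` in mother/father/placenta).
#' @param parental_cnvs consensus CNVs of the family's parental samples.
#' @param min_reciprocal matching threshold (default 0.4).
#' @return one of "maternal", "paternal", "somatic", "maternal_or_somatic",
#'   "paternal_or_somatic", "unknown".
#' @export
annotate_inheritance <- function(cnv, family_meta, parental_cnvs,
                                 min_reciprocal = 0.4) {
  mother <- family_meta$sample_id[family_meta$role == "mother"]
  father <- family_meta$sample_id[family_meta$role == "father"]
  if (length(mother) == 0 && length(father) == 0) return("unknown")
  matches <- function(parent_ids) {
    p <- parental_cnvs[parental_cnvs$sample_id %in% parent_ids &
                         parental_cnvs$type == cnv$type, , drop = FALSE]
    if (nrow(p) == 0) return(FALSE)
    any(reciprocal_overlap(cnv$chrom, cnv$start, cnv$end,
                           p$chrom, p$start, p$end) >= min_reciprocal)
  }
  if (length(mother) && matches(mother)) return("maternal")
  if (length(father) && matches(father)) return("paternal")
  if (length(mother) && length(father)) return("somatic")
  if (length(mother)) return("paternal_or_somatic")
  "maternal_or_somatic"
}
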