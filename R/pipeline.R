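#' Pipeline configuration
#'
#' Bundles the input locations (paths or in-memory objects) and every
#' threshold of the analysis. Defaults are the conventional values: 40%
#' reciprocal overlap and at least 2 callers for consensus, 40%
#' coverage-of-at-least-one for CNVR clustering, a confidence floor of 5
#' for the confidence-reporting caller, a 300 kb large-CNV threshold, 5%
#' context windows and a 0.05 normality-gate alpha.
#'
#' @param calls raw calls: data.frame or TSV path.
#' @param chroms chromosome table: [chrom_info()] or TSV path.
#' @param meta sample metadata: data.frame or TSV path.
#' @param genes optional gene annotation: data.frame or BED path.
#' @param counts optional raw-count matrix (or TSV path) for the carrier
#'   z-score analysis.
#' @param fpkm optional FPKM matrix (or TSV path) for the median-expression
#'   comparison.
#' @param min_reciprocal,min_callers consensus thresholds.
#' @param confidence_caller,min_conf confidence filter (set
#'   `confidence_caller = NULL` to skip).
#' @param cnvr_min_max_fraction CNVR clustering threshold.
#' @param count_singletons singleton components are CNVRs (default `TRUE`).
#' @param large_cnv_bp large-CNV length threshold (exclusive).
#' @param window_frac pericentromeric/subtelomeric window fraction.
#' @param alpha_normality normality-gate alpha for group comparisons.
#' @param output_dir optional directory for TSV/JSON outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(calls, chroms, meta, genes = NULL, counts = NULL,
                            fpkm = NULL,
                            min_reciprocal = 0.4, min_callers = 2,
                            confidence_caller = "callerA", min_conf = 5,
                            cnvr_min_max_fraction = 0.4,
                            count_singletons = TRUE,
                            large_cnv_bp = 300000, window_frac = 0.05,
                            alpha_normality = 0.05, output_dir = NULL) {
  stopifnot(min_reciprocal > 0, min_reciprocal <= 1,
            cnvr_min_max_fraction > 0, cnvr_min_max_fraction <= 1,
            min_callers >= 1, large_cnv_bp > 0,
            window_frac > 0, window_frac < 0.5,
            alpha_normality > 0, alpha_normality < 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML holds input paths under `inputs:` (calls, chroms, meta, genes,
#' counts, fpkm) and any subset of the threshold names of
#' [pipeline_config()] under `thresholds:`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- c(y$inputs, y$thresholds)
  do.call(pipeline_config, args)
}

.load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

#' Run the full CNV analysis pipeline
#'
#' Sequences the stages: confidence filter, per-sample consensus, burden
#' summaries and Shapiro-Wilk gated group comparisons (CNV counts and
#' cumulative spans, per tissue), per-tissue CNVR clustering, cross-group
#' sharing summaries, the large-CNV pericentromeric/subtelomeric profile of
#' the blood (parental) samples, and -- when expression inputs are present
#' -- the CNV-gene classification with median-FPKM comparisons and the
#' pooled carrier z-score analysis on median-of-ratios normalized counts.
#' Deterministic for fixed inputs; a self-audit recomputes every derived
#' percentage in the report from its own counts.
#'
#' @param config a [pipeline_config()].
#' @return object of class `cnv_report`.
#' @export
run_cnv_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  chroms <- stage("inputs", .load_input(config$chroms, read_chrom_info))
  calls <- stage("inputs", .load_input(config$calls, read_cnv_calls, chroms))
  meta <- stage("inputs", .load_input(config$meta, read_sample_meta))
  genes <- if (is.null(config$genes)) NULL else
    stage("inputs", .load_input(config$genes, read_gene_bed, chroms))
  counts <- if (is.null(config$counts)) NULL else
    stage("inputs", .load_input(config$counts, read_expression))
  fpkm <- if (is.null(config$fpkm)) NULL else
    stage("inputs", .load_input(config$fpkm, read_expression))

  log <- list(n_raw_calls = nrow(calls))
  filtered <- stage("confidence_filter", {
    if (is.null(config$confidence_caller)) calls else
      filter_by_confidence(calls, config$confidence_caller, config$min_conf)
  })
  log$n_filtered_out <- nrow(calls) - nrow(filtered)

  consensus <- stage("consensus", consensus_all_samples(
    filtered, config$min_reciprocal, config$min_callers,
    confidence_caller = NULL))
  log$n_consensus <- nrow(consensus)

  burden <- stage("burden", burden_table(consensus, meta$sample_id))

  tissues <- unique(meta$tissue)
  comparisons <- list()
  cnvrs <- list()
  sharing <- list()
  for (tis in tissues) {
    m <- meta[meta$tissue == tis, , drop = FALSE]
    b <- burden[burden$sample_id %in% m$sample_id, , drop = FALSE]
    grp <- stats::setNames(as.character(m$group), m$sample_id)
    groups <- unique(grp)
    if (length(groups) >= 2) {
      for (metric in c("n_all", "span_all_mb")) {
        pairs <- utils::combn(groups, 2, simplify = FALSE)
        for (pr in pairs) {
          va <- b[[metric]][grp[b$sample_id] == pr[1]]
          vb <- b[[metric]][grp[b$sample_id] == pr[2]]
          if (length(va) >= 2 && length(vb) >= 2) {
            key <- paste(tis, metric, pr[1], "vs", pr[2], sep = ".")
            comparisons[[key]] <- stage("group_comparison",
              compare_groups(va, vb, config$alpha_normality, labels = pr))
          }
        }
      }
    }
    cs <- stage("cnvr", build_cnvrs(
      consensus[consensus$sample_id %in% m$sample_id, , drop = FALSE],
      config$cnvr_min_max_fraction, meta = m,
      count_singletons = config$count_singletons))
    cnvrs[[tis]] <- cs
    sharing[[tis]] <- lapply(stats::setNames(groups, groups), function(g) {
      stage("sharing", sharing_summary(cs, m, g))
    })
  }
  log$n_cnvrs <- vapply(cnvrs, function(x) nrow(x$cnvrs), integer(1))

  large_profile <- NULL
  if ("blood" %in% tissues) {
    large_profile <- stage("large_cnv_profile", large_cnv_profile(
      consensus, meta, chroms, tissue = "blood",
      size_threshold_bp = config$large_cnv_bp,
      window_frac = config$window_frac))
  }

  expression <- NULL
  if (!is.null(genes) && (!is.null(fpkm) || !is.null(counts))) {
    expression <- stage("expression", {
      pl_cnvrs <- if ("placenta" %in% names(cnvrs)) cnvrs[["placenta"]] else
        cnvrs[[1]]
      cls <- classify_genes(genes, pl_cnvrs)
      res <- list(classes = cls, class_counts = table(cls$cnv_class))
      if (!is.null(fpkm)) {
        med <- apply(fpkm[intersect(rownames(fpkm), genes$gene_id), ,
                          drop = FALSE], 1, stats::median)
        cl_of <- stats::setNames(cls$cnv_class, cls$gene_id)[names(med)]
        res$median_fpkm <- med
        res$cnv_vs_noncnv <- compare_median_expression(
          med[cl_of %in% c("del_only", "dup_only", "both")],
          med[cl_of == "non_cnv"])
        if (any(cl_of == "del_only")) {
          res$del_vs_noncnv <- compare_median_expression(
            med[cl_of == "del_only"], med[cl_of == "non_cnv"])
        }
        if (any(cl_of == "dup_only")) {
          res$dup_vs_noncnv <- compare_median_expression(
            med[cl_of == "dup_only"], med[cl_of == "non_cnv"])
        }
      }
      if (!is.null(counts)) {
        sf <- size_factors(counts)
        norm <- normalize_counts(counts, sf)
        members <- pl_cnvrs$members
        cnv_genes <- cls$gene_id[cls$cnv_class != "non_cnv"]
        gsub_ <- genes[genes$gene_id %in% cnv_genes, , drop = FALSE]
        carrier_map <- lapply(stats::setNames(gsub_$gene_id, gsub_$gene_id),
                              function(gid) {
          gi <- gsub_[gsub_$gene_id == gid, ]
          hit <- members$chrom == gi$chrom &
            pmin(members$end, gi$end) > pmax(members$start, gi$start)
          unique(members$sample_id[hit & members$sample_id %in% colnames(norm)])
        })
        carrier_map <- carrier_map[vapply(carrier_map, length, integer(1)) > 0]
        res$size_factors <- sf
        res$zscore_pooled <- zscore_carrier_analysis(norm, carrier_map,
                                                     mode = "pooled")
      }
      res
    })
  }

  report <- structure(list(
    consensus = consensus, burden = burden, comparisons = comparisons,
    cnvrs = cnvrs, sharing = sharing, large_profile = large_profile,
    expression = expression, log = log, meta = meta, chroms = chroms,
    config = config,
    provenance = list(package_version = as.character(utils::packageVersion("cnvburden")))
  ), class = "cnv_report")
  stage("audit", .audit_report(report))
  if (!is.null(config$output_dir)) stage("write", write_report(report))
  report
}

# Internal consistency audit: derived fractions must equal recomputation
# from the report's own counts.
.audit_report <- function(report) {
  ok <- TRUE
  b <- report$burden
  stopifnot(all(b$n_all == b$n_dup + b$n_del),
            all(abs(b$span_all_mb - (b$span_dup_mb + b$span_del_mb)) < 1e-9))
  if (!is.null(report$large_profile)) {
    lp <- report$large_profile
    stopifnot(all(abs(lp$rate_all - lp$n_all / lp$n_samples) < 1e-9),
              all(lp$n_large <= lp$n_all),
              all(lp$n_peri_large + lp$n_subtel_large <= lp$n_large))
    recomputed <- ifelse(lp$n_all > 0, 100 * lp$n_large / lp$n_all, 0)
    stopifnot(all(abs(lp$percent_large - recomputed) < 1e-9))
  }
  for (tis in names(report$sharing)) {
    for (s in report$sharing[[tis]]) {
      stopifnot(abs(s$per_sample_rate - s$pool_size / s$n_samples) < 1e-9)
    }
  }
  invisible(ok)
}

#' Write a pipeline report's tables to disk
#'
#' @param report a `cnv_report`.
#' @param dir output directory (default: the config's `output_dir`).
#' @return named vector of written paths.
#' @export
write_report <- function(report, dir = report$config$output_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    consensus = file.path(dir, "consensus_cnvs.tsv"),
    burden = file.path(dir, "burden_per_sample.tsv"),
    comparisons = file.path(dir, "group_comparisons.json")
  )
  write_cnv_table(report$consensus, paths["consensus"])
  .write_tsv(report$burden, paths["burden"])
  comp <- lapply(report$comparisons, function(x) {
    list(labels = x$labels, n = x$n, median = x$median,
         test_used = x$test_used, p_value = x$p_value)
  })
  jsonlite::write_json(comp, paths["comparisons"], auto_unbox = TRUE,
                       digits = NA)
  for (tis in names(report$cnvrs)) {
    p <- file.path(dir, paste0("cnvrs_", tis, ".tsv"))
    write_cnv_table(report$cnvrs[[tis]]$cnvrs, p)
    paths[paste0("cnvrs_", tis)] <- p
  }
  if (!is.null(report$large_profile)) {
    paths["large_profile"] <- file.path(dir, "large_cnv_profile.tsv")
    .write_tsv(report$large_profile, paths["large_profile"])
  }
  invisible(paths)
}

#' @export
print.cnv_report <- function(x, ...) {
  cat("cnv_report\n")
  cat(sprintf("  raw calls: %d (%d removed by confidence filter)\n",
              x$log$n_raw_calls, x$log$n_filtered_out))
  cat(sprintf("  consensus CNVs: %d across %d samples\n",
              x$log$n_consensus, length(unique(x$consensus$sample_id))))
  for (tis in names(x$cnvrs)) {
    cat(sprintf("  %s CNVRs: %d\n", tis, nrow(x$cnvrs[[tis]]$cnvrs)))
  }
  if (!is.null(x$large_profile)) {
    cat("  large-CNV profile groups:",
        paste(x$large_profile$group, collapse = ", "), "\n")
  }
  if (!is.null(x$expression)) {
    cat("  expression classes:",
        paste(names(x$expression$class_counts), x$expression$class_counts,
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.cnv_report <- function(object, ...) {
  grp <- stats::setNames(as.character(object$meta$group),
                         object$meta$sample_id)
  tis <- stats::setNames(as.character(object$meta$tissue),
                         object$meta$sample_id)
  b <- object$burden
  agg <- stats::aggregate(
    b[, c("n_all", "n_dup", "n_del", "span_all_mb")],
    by = list(group = grp[b$sample_id], tissue = tis[b$sample_id]),
    FUN = stats::median)
  cat("Median per-sample burden by group:\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}
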