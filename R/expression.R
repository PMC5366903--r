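#' Classify genes by CNVR overlap
#'
#' Each gene is assigned exactly one class from its any-overlap (>= 1 bp)
#' with deletion and duplication CNVRs: `non_cnv` (no overlap), `del_only`,
#' `dup_only`, or `both`. Genes in the `both` class are retained in the
#' table but conventionally excluded from the del/dup subgroup comparisons.
#' Strand is ignored (CNVs are unstranded).
#'
#' @param genes gene annotation data.frame: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param cnvr_set a [build_cnvrs()] result (or a plain CNVR data.frame with
#'   `chrom`, `start`, `end`, `type`).
#' @return data.frame `gene_id`, `cnv_class`.
#' @export
classify_genes <- function(genes, cnvr_set) {
  .assert_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  if (anyDuplicated(genes$gene_id)) stop("gene_id must be unique")
  regions <- if (inherits(cnvr_set, "cnvr_set")) cnvr_set$cnvrs else cnvr_set
  hits_type <- function(tp) {
    r <- regions[regions$type == tp, , drop = FALSE]
    if (nrow(r) == 0) return(rep(FALSE, nrow(genes)))
    vapply(seq_len(nrow(genes)), function(i) {
      same <- r$chrom == genes$chrom[i]
      any(pmin(r$end[same], genes$end[i]) > pmax(r$start[same], genes$start[i]))
    }, logical(1))
  }
  in_del <- hits_type("del")
  in_dup <- hits_type("dup")
  data.frame(
    gene_id = genes$gene_id,
    cnv_class = ifelse(in_del & in_dup, "both",
                       ifelse(in_del, "del_only",
                              ifelse(in_dup, "dup_only", "non_cnv"))),
    stringsAsFactors = FALSE
  )
}

#' Compare per-gene median expression between two gene classes
#'
#' Given the per-gene median FPKM values of two gene classes (e.g. 'CNV
#' genes' vs 'non CNV genes'), reports both class medians, their fold ratio,
#' and a two-sided Wilcoxon rank-sum p-value on the full distributions.
#'
#' @param medians_a,medians_b numeric vectors of per-gene median expression
#'   for the two classes (each non-empty).
#' @return list `median_a`, `median_b`, `fold` (median_a / median_b; `NA`
#'   when `median_b` is 0), `p_value`.
#' @export
compare_median_expression <- function(medians_a, medians_b) {
  if (length(medians_a) == 0 || length(medians_b) == 0) {
    stop("both classes must be non-empty")
  }
  ma <- stats::median(medians_a)
  mb <- stats::median(medians_b)
  p <- suppressWarnings(stats::wilcox.test(medians_a, medians_b))$p.value
  list(
    median_a = ma, median_b = mb,
    fold = if (mb > 0) ma / mb else NA_real_,
    p_value = p
  )
}

#' Median-of-ratios size factors
#'
#' For each gene with nonzero counts in every sample, the ratio of each
#' sample's count to the gene's geometric mean across samples is formed; a
#' sample's size factor is the median of its ratios. This is the standard
#' median-of-ratios normalization for sequencing counts; factors are not
#' rescaled afterwards (no unit-product constraint).
#'
#' @param counts numeric matrix, genes x samples, nonnegative.
#' @return named numeric vector of positive size factors, one per column.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be nonnegative")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no gene has nonzero counts in all samples")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - log_geo[use]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors, as from [size_factors()] (default: computed).
#' @return matrix of normalized counts (raw / size factor per column).
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(as.matrix(counts), 2, sf, "/")
}

#' Per-gene z-score comparison of CNV carriers vs non-carriers
#'
#' Normalized counts of one gene are z-transformed across the included
#' samples (carriers plus non-carriers); carrier and non-carrier z-scores
#' are compared by a two-sided Wilcoxon rank-sum test. Genes with zero
#' variance across the included samples are excluded (`skipped` reason
#' "zero_variance"), as are genes with an empty carrier or non-carrier set.
#'
#' @param norm_counts normalized genes x samples matrix (rownames = gene
#'   ids).
#' @param gene_id gene to test.
#' @param carriers,noncarriers sample id sets (column names).
#' @return list `gene_id`, `z` (named z-scores over included samples),
#'   `mean_z_carriers`, `mean_z_noncarriers`, `p_value`; or, for a skipped
#'   gene, `gene_id`, `skipped = TRUE`, `reason`.
#' @export
zscore_carrier_compare <- function(norm_counts, gene_id, carriers, noncarriers) {
  if (length(carriers) < 1 || length(noncarriers) < 1) {
    return(list(gene_id = gene_id, skipped = TRUE, reason = "empty_class"))
  }
  if (!gene_id %in% rownames(norm_counts)) stop("unknown gene: ", gene_id)
  samp <- c(carriers, noncarriers)
  if (!all(samp %in% colnames(norm_counts))) stop("unknown sample id(s)")
  v <- norm_counts[gene_id, samp]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    return(list(gene_id = gene_id, skipped = TRUE, reason = "zero_variance"))
  }
  z <- (v - mean(v)) / s
  zc <- z[carriers]; zn <- z[noncarriers]
  p <- suppressWarnings(stats::wilcox.test(zc, zn))$p.value
  list(
    gene_id = gene_id, z = z,
    mean_z_carriers = mean(zc), mean_z_noncarriers = mean(zn),
    p_value = p, skipped = FALSE
  )
}

#' Carrier z-score analysis over a gene set
#'
#' Runs [zscore_carrier_compare()] per gene, either testing each gene
#' separately (`mode = "per_gene"`) or pooling all genes' carrier and
#' non-carrier z-scores into one rank-sum test (`mode = "pooled"`).
#'
#' @param norm_counts normalized genes x samples matrix.
#' @param carrier_map named list: for each gene id, the character vector of
#'   carrier sample ids (non-carriers are the remaining columns).
#' @param mode "per_gene" or "pooled".
#' @return for `per_gene`, a data.frame (`gene_id`, `mean_z_carriers`,
#'   `p_value`, `skipped`, `reason`); for `pooled`, a list with pooled
#'   z-score vectors, their means and a single `p_value`, plus `n_skipped`.
#' @export
zscore_carrier_analysis <- function(norm_counts, carrier_map,
                                    mode = c("per_gene", "pooled")) {
  mode <- match.arg(mode)
  all_samples <- colnames(norm_counts)
  res <- lapply(names(carrier_map), function(g) {
    car <- intersect(carrier_map[[g]], all_samples)
    zscore_carrier_compare(norm_counts, g, car, setdiff(all_samples, car))
  })
  if (mode == "per_gene") {
    return(do.call(rbind, lapply(res, function(r) {
      data.frame(
        gene_id = r$gene_id,
        mean_z_carriers = if (isTRUE(r$skipped)) NA_real_ else r$mean_z_carriers,
        p_value = if (isTRUE(r$skipped)) NA_real_ else r$p_value,
        skipped = isTRUE(r$skipped),
        reason = if (isTRUE(r$skipped)) r$reason else "",
        stringsAsFactors = FALSE
      )
    })))
  }
  ok <- res[!vapply(res, function(r) isTRUE(r$skipped), logical(1))]
  zc <- unlist(lapply(ok, function(r) {
    r$z[names(r$z) %in% carrier_map[[r$gene_id]]]
  }))
  zn <- unlist(lapply(ok, function(r) {
    r$z[!names(r$z) %in% carrier_map[[r$gene_id]]]
  }))
  p <- if (length(zc) && length(zn)) {
    suppressWarnings(stats::wilcox.test(zc, zn))$p.value
  } else NA_real_
  list(z_carriers = zc, z_noncarriers = zn,
       mean_z_carriers = mean(zc), mean_z_noncarriers = mean(zn),
       p_value = p, n_skipped = length(res) - length(ok))
}

#' Density plot of per-gene median expression by gene class
#'
#' Diagnostic plot of the distributions of per-gene median expression (on
#' log10(x + offset) scale) for several gene classes. The smoothing
#' bandwidth is chosen by biased cross-validation, falling back to the
#' normal-reference rule when that fails to converge.
#'
#' @param median_list named list of numeric vectors (one per gene class).
#' @param offset added before log10 (default 0.01).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the list of `stats::density` objects.
#' @export
plot_expression_density <- function(median_list, offset = 0.01, ...) {
  dens <- lapply(median_list, function(x) {
    lx <- log10(x + offset)
    bw <- tryCatch(suppressWarnings(stats::bw.bcv(lx)),
                   error = function(e) stats::bw.nrd0(lx))
    stats::density(lx, bw = bw)
  })
  xr <- range(unlist(lapply(dens, function(d) d$x)))
  yr <- range(unlist(lapply(dens, function(d) d$y)))
  graphics::plot(NA, xlim = xr, ylim = yr,
                 xlab = sprintf("log10(median FPKM + %.2g)", offset),
                 ylab = "density", ...)
  for (i in seq_along(dens)) graphics::lines(dens[[i]], col = i, lty = i)
  graphics::legend("topright", legend = names(median_list),
                   col = seq_along(dens), lty = seq_along(dens), bty = "n")
  invisible(dens)
}
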