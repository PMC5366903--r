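#' Default toy chromosome set for simulation
#'
#' Four autosomes between 50 and 150 Mb including metacentric,
#' submetacentric and acrocentric examples, so that pericentromeric-window
#' clipping at the chromosome start is exercised.
#'
#' @return a [chrom_info()] table.
#' @export
sim_chrom_info <- function() {
  chrom_info(
    chrom = c("chr1", "chr2", "chr3", "chr4"),
    length_bp = c(150e6, 120e6, 80e6, 50e6),
    centromere_center_bp = c(60e6, 45e6, 32e6, 2e6)
  )
}

#' Default group design for simulated cohorts
#'
#' Placental study groups with their sample sizes, mean CNV counts and
#' duplication fractions chosen to emulate a recurrent-pregnancy-loss
#' cohort design: RPL miscarriage placentas (n = 10, mean 9 CNVs, dup
#' fraction ~0.28), RPL live-birth placentas (n = 3, mean 7), normal
#' first-trimester placentas (n = 9, mean 15, ~0.53) and normal term
#' placentas (n = 8, mean 31, ~0.82). `trio_fraction` is the fraction of
#' families with a genotyped father (term controls are full trios,
#' first-trimester controls mother-placenta duos). `pool_freq` is the
#' per-locus carrier frequency of shared polymorphic CNV loci in the group.
#'
#' @return data.frame with one row per placental group.
#' @export
sim_group_design <- function() {
  data.frame(
    group = c("rpl_loss", "rpl_livebirth", "control_first_trimester",
              "control_term"),
    n_samples = c(10L, 3L, 9L, 8L),
    mean_cnv = c(9, 7, 15, 31),
    dup_frac = c(0.28, 0.4, 0.53, 0.82),
    trio_fraction = c(0.6, 1, 0, 1),
    pool_freq = c(0.05, 0.05, 0.12, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator with defaults that
#' emulate the study design the pipeline targets. One global `seed` fixes
#' everything; per-stage substream seeds (cohort, callers, expression) are
#' derived from it in that documented order, so stages can be regenerated
#' independently.
#'
#' @param seed integer global seed.
#' @param chroms chromosome table (default [sim_chrom_info()]).
#' @param groups group design (default [sim_group_design()]).
#' @param with_parents generate parental blood samples per family and
#'   inherited placental CNVs (default `TRUE`).
#' @param parent_mean_cnv mean CNV count per parental genome (default 9).
#' @param parent_dup_frac duplication fraction in parental genomes
#'   (default 0.25).
#' @param inherit_prob probability a placental sample inherits each parental
#'   CNV (default 0.3).
#' @param length_meanlog,length_sdlog log-normal CNV length parameters
#'   (defaults `log(5e4)` and 1: median 50 kb, a few percent above 300 kb,
#'   matching SNP-array-scale CNV spectra).
#' @param min_len_bp minimum CNV length (default 1000).
#' @param n_pool_loci number of shared polymorphic CNV loci (default 50).
#' @param pool_dup_frac duplication fraction among pool loci (default 0.5).
#' @param callers data.frame `caller_id`, `detect_prob`, `jitter_sd`,
#'   `fp_rate` (defaults: three callers, detection 0.9, breakpoint jitter
#'   sd 2 kb -- about half the array's mean probe spacing -- and 2 false
#'   positives per genome each).
#' @param confidence_caller caller that reports a log Bayes Factor style
#'   confidence (default "callerA").
#' @param conf_meanlog,conf_sdlog log-normal confidence parameters for true
#'   calls of the confidence caller (median 20).
#' @param conf_fp_meanlog,conf_fp_sdlog confidence parameters for its false
#'   positives (median 3, so most fall under the conventional floor of 5).
#' @param n_genes,gene_len_meanlog,gene_len_sdlog simulated gene annotation.
#' @param base_meanlog,base_sdlog log-normal baseline expression (counts
#'   scale).
#' @param del_prone_fold baseline multiplier for genes overlapping deletion
#'   CNVs (default 3, emulating the elevated expression of deletion-prone
#'   loci).
#' @param dosage_on apply per-carrier dosage factors (default `TRUE`).
#' @param dosage_del,dosage_dup dosage multipliers per carried deletion /
#'   duplication (0.5 / 1.5: one copy lost / gained on a diploid baseline).
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param lib_sdlog log-normal sd of per-sample library size factors
#'   (default 0.2).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chroms = sim_chrom_info(),
                       groups = sim_group_design(),
                       with_parents = TRUE,
                       parent_mean_cnv = 9,
                       parent_dup_frac = 0.25,
                       inherit_prob = 0.3,
                       length_meanlog = log(5e4),
                       length_sdlog = 1,
                       min_len_bp = 1000,
                       n_pool_loci = 50,
                       pool_dup_frac = 0.5,
                       callers = data.frame(
                         caller_id = c("callerA", "callerB", "callerC"),
                         detect_prob = 0.9,
                         jitter_sd = 2000,
                         fp_rate = 2,
                         stringsAsFactors = FALSE
                       ),
                       confidence_caller = "callerA",
                       conf_meanlog = log(20), conf_sdlog = 1,
                       conf_fp_meanlog = log(3), conf_fp_sdlog = 0.8,
                       n_genes = 2000,
                       gene_len_meanlog = log(2e4), gene_len_sdlog = 0.8,
                       base_meanlog = log(50), base_sdlog = 1.5,
                       del_prone_fold = 3,
                       dosage_on = TRUE,
                       dosage_del = 0.5, dosage_dup = 1.5,
                       dispersion = 0.1,
                       lib_sdlog = 0.2) {
  chroms <- .assert_chrom_info(chroms)
  .assert_cols(groups, c("group", "n_samples", "mean_cnv", "dup_frac"),
               "groups")
  if (!"trio_fraction" %in% names(groups)) groups$trio_fraction <- 0
  if (!"pool_freq" %in% names(groups)) groups$pool_freq <- 0
  stopifnot(all(groups$dup_frac >= 0 & groups$dup_frac <= 1),
            all(groups$pool_freq >= 0 & groups$pool_freq <= 1),
            all(callers$detect_prob >= 0 & callers$detect_prob <= 1),
            inherit_prob >= 0, inherit_prob <= 1,
            length_sdlog > 0, min_len_bp >= 1, dispersion > 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Derived per-stage seeds; the draw order (cohort, callers, expression) is
# part of the generator's contract.
.stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                  c("cohort", "callers", "expression"))
}

# Draw one CNV interval not overlapping same-type intervals already present
# in `existing` (data.frame chrom/start/end/type), by rejection.
.draw_cnv <- function(chroms, length_meanlog, length_sdlog, min_len_bp,
                      type, existing, max_tries = 50L) {
  for (k in seq_len(max_tries)) {
    len <- round(stats::rlnorm(1, length_meanlog, length_sdlog))
    ci <- sample.int(nrow(chroms), 1, prob = chroms$length_bp)
    L <- chroms$length_bp[ci]
    len <- min(max(len, min_len_bp), floor(0.5 * L))
    start <- floor(stats::runif(1, 0, L - len))
    end <- start + len
    clash <- FALSE
    if (nrow(existing)) {
      same <- existing$type == type & existing$chrom == chroms$chrom[ci]
      clash <- any(pmin(existing$end[same], end) > pmax(existing$start[same], start))
    }
    if (!clash) {
      return(data.frame(chrom = chroms$chrom[ci], start = start, end = end,
                        type = type, stringsAsFactors = FALSE))
    }
  }
  stop("could not place a non-overlapping CNV; config may be infeasible")
}

#' Generate a synthetic cohort with ground-truth CNVs
#'
#' Produces sample metadata (placental samples per group, plus mothers and
#' fathers when `with_parents`), a shared pool of polymorphic CNV loci, and
#' per-sample true CNVs. Parental genomes draw `Poisson(parent_mean_cnv)`
#' CNVs; placental genomes first inherit each parental CNV of their family
#' with probability `inherit_prob`, then add somatic CNVs so that the
#' expected total matches the group's `mean_cnv` (groups without parents
#' draw exactly `Poisson(mean_cnv)`). Each somatic CNV is either a carried
#' shared-pool locus (per-locus Bernoulli at the group's `pool_freq`) or a
#' private interval (position uniform, length log-normal, type per the
#' group's duplication fraction). Same-type CNVs never overlap within a
#' sample. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `cnv_cohort`: `truth` (sample_id, chrom, start,
#'   end, type, origin in pool/private/inherited, pool_locus,
#'   inherited_from), `meta` (sample_id, group, tissue, family_id, role),
#'   `chroms`, `pool` (the pool locus table) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .stage_seeds(config$seed)
  set.seed(seeds[["cohort"]])
  chroms <- config$chroms
  if (any(stats::qlnorm(0.99, config$length_meanlog, config$length_sdlog) >
          chroms$length_bp)) {
    stop("CNV length distribution is too long for the chromosome set")
  }

  # shared polymorphic loci, mutually non-overlapping
  pool <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), type = character(0),
                     stringsAsFactors = FALSE)
  for (i in seq_len(config$n_pool_loci)) {
    tp <- if (stats::runif(1) < config$pool_dup_frac) "dup" else "del"
    row <- .draw_cnv(chroms, config$length_meanlog, config$length_sdlog,
                     config$min_len_bp, tp, pool)
    pool <- rbind(pool, row)
  }
  if (nrow(pool)) pool$locus <- seq_len(nrow(pool))

  # sample metadata with family structure
  meta <- list(); fam_n <- 0L
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups[gi, ]
    for (si in seq_len(g$n_samples)) {
      fam_n <- fam_n + 1L
      fam <- sprintf("FAM%03d", fam_n)
      pid <- sprintf("%s_P%02d", g$group, si)
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = pid, group = g$group, tissue = "placenta",
        family_id = fam, role = "placenta", stringsAsFactors = FALSE)
      if (config$with_parents) {
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sprintf("%s_M%02d", g$group, si), group = g$group,
          tissue = "blood", family_id = fam, role = "mother",
          stringsAsFactors = FALSE)
        if (stats::runif(1) < g$trio_fraction) {
          meta[[length(meta) + 1L]] <- data.frame(
            sample_id = sprintf("%s_F%02d", g$group, si), group = g$group,
            tissue = "blood", family_id = fam, role = "father",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  meta <- do.call(rbind, meta)

  grp_row <- function(g) config$groups[config$groups$group == g, ]

  draw_somatic <- function(mean_total, pool_freq, dup_frac, existing) {
    out <- existing[0, c("chrom", "start", "end", "type")]
    origin <- character(0); locus <- integer(0)
    if (nrow(pool) && pool_freq > 0) {
      carried <- which(stats::runif(nrow(pool)) < pool_freq)
      for (i in carried) {
        same <- rbind(existing[, c("chrom", "start", "end", "type")], out)
        sm <- same$type == pool$type[i] & same$chrom == pool$chrom[i]
        if (any(pmin(same$end[sm], pool$end[i]) >
                pmax(same$start[sm], pool$start[i]))) next
        out <- rbind(out, pool[i, c("chrom", "start", "end", "type")])
        origin <- c(origin, "pool"); locus <- c(locus, pool$locus[i])
      }
    }
    mean_private <- max(0, mean_total - nrow(pool) * pool_freq)
    n_priv <- stats::rpois(1, mean_private)
    for (k in seq_len(n_priv)) {
      tp <- if (stats::runif(1) < dup_frac) "dup" else "del"
      same <- rbind(existing[, c("chrom", "start", "end", "type")], out)
      row <- .draw_cnv(chroms, config$length_meanlog, config$length_sdlog,
                       config$min_len_bp, tp, same)
      out <- rbind(out, row)
      origin <- c(origin, "private"); locus <- c(locus, NA_integer_)
    }
    if (nrow(out)) { out$origin <- origin; out$pool_locus <- locus }
    out
  }

  truth <- list()
  none <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), type = character(0),
                     stringsAsFactors = FALSE)

  # parental genomes first (placental inheritance copies from them)
  parents <- meta[meta$role %in% c("mother", "father"), , drop = FALSE]
  for (i in seq_len(nrow(parents))) {
    g <- grp_row(parents$group[i])
    cn <- draw_somatic(config$parent_mean_cnv, g$pool_freq,
                       config$parent_dup_frac, none)
    if (nrow(cn)) {
      cn$sample_id <- parents$sample_id[i]
      cn$inherited_from <- NA_character_
      truth[[length(truth) + 1L]] <- cn
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL

  placentas <- meta[meta$role == "placenta", , drop = FALSE]
  for (i in seq_len(nrow(placentas))) {
    g <- grp_row(placentas$group[i])
    fam_par <- meta$sample_id[meta$family_id == placentas$family_id[i] &
                                meta$role %in% c("mother", "father")]
    inh <- none; inh_from <- character(0); inh_locus <- integer(0); inh_origin <- character(0)
    if (length(fam_par) && !is.null(truth_df)) {
      pcnv <- truth_df[truth_df$sample_id %in% fam_par, , drop = FALSE]
      for (k in seq_len(nrow(pcnv))) {
        if (stats::runif(1) >= config$inherit_prob) next
        sm <- inh$type == pcnv$type[k] & inh$chrom == pcnv$chrom[k]
        if (any(pmin(inh$end[sm], pcnv$end[k]) >
                pmax(inh$start[sm], pcnv$start[k]))) next
        inh <- rbind(inh, pcnv[k, c("chrom", "start", "end", "type")])
        inh_from <- c(inh_from, pcnv$sample_id[k])
        inh_locus <- c(inh_locus, pcnv$pool_locus[k])
        inh_origin <- c(inh_origin, "inherited")
      }
    }
    exp_inherited <- config$inherit_prob * config$parent_mean_cnv * length(fam_par)
    mean_somatic <- if (length(fam_par)) {
      max(0.5, g$mean_cnv - exp_inherited)
    } else {
      g$mean_cnv
    }
    som <- draw_somatic(mean_somatic, g$pool_freq, g$dup_frac, inh)
    cn <- inh
    if (nrow(cn)) {
      cn$origin <- inh_origin; cn$pool_locus <- inh_locus
    }
    all_cn <- rbind(cn, som)
    if (nrow(all_cn)) {
      all_cn$sample_id <- placentas$sample_id[i]
      all_cn$inherited_from <- c(inh_from, rep(NA_character_, nrow(som)))
      truth[[length(truth) + 1L]] <- all_cn
    }
  }

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               type = character(0), origin = character(0),
               pool_locus = integer(0), sample_id = character(0),
               inherited_from = character(0), stringsAsFactors = FALSE)
  truth_df <- truth_df[, c("sample_id", "chrom", "start", "end", "type",
                           "origin", "pool_locus", "inherited_from")]
  truth_df <- truth_df[order(truth_df$sample_id, truth_df$chrom,
                             truth_df$start, truth_df$end), , drop = FALSE]
  rownames(truth_df) <- NULL
  structure(list(truth = truth_df, meta = meta, chroms = chroms,
                 pool = pool, config = config),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("cnv_cohort:", nrow(x$meta), "samples,", nrow(x$truth), "true CNVs,",
      "seed", x$config$seed, "\n")
  tab <- table(x$meta$group, x$meta$tissue)
  print(tab)
  invisible(x)
}

#' Emulate imperfect CNV callers on a simulated cohort
#'
#' Each true CNV is detected by each configured caller independently with
#' its detection probability; detected breakpoints are jittered with rounded
#' Gaussian noise, clipped to the chromosome and re-validated against the
#' generator's minimum length. Each caller adds per-sample false-positive
#' calls at random loci (`Poisson(fp_rate)`). The confidence-reporting
#' caller attaches log Bayes Factor style confidences (drawn from separate
#' distributions for true and false calls); other callers report `NA`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config the same [sim_config()] (default: the cohort's).
#' @return raw-call data.frame: `sample_id`, `caller_id`, `chrom`, `start`,
#'   `end`, `type`, `confidence`, `is_fp` (truth flag for evaluation only),
#'   `truth_row` (index into `cohort$truth`, NA for false positives).
#' @export
emulate_callers <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  seeds <- .stage_seeds(config$seed)
  set.seed(seeds[["callers"]])
  chroms <- cohort$chroms
  truth <- cohort$truth
  callers <- config$callers
  out <- list()
  for (ci in seq_len(nrow(callers))) {
    cal <- callers[ci, ]
    if (nrow(truth)) {
      det <- stats::runif(nrow(truth)) < cal$detect_prob
      d <- truth[det, , drop = FALSE]
      if (nrow(d)) {
        L <- chroms$length_bp[match(d$chrom, chroms$chrom)]
        s <- d$start + round(stats::rnorm(nrow(d), 0, cal$jitter_sd))
        e <- d$end + round(stats::rnorm(nrow(d), 0, cal$jitter_sd))
        s <- pmax(0, pmin(s, L - config$min_len_bp))
        e <- pmax(s + config$min_len_bp, pmin(e, L))
        out[[length(out) + 1L]] <- data.frame(
          sample_id = d$sample_id, caller_id = cal$caller_id,
          chrom = d$chrom, start = s, end = e, type = d$type,
          confidence = NA_real_, is_fp = FALSE,
          truth_row = which(det), stringsAsFactors = FALSE)
      }
    }
    if (cal$fp_rate > 0) {
      for (sid in cohort$meta$sample_id) {
        n_fp <- stats::rpois(1, cal$fp_rate)
        for (k in seq_len(n_fp)) {
          tp <- if (stats::runif(1) < 0.5) "dup" else "del"
          row <- .draw_cnv(chroms, config$length_meanlog, config$length_sdlog,
                           config$min_len_bp, tp,
                           data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), type = character(0)))
          out[[length(out) + 1L]] <- data.frame(
            sample_id = sid, caller_id = cal$caller_id,
            chrom = row$chrom, start = row$start, end = row$end, type = tp,
            confidence = NA_real_, is_fp = TRUE, truth_row = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), caller_id = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               type = character(0), confidence = numeric(0),
               is_fp = logical(0), truth_row = integer(0),
               stringsAsFactors = FALSE)
  cc <- calls$caller_id == config$confidence_caller
  if (any(cc)) {
    n_true <- sum(cc & !calls$is_fp); n_fp <- sum(cc & calls$is_fp)
    calls$confidence[cc & !calls$is_fp] <-
      stats::rlnorm(n_true, config$conf_meanlog, config$conf_sdlog)
    calls$confidence[cc & calls$is_fp] <-
      stats::rlnorm(n_fp, config$conf_fp_meanlog, config$conf_fp_sdlog)
  }
  calls <- calls[order(calls$sample_id, calls$caller_id, calls$chrom,
                       calls$start, calls$end), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Simulate a gene annotation on the toy genome
#'
#' Genes are placed uniformly along the chromosomes (proportional to
#' length) with log-normal lengths; overlaps between genes are allowed.
#'
#' @param config a [sim_config()] (uses `n_genes`, gene length parameters
#'   and the chromosome set). Drawn from the expression substream so the
#'   annotation is reproducible from the global seed.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `length_bp`.
#' @export
simulate_genes <- function(config) {
  seeds <- .stage_seeds(config$seed)
  set.seed(seeds[["expression"]])
  chroms <- config$chroms
  n <- config$n_genes
  len <- pmax(200, round(stats::rlnorm(n, config$gene_len_meanlog,
                                       config$gene_len_sdlog)))
  ci <- sample.int(nrow(chroms), n, replace = TRUE, prob = chroms$length_bp)
  L <- chroms$length_bp[ci]
  len <- pmin(len, floor(L / 2))
  start <- floor(stats::runif(n, 0, L - len))
  data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    chrom = chroms$chrom[ci],
    start = start, end = start + len, length_bp = len,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic expression matrix with CNV structure
#'
#' Per-gene baselines are log-normal; genes overlapping any true deletion
#' CNV in the cohort ("deletion-prone" loci) get their baseline multiplied
#' by `del_prone_fold`, emulating the elevated expression of
#' deletion-tolerant regions. Per sample, a carried deletion or duplication
#' overlapping a gene multiplies its expectation by the dosage factors
#' (when `dosage_on`). Counts are negative-binomial around baseline x
#' library factor x dosage; an FPKM layer is derived from the counts and
#' gene lengths.
#'
#' @param cohort a [generate_cohort()] result.
#' @param genes gene annotation (default [simulate_genes()] on the cohort's
#'   config).
#' @param config the [sim_config()] (default: the cohort's).
#' @param samples sample ids to generate expression for (default: all
#'   placental samples).
#' @return list of class `expr_set`: `counts` and `fpkm` (genes x samples
#'   matrices), `genes`, `del_prone` (logical per gene), `samples`.
#' @export
generate_expression <- function(cohort, genes = NULL, config = cohort$config,
                                samples = NULL) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  if (is.null(genes)) genes <- simulate_genes(config)
  seeds <- .stage_seeds(config$seed)
  set.seed(seeds[["expression"]] + 1L)
  if (is.null(samples)) {
    samples <- cohort$meta$sample_id[cohort$meta$tissue == "placenta"]
  }
  truth <- cohort$truth[cohort$truth$sample_id %in% samples, , drop = FALSE]
  ng <- nrow(genes); ns <- length(samples)

  overlap_any <- function(cnvs) {
    # logical genes x 1: gene overlaps >=1 row of cnvs
    if (nrow(cnvs) == 0) return(rep(FALSE, ng))
    vapply(seq_len(ng), function(i) {
      sm <- cnvs$chrom == genes$chrom[i]
      any(pmin(cnvs$end[sm], genes$end[i]) > pmax(cnvs$start[sm], genes$start[i]))
    }, logical(1))
  }
  del_prone <- overlap_any(truth[truth$type == "del", , drop = FALSE])
  base <- stats::rlnorm(ng, config$base_meanlog, config$base_sdlog)
  base[del_prone] <- base[del_prone] * config$del_prone_fold
  libf <- stats::rlnorm(ns, 0, config$lib_sdlog)

  counts <- matrix(0, ng, ns, dimnames = list(genes$gene_id, samples))
  for (j in seq_len(ns)) {
    dos <- rep(1, ng)
    if (config$dosage_on) {
      cn <- truth[truth$sample_id == samples[j], , drop = FALSE]
      if (nrow(cn)) {
        in_del <- overlap_any(cn[cn$type == "del", , drop = FALSE])
        in_dup <- overlap_any(cn[cn$type == "dup", , drop = FALSE])
        dos[in_del] <- dos[in_del] * config$dosage_del
        dos[in_dup] <- dos[in_dup] * config$dosage_dup
      }
    }
    mu <- base * libf[j] * dos
    counts[, j] <- stats::rnbinom(ng, mu = mu, size = 1 / config$dispersion)
  }
  total <- colSums(counts)
  fpkm <- sweep(counts / (genes$length_bp / 1000), 2, total / 1e6, "/")
  structure(list(counts = counts, fpkm = fpkm, genes = genes,
                 del_prone = del_prone, samples = samples),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      sum(x$del_prone), "deletion-prone genes\n")
  invisible(x)
}
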