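test_that("one seed fixes the whole cohort, calls and expression", {
  cfg <- test_sim_config(seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$meta, c2$meta)
  expect_identical(emulate_callers(c1), emulate_callers(c2))
  e1 <- generate_expression(c1)
  e2 <- generate_expression(c2)
  expect_identical(e1$counts, e2$counts)
  # a different seed changes the cohort
  c3 <- generate_cohort(test_sim_config(seed = 78))
  expect_false(identical(c1$truth, c3$truth))
})

test_that("per-sample CNV counts follow the configured Poisson mean", {
  cfg <- sim_config(
    seed = 9,
    groups = data.frame(group = "control_first_trimester", n_samples = 400,
                        mean_cnv = 15, dup_frac = 0.5, trio_fraction = 0,
                        pool_freq = 0.1),
    with_parents = FALSE
  )
  coh <- generate_cohort(cfg)
  counts <- table(factor(coh$truth$sample_id,
                         levels = coh$meta$sample_id))
  se <- sqrt(15 / 400)
  expect_lt(abs(mean(counts) - 15), 3 * se)
  # same-type CNVs never overlap within a sample
  bad <- vapply(split(coh$truth, coh$truth$sample_id), function(df) {
    any(vapply(split(df, paste(df$chrom, df$type)), function(d) {
      if (nrow(d) < 2) return(FALSE)
      d <- d[order(d$start), ]
      any(d$start[-1] < d$end[-nrow(d)])
    }, logical(1)))
  }, logical(1))
  expect_false(any(bad))
})

test_that("zero pool frequency yields no cross-sample sharing by construction", {
  cfg <- test_sim_config(
    seed = 10,
    groups = data.frame(group = c("rpl_loss", "control_term"),
                        n_samples = c(6, 6), mean_cnv = c(8, 8),
                        dup_frac = 0.5, trio_fraction = 0, pool_freq = 0),
    with_parents = FALSE
  )
  coh <- generate_cohort(cfg)
  expect_false(any(coh$truth$origin == "pool"))
  cs <- build_cnvrs(coh$truth, meta = coh$meta)
  ss <- sharing_summary(cs, coh$meta, "rpl_loss", "control_term")
  # private 50 kb-scale CNVs on a 400 Mb genome essentially never collide
  expect_equal(unname(ss$shared[["control_term"]]), 0L)
})

test_that("imperfect callers miss, jitter and fabricate calls as configured", {
  cfg <- test_sim_config(
    seed = 11,
    groups = data.frame(group = "control_term", n_samples = 10, mean_cnv = 20,
                        dup_frac = 0.5, trio_fraction = 0, pool_freq = 0.1),
    with_parents = FALSE,
    callers = data.frame(caller_id = c("callerA", "callerB", "callerC"),
                         detect_prob = 0.8, jitter_sd = 500, fp_rate = 1.5)
  )
  coh <- generate_cohort(cfg)
  calls <- emulate_callers(coh)
  n_true_calls <- sum(!calls$is_fp)
  n_expected <- 3 * 0.8 * nrow(coh$truth)
  se <- sqrt(3 * 0.8 * 0.2 * nrow(coh$truth))
  expect_lt(abs(n_true_calls - n_expected), 4 * se)
  fp <- calls[calls$is_fp, ]
  expect_gt(nrow(fp), 0)
  se_fp <- sqrt(1.5 * 3 * 10)
  expect_lt(abs(nrow(fp) - 1.5 * 3 * 10), 4 * se_fp)
  # jitter: detected breakpoints deviate from truth but stay valid
  det <- calls[!calls$is_fp, ]
  tr <- coh$truth[det$truth_row, ]
  expect_true(any(det$start != tr$start))
  expect_lt(median(abs(det$start - tr$start)), 4 * 500)
  expect_true(all(det$end - det$start >= cfg$min_len_bp))
  # only the confidence caller reports confidences
  expect_true(all(is.na(calls$confidence[calls$caller_id != "callerA"])))
  expect_true(all(!is.na(calls$confidence[calls$caller_id == "callerA"])))
  # its false positives mostly fall under the conventional floor of 5
  fpa <- calls$confidence[calls$is_fp & calls$caller_id == "callerA"]
  expect_gt(mean(fpa < 5), 0.5)
})

test_that("moderate jitter leaves consensus recall intact on 50 kb CNVs", {
  base_groups <- data.frame(group = "control_term", n_samples = 15,
                            mean_cnv = 20, dup_frac = 0.5, trio_fraction = 0,
                            pool_freq = 0)
  recall_at <- function(jitter, fp) {
    cfg <- test_sim_config(
      seed = 12, groups = base_groups, with_parents = FALSE,
      length_meanlog = log(5e4), length_sdlog = 0.3,
      callers = data.frame(caller_id = c("callerA", "callerB", "callerC"),
                           detect_prob = 1, jitter_sd = jitter, fp_rate = fp))
    coh <- generate_cohort(cfg)
    cons <- consensus_all_samples(emulate_callers(coh))
    tr <- coh$truth
    hit <- vapply(seq_len(nrow(tr)), function(i) {
      cs <- cons[cons$sample_id == tr$sample_id[i] & cons$type == tr$type[i], ]
      nrow(cs) > 0 && any(reciprocal_overlap(tr$chrom[i], tr$start[i], tr$end[i],
                                             cs$chrom, cs$start, cs$end) >= 0.4)
    }, logical(1))
    mean(hit)
  }
  expect_equal(recall_at(500, 0), 1)   # jitter sd 500 bp << 40% of 50 kb
  # recall degrades monotonically along a noise ladder
  ladder <- c(recall_at(0, 0), recall_at(2000, 0), recall_at(20000, 0))
  expect_equal(ladder[1], 1)
  expect_true(all(diff(ladder) <= 0))
})

test_that("family structure produces inherited placental CNVs with matching parents", {
  cfg <- test_sim_config(seed = 13, inherit_prob = 0.5)
  coh <- generate_cohort(cfg)
  inh <- coh$truth[coh$truth$origin == "inherited", ]
  expect_gt(nrow(inh), 0)
  # every inherited CNV exists identically in the named parent
  for (i in sample(nrow(inh), min(20, nrow(inh)))) {
    p <- coh$truth[coh$truth$sample_id == inh$inherited_from[i], ]
    expect_true(any(p$chrom == inh$chrom[i] & p$start == inh$start[i] &
                      p$end == inh$end[i] & p$type == inh$type[i]))
  }
  # parents belong to the same family as the placenta
  fam_of <- setNames(coh$meta$family_id, coh$meta$sample_id)
  expect_true(all(fam_of[inh$sample_id] == fam_of[inh$inherited_from]))
  # inheritance annotation recovers the parental origin
  one <- inh[1, ]
  fam <- coh$meta[coh$meta$family_id == fam_of[[one$sample_id]], ]
  parents_cnvs <- coh$truth[coh$truth$sample_id %in%
                              fam$sample_id[fam$role != "placenta"], ]
  lab <- annotate_inheritance(one, fam, parents_cnvs)
  role <- coh$meta$role[coh$meta$sample_id == one$inherited_from]
  expect_true(lab %in% c("maternal", "paternal"))
  expect_equal(lab, if (role == "mother") "maternal" else "paternal")
})

test_that("simulated placental group medians preserve the configured ordering", {
  set.seed(14)
  ok <- 0
  for (k in 1:20) {
    cfg <- sim_config(
      seed = 1000 + k,
      groups = data.frame(
        group = c("rpl_loss", "control_first_trimester", "control_term"),
        n_samples = c(10, 9, 8), mean_cnv = c(9, 15, 31),
        dup_frac = c(0.28, 0.53, 0.82), trio_fraction = 0,
        pool_freq = c(0.05, 0.12, 0.2)),
      with_parents = FALSE
    )
    coh <- generate_cohort(cfg)
    counts <- table(factor(coh$truth$sample_id, levels = coh$meta$sample_id))
    med <- tapply(as.integer(counts),
                  coh$meta$group[match(names(counts), coh$meta$sample_id)],
                  median)
    if (med[["rpl_loss"]] < med[["control_first_trimester"]] &&
        med[["control_first_trimester"]] < med[["control_term"]]) ok <- ok + 1
  }
  expect_gte(ok, 19)
})
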