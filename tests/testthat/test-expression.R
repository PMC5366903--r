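test_that("gene classification by CNVR overlap is a partition with correct labels", {
  genes <- data.frame(
    gene_id = c("g_del", "g_dup", "g_both", "g_none"),
    chrom = "chr1",
    start = c(0, 2e5, 4e5, 6e5),
    end = c(1e5, 3e5, 5e5, 7e5),
    stringsAsFactors = FALSE
  )
  cnvrs <- data.frame(
    chrom = "chr1",
    start = c(5e4, 25e4, 45e4, 48e4),
    end = c(9e4, 29e4, 47e4, 49e4),
    type = c("del", "dup", "del", "dup"),
    stringsAsFactors = FALSE
  )
  cls <- classify_genes(genes, cnvrs)
  expect_equal(cls$cnv_class, c("del_only", "dup_only", "both", "non_cnv"))
  expect_equal(nrow(cls), nrow(genes))
})

test_that("gene classification agrees with a per-gene brute-force scan", {
  set.seed(41)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      chrom = sample(c("chr1", "chr2"), 200, TRUE),
                      start = floor(runif(200, 0, 9e5)))
  genes$end <- genes$start + sample(1e3:5e4, 200, TRUE)
  cnvrs <- rand_calls(60, n_samples = 4)[, c("chrom", "start", "end", "type")]
  cls <- classify_genes(genes, cnvrs)
  for (i in sample(200, 50)) {
    ov <- function(tp) {
      r <- cnvrs[cnvrs$type == tp & cnvrs$chrom == genes$chrom[i], ]
      nrow(r) > 0 && any(r$start < genes$end[i] & r$end > genes$start[i])
    }
    want <- if (ov("del") && ov("dup")) "both" else if (ov("del")) "del_only"
            else if (ov("dup")) "dup_only" else "non_cnv"
    expect_equal(cls$cnv_class[i], want)
  }
})

test_that("median-expression comparison reports medians, fold and rank-sum p", {
  a <- c(0.1, 0.151, 0.9); b <- c(0.01, 0.094, 0.4)
  r <- compare_median_expression(a, b)
  expect_equal(r$median_a, 0.151)
  expect_equal(r$fold, 0.151 / 0.094)
  r2 <- compare_median_expression(a, a)
  expect_equal(r2$fold, 1)
  expect_equal(r2$p_value, 1)
  r3 <- compare_median_expression(a, c(0, 0, 0))
  expect_true(is.na(r3$fold))
  expect_error(compare_median_expression(a, numeric(0)), "non-empty")
})

test_that("size factors follow the median-of-ratios closed forms", {
  m1 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
               dimnames = list(NULL, c("s1", "s2")))
  expect_equal(unname(size_factors(m1)), c(1 / sqrt(2), sqrt(2)))
  m2 <- matrix(rpois(30, 50) + 1, ncol = 3)
  expect_equal(unname(size_factors(cbind(m2[, 1], m2[, 1], m2[, 1]))),
               c(1, 1, 1))
  # 3-gene x 2-sample toy matrix vs hand computation
  m3 <- matrix(c(4, 9, 25, 16, 9, 100), ncol = 2)
  gm <- sqrt(m3[, 1] * m3[, 2])
  hand <- c(median(m3[, 1] / gm), median(m3[, 2] / gm))
  expect_equal(unname(size_factors(m3)), hand)
  # genes with a zero in any sample are excluded; none usable -> error
  expect_error(size_factors(matrix(c(0, 5, 3, 0), 2)), "nonzero")
})

test_that("size factors match the reference normalization implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(600, mu = 80, size = 5), ncol = 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  m[m == 0] <- 1
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("size factors are scale-equivariant in any one sample", {
  # multiplying one sample's counts by c also scales every gene's geometric
  # mean by c^(1/n), so equivariance holds for size-factor RATIOS (the
  # normalization is defined up to that common factor)
  set.seed(43)
  m <- matrix(rpois(400, 60) + 1, ncol = 4)
  sf <- size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  sf2 <- size_factors(m2)
  expect_equal(sf2[3] / sf2[1], 5 * sf[3] / sf[1], tolerance = 1e-12)
  expect_equal(sf2[2] / sf2[4], sf[2] / sf[4], tolerance = 1e-12)
  # ... exactly as the reference implementation behaves
  expect_equal(unname(sf2 / sf), rep(5^(-1 / 4) * c(1, 1, 5, 1), 1),
               tolerance = 1e-12)
  norm <- normalize_counts(m, sf)
  expect_equal(norm[, 2], m[, 2] / sf[2])
})

test_that("carrier z-score analysis detects a shifted gene and skips degenerate ones", {
  set.seed(44)
  samples <- sprintf("s%02d", 1:40)
  m <- matrix(rnbinom(40 * 20, mu = 100, size = 10), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), samples))
  carriers <- samples[1:20]; noncar <- samples[21:40]
  m["g01", carriers] <- m["g01", carriers] + 500
  r <- zscore_carrier_compare(m, "g01", carriers, noncar)
  expect_lt(r$p_value, 1e-4)
  expect_gt(r$mean_z_carriers, 0)
  # z-scores are centred and scaled over the included samples
  expect_equal(mean(r$z), 0, tolerance = 1e-12)
  expect_equal(sd(r$z), 1, tolerance = 1e-12)
  m["g02", ] <- 7
  r2 <- zscore_carrier_compare(m, "g02", carriers, noncar)
  expect_true(r2$skipped)
  expect_equal(r2$reason, "zero_variance")
  r3 <- zscore_carrier_compare(m, "g01", character(0), noncar)
  expect_true(r3$skipped)
  # null construction: no shift -> moderate p, near-zero mean z
  pooled <- zscore_carrier_analysis(
    m[3:12, ], lapply(setNames(rownames(m)[3:12], rownames(m)[3:12]),
                      function(g) sample(samples, 15)),
    mode = "pooled")
  expect_equal(pooled$mean_z_carriers, 0, tolerance = 0.5)
  expect_gt(pooled$p_value, 0.001)
})

test_that("a configured deletion-prone expression fold is recovered", {
  # the median-of-medians fold estimator over ~170 deletion-prone genes has
  # a log-scale sampling sd of ~8% per cohort, so the 15% recovery band is
  # checked on the mean fold over three replicate cohorts
  folds <- vapply(8:10, function(s) {
    cfg <- sim_config(
      seed = s, n_genes = 2000, del_prone_fold = 3, dosage_on = FALSE,
      base_sdlog = 0.8,
      groups = data.frame(group = "control_term", n_samples = 20, mean_cnv = 30,
                          dup_frac = 0.3, trio_fraction = 0, pool_freq = 0.1),
      with_parents = FALSE
    )
    coh <- generate_cohort(cfg)
    expr <- generate_expression(coh)
    cnvrs <- build_cnvrs(coh$truth)
    cls <- classify_genes(expr$genes, cnvrs)
    med <- apply(expr$fpkm, 1, median)
    r <- compare_median_expression(med[cls$cnv_class == "del_only"],
                                   med[cls$cnv_class == "non_cnv"])
    expect_gt(sum(cls$cnv_class == "del_only"), 50)
    expect_lt(r$p_value, 1e-6)
    r$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 3) / 3, 0.15)
})

test_that("density plotting returns bandwidth-selected densities", {
  set.seed(45)
  pdf(NULL)
  on.exit(dev.off())
  d <- plot_expression_density(list(a = rlnorm(200), b = rlnorm(200, 1)))
  expect_length(d, 2)
  expect_s3_class(d[[1]], "density")
})
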