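mk_cnvs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], chrom = r[["chrom"]] %||% "chr1",
               start = as.numeric(r[[2]]), end = as.numeric(r[[3]]),
               type = r[["type"]] %||% "del", stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cross-sample CNVs cluster under the coverage-of-at-least-one rule", {
  cs <- build_cnvrs(mk_cnvs(list("s1", 0, 1e5), list("s2", 1e4, 11e4)))
  expect_equal(nrow(cs$cnvrs), 1)
  expect_equal(c(cs$cnvrs$start, cs$cnvrs$end), c(0, 11e4))
  # 30% of the large CNV but 100% of the small one: still one CNVR
  cs2 <- build_cnvrs(mk_cnvs(list("s1", 0, 1e5), list("s2", 3e4, 6e4)))
  expect_equal(nrow(cs2$cnvrs), 1)
  expect_equal(cs2$cnvrs$n_samples, 2)
  # the same pair under the stricter reciprocal rule would NOT merge
  expect_equal(reciprocal_overlap("chr1", 0, 1e5, "chr1", 3e4, 6e4), 0.3)
})

test_that("overlapping dup and del form separate CNVRs", {
  cs <- build_cnvrs(mk_cnvs(list("s1", 0, 1e5, type = "dup"),
                            list("s2", 0, 1e5, type = "del")))
  expect_equal(nrow(cs$cnvrs), 2)
  expect_setequal(cs$cnvrs$type, c("dup", "del"))
})

test_that("every consensus CNV belongs to exactly one CNVR (partition)", {
  set.seed(201)
  for (k in 1:10) {
    cnvs <- rand_calls(150, n_samples = 10)[, c("sample_id", "chrom",
                                                "start", "end", "type")]
    cs <- build_cnvrs(cnvs)
    expect_equal(nrow(cs$members), nrow(cnvs))
    expect_false(anyNA(cs$members$cnvr_id))
    expect_equal(sum(cs$cnvrs$n_members), nrow(cnvs))
    expect_setequal(unique(cs$members$cnvr_id), cs$cnvrs$cnvr_id)
  }
})

test_that("CNVR clustering matches the brute-force oracle on random instances", {
  set.seed(202)
  for (k in 1:40) {
    cnvs <- rand_calls(sample(2:150, 1), n_samples = 8)[
      , c("sample_id", "chrom", "start", "end", "type")]
    cs <- build_cnvrs(cnvs)
    got <- canon_partition(cs$members$cnvr_id)
    want <- canon_partition(oracle_cluster(cnvs, 0.4, "max"))
    expect_equal(got, want)
  }
})

test_that("count_singletons = FALSE drops single-member regions only", {
  cnvs <- mk_cnvs(list("s1", 0, 1e5), list("s2", 1e4, 11e4),
                  list("s3", 5e6, 51e5))
  cs <- build_cnvrs(cnvs, count_singletons = FALSE)
  expect_equal(nrow(cs$cnvrs), 1)
  expect_equal(cs$cnvrs$n_members, 2)
  expect_equal(sum(is.na(cs$members$cnvr_id)), 1)
})

test_that("sharing summary counts co-membership, uniqueness and rates", {
  meta <- data.frame(sample_id = c("a1", "a2", "b1"),
                     group = c("A", "A", "B"), stringsAsFactors = FALSE)
  # disjoint pools: zero sharing
  cs <- build_cnvrs(mk_cnvs(list("a1", 0, 1e5), list("b1", 5e6, 51e5)),
                    meta = meta)
  ss <- sharing_summary(cs, meta, "A", "B")
  expect_equal(ss$pool_size, 1)
  expect_equal(unname(ss$shared["B"]), 0L)
  expect_equal(ss$unique_fraction, 1)
  expect_equal(ss$per_sample_rate, 0.5)
  # focal group vs itself shares its whole pool
  expect_equal(unname(sharing_summary(cs, meta, "A", "A")$shared["A"]),
               ss$pool_size)
  # co-membership in one region counts as shared
  cs2 <- build_cnvrs(mk_cnvs(list("a1", 0, 1e5), list("b1", 0, 1e5)),
                     meta = meta)
  ss2 <- sharing_summary(cs2, meta, "A", "B")
  expect_equal(unname(ss2$shared["B"]), 1L)
  expect_equal(ss2$unique_fraction, 0)
  expect_error(sharing_summary(cs2, meta, "Z"), "no samples")
})

test_that("a configured co-membership rate is recovered within sampling error", {
  set.seed(203)
  n_regions <- 131
  p_share <- 0.35
  shared_truth <- rbinom(n_regions, 1, p_share) == 1
  rows <- list()
  for (i in seq_len(n_regions)) {
    s <- (i - 1) * 1e6
    rows[[length(rows) + 1]] <- mk_cnvs(list(sprintf("g1_%02d", (i %% 9) + 1), s, s + 5e4))
    if (shared_truth[i]) {
      rows[[length(rows) + 1]] <- mk_cnvs(list(sprintf("g2_%02d", (i %% 8) + 1), s, s + 5e4))
    }
  }
  cnvs <- do.call(rbind, rows)
  meta <- data.frame(sample_id = unique(cnvs$sample_id), stringsAsFactors = FALSE)
  meta$group <- ifelse(grepl("^g1", meta$sample_id), "G1", "G2")
  cs <- build_cnvrs(cnvs, meta = meta)
  ss <- sharing_summary(cs, meta, "G1", "G2")
  expect_equal(ss$pool_size, n_regions)
  se <- sqrt(p_share * (1 - p_share) / n_regions)
  expect_lt(abs(ss$shared_fraction[["G2"]] - p_share), 3 * se)
})

test_that("Venn-style sharing counts are internally consistent on random cohorts", {
  set.seed(204)
  for (k in 1:5) {
    cnvs <- rand_calls(200, n_samples = 12)[, c("sample_id", "chrom",
                                                "start", "end", "type")]
    meta <- data.frame(sample_id = paste0("S", 1:12),
                       group = rep(c("A", "B", "C"), each = 4),
                       stringsAsFactors = FALSE)
    cs <- build_cnvrs(cnvs, meta = meta)
    for (g in c("A", "B", "C")) {
      ss <- sharing_summary(cs, meta, g)
      # unique + shared-with-anyone = pool (inclusion-exclusion on members)
      m <- cs$members
      m$group <- meta$group[match(m$sample_id, meta$sample_id)]
      pool <- unique(m$cnvr_id[m$group == g])
      with_other <- unique(m$cnvr_id[m$group != g])
      expect_equal(ss$pool_size, length(pool))
      expect_equal(ss$n_unique, length(setdiff(pool, with_other)))
      expect_equal(ss$n_unique + length(intersect(pool, with_other)),
                   ss$pool_size)
    }
  }
})

test_that("inheritance labels follow the parental-match rules", {
  fam <- data.frame(sample_id = c("pl", "mo", "fa"),
                    role = c("placenta", "mother", "father"),
                    stringsAsFactors = FALSE)
  pl_del <- data.frame(chrom = "chr1", start = 0, end = 1e5, type = "del")
  mo_match <- data.frame(sample_id = "mo", chrom = "chr1", start = 5e3,
                         end = 1.05e5, type = "del", stringsAsFactors = FALSE)
  none <- mo_match[0, ]
  # reciprocal ~0.9 match to the mother; father genotyped and negative
  expect_equal(annotate_inheritance(pl_del, fam, mo_match), "maternal")
  # both parents genotyped, no match -> somatic
  expect_equal(annotate_inheritance(pl_del, fam, none), "somatic")
  # same interval but wrong type does not match
  mo_dup <- transform(mo_match, type = "dup")
  expect_equal(annotate_inheritance(pl_del, fam, mo_dup), "somatic")
  # only the mother profiled and negative -> paternal_or_somatic
  duo <- fam[fam$role != "father", ]
  expect_equal(annotate_inheritance(pl_del, duo, none), "paternal_or_somatic")
  # only the father profiled and negative -> maternal_or_somatic
  duo_f <- fam[fam$role != "mother", ]
  expect_equal(annotate_inheritance(pl_del, duo_f, none), "maternal_or_somatic")
  # no family link
  expect_equal(annotate_inheritance(pl_del, fam[0, ], none), "unknown")
})
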