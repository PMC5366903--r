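# Independent brute-force oracles and random-instance generators used by the
# unit and acceptance tests. These are deliberately naive (all-pairs matrices,
# per-bp scans, full hypergeometric enumeration) and share no code with the
# package's implementation paths.

# canonical form of a partition label vector (ids by first appearance)
canon_partition <- function(cl) match(cl, unique(cl))

# All-pairs single-linkage clustering oracle: full n x n fraction matrix,
# adjacency, connected components via igraph. rule = "reciprocal" (min) or
# "max" (coverage of at least one).
oracle_cluster <- function(df, min_frac, rule = c("reciprocal", "max")) {
  rule <- match.arg(rule)
  n <- nrow(df)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  ov <- outer(seq_len(n), seq_len(n), function(i, j) {
    pmax(0, pmin(df$end[i], df$end[j]) - pmax(df$start[i], df$start[j]))
  })
  same <- outer(df$chrom, df$chrom, "==") & outer(df$type, df$type, "==")
  len <- df$end - df$start
  fi <- sweep(ov, 1, len, "/")
  fj <- sweep(ov, 2, len, "/")
  fr <- if (rule == "reciprocal") pmin(fi, fj) else pmax(fi, fj)
  adj <- same & fr >= min_frac
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# Consensus oracle: cluster one sample's calls with the reciprocal rule,
# keep components with >= min_callers distinct callers, report union spans
# sorted by (chrom, start, end, type).
oracle_consensus <- function(calls, min_rec = 0.4, min_callers = 2) {
  cl <- oracle_cluster(calls, min_rec, "reciprocal")
  out <- do.call(rbind, lapply(split(seq_len(nrow(calls)), cl), function(ix) {
    if (length(unique(calls$caller_id[ix])) < min_callers) return(NULL)
    data.frame(chrom = calls$chrom[ix][1], start = min(calls$start[ix]),
               end = max(calls$end[ix]), type = calls$type[ix][1],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), type = character(0)))
  }
  out <- out[order(out$chrom, out$start, out$end, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-bp genomic-context oracle on a small chromosome.
oracle_classify <- function(start, end, L, cc, window_frac = 0.05) {
  w <- round(window_frac * L)
  bp <- seq(start, end - 1)
  subtel <- any(bp < w | bp >= L - w)
  peri <- any(bp >= max(0, cc - w) & bp < min(L, cc + w))
  list(pericentromeric = peri, subtelomeric = subtel,
       primary_label = if (peri) "pericentromeric" else
         if (subtel) "subtelomeric" else "interstitial")
}

# Exact two-sided Fisher p by full enumeration of the hypergeometric support
# (sum of point probabilities <= observed, with the conventional relative
# tolerance).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(m, k)
  dd <- stats::dhyper(supp, m, n, k)
  sum(dd[dd <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Welch t-test p from the closed-form statistic and Welch-Satterthwaite df.
oracle_welch_p <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tt), df)
}

# Random call-table generator for oracle-equivalence tests.
rand_calls <- function(n, n_chrom = 2, chrom_len = 1e6, n_callers = 3,
                       n_samples = 1) {
  len <- pmax(10, round(stats::rlnorm(n, log(3e4), 1.2)))
  len <- pmin(len, chrom_len %/% 2)
  start <- floor(stats::runif(n, 0, chrom_len - len))
  data.frame(
    sample_id = paste0("S", sample.int(n_samples, n, replace = TRUE)),
    caller_id = paste0("caller", sample(LETTERS[1:n_callers], n, replace = TRUE)),
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start, end = start + len,
    type = sample(c("dup", "del"), n, replace = TRUE),
    confidence = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Small fast simulation config for tests (one chromosome set, fewer genes).
test_sim_config <- function(seed = 42, ...) {
  sim_config(seed = seed, n_genes = 300, ...)
}
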