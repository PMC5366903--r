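# Shared internal helpers: union-find, overlapping-pair sweep, validation.

# Iterative union-find with path halving. parent is an integer vector;
# returns updated parent after union of all edge pairs.
.uf_new <- function(n) seq_len(n)

.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Union edges (two-column integer matrix) into parent; returns parent.
.uf_union_edges <- function(parent, edges) {
  if (length(edges) == 0L) return(parent)
  for (k in seq_len(nrow(edges))) {
    ri <- .uf_find(parent, edges[k, 1L])
    rj <- .uf_find(parent, edges[k, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  parent
}

# Component labels (1..k, in order of first appearance) from a parent vector.
.uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) .uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

# Enumerate all index pairs (i, j), i < j in start-order, whose intervals
# share >= 1 bp, within one chromosome. start/end must be sorted by start.
# Returns a 2-column matrix of indices into the sorted order.
.overlapping_pairs <- function(start, end) {
  n <- length(start)
  out_i <- integer(0)
  out_j <- integer(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && start[j] < end[i]) {
        out_i <- c(out_i, i)
        out_j <- c(out_j, j)
        j <- j + 1L
      }
    }
  }
  cbind(out_i, out_j)
}

# Single-linkage clustering of intervals under an overlap-fraction criterion.
# df must have chrom, start, end, type columns. frac_fun computes the pairwise
# fraction ("reciprocal" = min rule, "max" = coverage-of-at-least-one rule).
# Returns an integer cluster id per row of df (ids ordered by chrom, start,
# type of the cluster's first member).
.cluster_intervals <- function(df, min_frac, rule = c("reciprocal", "max")) {
  rule <- match.arg(rule)
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  cl <- integer(n)
  next_id <- 0L
  key <- paste(df$chrom, df$type, sep = "\r")
  for (grp in split(seq_len(n), key)) {
    ord <- grp[order(df$start[grp], df$end[grp])]
    s <- df$start[ord]; e <- df$end[ord]
    parent <- .uf_new(length(ord))
    pairs <- .overlapping_pairs(s, e)
    if (nrow(pairs) > 0L) {
      ov <- pmin(e[pairs[, 1L]], e[pairs[, 2L]]) - pmax(s[pairs[, 1L]], s[pairs[, 2L]])
      f1 <- ov / (e[pairs[, 1L]] - s[pairs[, 1L]])
      f2 <- ov / (e[pairs[, 2L]] - s[pairs[, 2L]])
      fr <- if (rule == "reciprocal") pmin(f1, f2) else pmax(f1, f2)
      parent <- .uf_union_edges(parent, pairs[fr >= min_frac, , drop = FALSE])
    }
    comp <- .uf_components(parent)
    cl[ord] <- comp + next_id
    next_id <- next_id + max(comp)
  }
  # renumber deterministically by (chrom, min start, min end, type) per cluster
  ids <- sort(unique(cl))
  chrom_c <- vapply(ids, function(k) df$chrom[cl == k][1L], character(1))
  type_c <- vapply(ids, function(k) df$type[cl == k][1L], character(1))
  start_c <- vapply(ids, function(k) min(df$start[cl == k]), numeric(1))
  end_c <- vapply(ids, function(k) min(df$end[cl == k]), numeric(1))
  lead <- order(chrom_c, start_c, end_c, type_c)
  remap <- integer(length(ids))
  remap[ids[lead]] <- seq_along(lead)
  remap[cl]
}

.assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

.assert_type <- function(type) {
  bad <- setdiff(unique(as.character(type)), c("dup", "del"))
  if (length(bad)) stop("unknown CNV type(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
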