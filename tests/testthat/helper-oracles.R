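# Independent brute-force oracles used to cross-check the package's
# interval, locus-calling and multiplicity machinery. These deliberately
# share no code with the implementation.

# all-pairs interval overlap (0-based half-open)
bf_overlap_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] && a$end[i] > b$start[j]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

# edge-to-edge gap (0 when overlapping or adjacent) to the nearest subject
bf_nearest <- function(a, b) {
  res <- data.frame(nearest = rep(NA_integer_, nrow(a)),
                    distance = rep(NA_real_, nrow(a)))
  for (i in seq_len(nrow(a))) {
    best <- NA_integer_; bestd <- Inf
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      d <- max(0, max(b$start[j] - a$end[i], a$start[i] - b$end[j]))
      if (d < bestd) { bestd <- d; best <- j }
    }
    if (!is.na(best)) { res$nearest[i] <- best; res$distance[i] <- bestd }
  }
  res
}

# union-find clustering of reads under the gap-<=-pad relation
bf_call_loci <- function(reads, pad, min_reads) {
  n <- nrow(reads)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || reads$chrom[i] != reads$chrom[j]) next
      gap <- max(reads$start[j] - reads$end[i], reads$start[i] - reads$end[j])
      if (gap <= pad) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  out <- list()
  for (r in unique(root)) {
    idx <- which(root == r)
    w <- sum(reads$weight[idx])
    if (w < min_reads) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = reads$chrom[idx[1]], start = min(reads$start[idx]),
      end = max(reads$end[idx]), weight = w)
  }
  if (!length(out)) return(data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), weight = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# textbook BH step-up
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 10000,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_reads <- function(n, chrom = "c1", span = 10000) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = start + sample(15:35, n, replace = TRUE),
             strand = ".", length = NA_integer_, weight = 1,
             sample_id = sample(c("sA", "sB"), n, replace = TRUE),
             stringsAsFactors = FALSE) -> r
  r$length <- r$end - r$start
  r
}

parent_meta_3v3 <- function() {
  data.frame(sample_id = sprintf("s%d", 1:6), generation = "parent",
             treatment = rep(c("control", "wounded"), each = 3),
             timepoint = "72h", leaf_pair = "second",
             maternal_line = NA_character_, stringsAsFactors = FALSE)
}
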