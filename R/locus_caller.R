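# Locus calling: merged coverage islands over pooled reads. Reads from all
# libraries are pooled to define one locus set; per-sample counts are then
# computed against the fixed loci. Two reads belong to one locus iff the gap
# between them (next.start - prev.end) is <= pad, transitively.

#' Call small-RNA loci from pooled read alignments
#'
#' Merges reads into coverage islands: reads whose gap is at most `pad`
#' (transitively) form one locus; islands with total read weight below
#' `min_reads` are dropped. The locus interval is the min start / max end of
#' its member reads, and per-locus read-length profiles and per-sample counts
#' are accumulated from read weights.
#'
#' @param reads data.frame of read alignments from all samples, as returned
#'   by [read_reads_bed] (columns `chrom`, `start`, `end`, `length`,
#'   `weight`, `sample_id`).
#' @param pad maximum gap (nt) between reads of one locus; default 75.
#' @param min_reads minimum total read weight per retained locus; default 5.
#' @param sample_ids optional character vector fixing the sample (column)
#'   universe; defaults to the samples present in `reads`.
#' @return object of class `srna_loci`: list with
#'   * `loci`: data.frame `id` (`chrom:start-end`), `chrom`, `start`, `end`,
#'     `length`, `n_reads` (total weight);
#'   * `profiles`: matrix loci x read lengths 15..35 of summed weight;
#'   * `counts`: matrix loci x samples of summed weight;
#'   * `pad`, `min_reads`: the parameters used.
#' @export
call_loci <- function(reads, pad = 75L, min_reads = 5, sample_ids = NULL) {
  stopifnot(pad >= 0, min_reads > 0)
  if (is.null(sample_ids)) sample_ids <- sort(unique(as.character(reads$sample_id)))
  lens <- 15:35
  empty <- structure(list(
    loci = data.frame(id = character(0), chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0), n_reads = numeric(0)),
    profiles = matrix(0, 0, length(lens), dimnames = list(NULL, lens)),
    counts = matrix(0, 0, length(sample_ids), dimnames = list(NULL, sample_ids)),
    pad = pad, min_reads = min_reads), class = "srna_loci")
  if (!nrow(reads)) return(empty)

  gr <- as_granges0(reads)
  islands <- GenomicRanges::reduce(gr, min.gapwidth = pad + 1L)
  hits <- GenomicRanges::findOverlaps(gr, islands)
  memb <- S4Vectors::subjectHits(hits) # each read falls in exactly one island

  n_isl <- length(islands)
  w <- reads$weight
  total_w <- as.vector(tapply(w, factor(memb, levels = seq_len(n_isl)), sum, default = 0))
  keep <- which(total_w >= min_reads)
  if (!length(keep)) return(empty)

  isl <- islands[keep]
  remap <- rep(NA_integer_, n_isl)
  remap[keep] <- seq_along(keep)
  ri <- remap[memb]
  sel <- !is.na(ri)

  chrom <- as.character(GenomeInfoDb::seqnames(isl))
  start0 <- GenomicRanges::start(isl) - 1L
  end0 <- GenomicRanges::end(isl)
  loci <- data.frame(
    id = sprintf("%s:%d-%d", chrom, start0, end0),
    chrom = chrom, start = start0, end = end0,
    length = end0 - start0, n_reads = total_w[keep],
    stringsAsFactors = FALSE
  )

  fl <- factor(reads$length[sel], levels = lens)
  fi <- factor(ri[sel], levels = seq_along(keep))
  profiles <- as.matrix(stats::xtabs(w ~ i + l,
    data = data.frame(w = w[sel], i = fi, l = fl)))
  dimnames(profiles) <- list(loci$id, lens)
  fs <- factor(as.character(reads$sample_id)[sel], levels = sample_ids)
  counts <- as.matrix(stats::xtabs(w ~ i + s,
    data = data.frame(w = w[sel], i = fi, s = fs)))
  dimnames(counts) <- list(loci$id, sample_ids)

  structure(list(loci = loci, profiles = profiles, counts = counts,
                 pad = pad, min_reads = min_reads), class = "srna_loci")
}

#' @export
print.srna_loci <- function(x, ...) {
  cat(sprintf("srna_loci: %d loci (pad=%d, min_reads=%g), %d samples\n",
              nrow(x$loci), x$pad, x$min_reads, ncol(x$counts)))
  invisible(x)
}

#' Read-length profile of one locus
#'
#' Sums member-read weights by read length (15-35 nt).
#'
#' @param locus single-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param reads data.frame of reads; only reads overlapping the locus
#'   interval contribute.
#' @return named numeric vector over lengths 15..35 with attribute `total`.
#' @export
profile_locus <- function(locus, reads) {
  on <- reads$chrom == locus$chrom & reads$start < locus$end & reads$end > locus$start
  prof <- tapply(reads$weight[on], factor(reads$length[on], levels = 15:35),
                 sum, default = 0)
  out <- as.numeric(prof)
  names(out) <- 15:35
  attr(out, "total") <- sum(out)
  out
}

#' Reads per million
#'
#' @param counts numeric vector/matrix of raw counts.
#' @param library_size matching per-sample library sizes (recycled across
#'   rows when `counts` is a matrix).
#' @return counts / library_size * 1e6.
#' @export
rpm <- function(counts, library_size) {
  if (is.matrix(counts)) {
    sweep(counts, 2, library_size, "/") * 1e6
  } else {
    counts / library_size * 1e6
  }
}

#' Mean RPM per locus across samples
#' @param cm a [count_matrix].
#' @return numeric vector, one mean RPM per locus.
#' @export
mean_rpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  rowMeans(rpm(cm$counts, cm$library_sizes))
}
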