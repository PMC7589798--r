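# Internal interval machinery. All coordinates in the package are 0-based
# half-open; conversion to the 1-based closed convention of GRanges (and of
# GFF3 on disk) happens only here and in the I/O layer. Strand is carried but
# ignored for overlap and distance; only tRF side-calling consults it.

#' Validate a set of genomic intervals
#'
#' Checks the package-wide coordinate invariants: `start >= 0`, `end > start`,
#' strand in `{+, -, .}`.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (0-based half-open).
#' @param what label used in error messages.
#' @return the input, invisibly, with a `strand` column guaranteed.
#' @keywords internal
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s table lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (is.null(df$strand)) df$strand <- "."
  if (nrow(df)) {
    if (any(df$start < 0)) stop(sprintf("%s: negative start coordinate", what))
    if (any(df$end <= df$start)) {
      bad <- which(df$end <= df$start)[1L]
      stop(sprintf("%s: end <= start at row %d (%s:%d-%d)", what, bad,
                   df$chrom[bad], df$start[bad], df$end[bad]))
    }
    if (!all(df$strand %in% c("+", "-", "."))) stop(sprintf("%s: invalid strand symbol", what))
  }
  invisible(df)
}

# 0-based half-open data.frame -> GRanges (strand dropped to "*": overlap and
# distance are strand-blind by design).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' All overlapping pairs between two interval sets
#'
#' @param query,subject data.frames of 0-based half-open intervals.
#' @return data.frame with integer columns `query`, `subject`, one row per
#'   pair of intervals sharing at least one base.
#' @keywords internal
overlap_pairs <- function(query, subject) {
  if (!nrow(query) || !nrow(subject)) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Edge-to-edge distance to the nearest interval
#'
#' Distance is the gap in bases between interval edges: 0 when the intervals
#' share a base (or are directly adjacent), otherwise the number of bases
#' separating them. Intervals on different sequences are never neighbours.
#'
#' @param query,subject data.frames of 0-based half-open intervals.
#' @return data.frame with one row per query: `nearest` (row index into
#'   `subject`, NA if no subject on the same sequence) and `distance`.
#' @keywords internal
nearest_distance <- function(query, subject) {
  out <- data.frame(nearest = rep(NA_integer_, nrow(query)),
                    distance = rep(NA_real_, nrow(query)))
  if (!nrow(query) || !nrow(subject)) return(out)
  q <- as_granges0(query)
  s <- as_granges0(subject)
  GenomeInfoDb::seqlevels(q) <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(s) <- GenomeInfoDb::seqlevels(q)
  hits <- GenomicRanges::distanceToNearest(q, s)
  qi <- S4Vectors::queryHits(hits)
  out$nearest[qi] <- S4Vectors::subjectHits(hits)
  out$distance[qi] <- S4Vectors::mcols(hits)$distance
  out
}
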