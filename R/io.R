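# I/O for the standard formats the pipeline touches: GFF3 annotation (genes
# with CDS children, transposable elements, tRNA genes with anticodon
# sub-intervals), BED6 small-RNA read alignments, TSV count/DMR/DEG/metadata
# tables. GFF3 and BED are parsed through rtracklayer; this layer only
# converts conventions (GFF3 is 1-based closed; everything internal is
# 0-based half-open) and enforces validity.

GFF3_KINDS <- c(gene = "gene", CDS = "CDS",
                transposable_element = "TE", TE = "TE", tRNA = "tRNA")

#' Construct a feature set
#'
#' Container for the genomic annotation the analysis consumes: gene/CDS/TE
#' and tRNA features, plus (optionally) externally supplied tables of
#' differentially methylated regions and differentially expressed genes.
#'
#' @param features data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `kind` (gene/CDS/TE/tRNA), `id`, `parent` (gene id for CDS, else NA), and
#'   for tRNAs `anticodon`, `amino_acid`, `ac_start`, `ac_end` (0-based
#'   half-open anticodon interval, strictly inside the tRNA).
#' @param dmrs data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `direction` (up/down: methylation change in progeny of wounded plants)
#'   and `context` (CG/CHG/CHH/any), or NULL.
#' @param degs data.frame with `gene_id`, `direction` (up/down/none) and
#'   `mean_expression` (non-negative control mean), or NULL.
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(features, dmrs = NULL, degs = NULL) {
  features <- validate_intervals(as.data.frame(features), "feature")
  for (col in c("kind", "id")) {
    if (is.null(features[[col]])) stop("feature table lacks column: ", col)
  }
  if (is.null(features$parent)) features$parent <- NA_character_
  for (col in c("anticodon", "amino_acid")) {
    if (is.null(features[[col]])) features[[col]] <- NA_character_
  }
  for (col in c("ac_start", "ac_end")) {
    if (is.null(features[[col]])) features[[col]] <- NA_real_
  }
  if (anyDuplicated(features$id)) {
    stop("feature ids are not unique: ", features$id[duplicated(features$id)][1L])
  }
  if (!all(features$kind %in% c("gene", "CDS", "TE", "tRNA"))) {
    stop("unknown feature kind: ",
         setdiff(unique(features$kind), c("gene", "CDS", "TE", "tRNA"))[1L])
  }
  tr <- features$kind == "tRNA"
  if (any(tr)) {
    bad <- tr & (is.na(features$ac_start) | is.na(features$ac_end) |
                   features$ac_start < features$start |
                   features$ac_end > features$end |
                   features$ac_end <= features$ac_start)
    if (any(bad)) {
      stop("tRNA feature without a valid anticodon interval strictly inside it: ",
           features$id[bad][1L])
    }
  }
  if (!is.null(dmrs)) {
    dmrs <- validate_intervals(as.data.frame(dmrs), "DMR")
    if (is.null(dmrs$direction) || !all(dmrs$direction %in% c("up", "down"))) {
      stop("DMR table needs a direction column with values up/down")
    }
    if (is.null(dmrs$context)) dmrs$context <- "any"
  }
  if (!is.null(degs)) {
    degs <- as.data.frame(degs)
    if (is.null(degs$gene_id) || is.null(degs$direction)) {
      stop("DEG table needs gene_id and direction columns")
    }
    if (!all(degs$direction %in% c("up", "down", "none"))) {
      stop("DEG direction must be up/down/none")
    }
    if (is.null(degs$mean_expression)) degs$mean_expression <- NA_real_
    if (any(degs$mean_expression < 0, na.rm = TRUE)) {
      stop("DEG mean_expression must be non-negative")
    }
    genes <- features$id[features$kind == "gene"]
    unknown <- setdiff(degs$gene_id, genes)
    if (length(unknown)) {
      stop("DEG gene_id not present among gene features: ", unknown[1L])
    }
  }
  structure(list(features = features, dmrs = dmrs, degs = degs),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  tab <- table(x$features$kind)
  cat("feature_set:", paste(sprintf("%d %s", tab, names(tab)), collapse = ", "))
  if (!is.null(x$dmrs)) cat(";", nrow(x$dmrs), "DMRs")
  if (!is.null(x$degs)) cat(";", nrow(x$degs), "DEGs")
  cat("\n")
  invisible(x)
}

# Light pre-scan so malformed GFF3 is reported with a line number before
# rtracklayer sees it.
scan_gff3_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stop(sprintf("GFF3 parse error at line %d: %d field(s)", i, length(f)))
    s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e)) stop(sprintf("GFF3 parse error at line %d: non-numeric coordinates", i))
    if (e < s) stop(sprintf("GFF3 coordinate error at line %d: end < start", i))
  }
  invisible(length(body))
}

#' Read a GFF3 annotation into a feature_set
#'
#' Converts GFF3 1-based inclusive coordinates to the internal 0-based
#' half-open convention. tRNA anticodons may be encoded either as child
#' features of type `anticodon` or as `anticodon=...;amino_acid=...;
#' ac_start=...;ac_end=...` attributes (1-based inclusive) on the tRNA line.
#' CDS features are grouped under their parent gene via the `Parent`
#' attribute.
#'
#' @param path path to a GFF3 file.
#' @return a [feature_set] (with empty DMR/DEG slots).
#' @export
read_gff3 <- function(path) {
  scan_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(name) {
    if (name %in% names(mc)) as.character(mc[[name]]) else rep(NA_character_, length(gr))
  }
  parent <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  id <- get_attr("ID")
  keep <- df$type %in% names(GFF3_KINDS)
  feats <- data.frame(
    chrom = as.character(df$seqnames)[keep],
    start = df$start[keep] - 1L,
    end = df$end[keep],
    strand = ifelse(as.character(df$strand)[keep] == "*", ".",
                    as.character(df$strand)[keep]),
    kind = unname(GFF3_KINDS[df$type[keep]]),
    id = id[keep],
    parent = parent[keep],
    anticodon = get_attr("anticodon")[keep],
    amino_acid = get_attr("amino_acid")[keep],
    ac_start = suppressWarnings(as.numeric(get_attr("ac_start")))[keep] - 1,
    ac_end = suppressWarnings(as.numeric(get_attr("ac_end")))[keep],
    stringsAsFactors = FALSE
  )
  feats$id[is.na(feats$id)] <- sprintf("feat_%d", which(is.na(feats$id)))
  # anticodon child features attach to their parent tRNA
  ac_rows <- df$type == "anticodon"
  if (any(ac_rows)) {
    for (j in which(ac_rows)) {
      p <- parent[j]
      k <- which(feats$kind == "tRNA" & feats$id == p)
      if (length(k) == 1L) {
        feats$ac_start[k] <- df$start[j] - 1
        feats$ac_end[k] <- df$end[j]
        if (!is.na(get_attr("anticodon")[j])) feats$anticodon[k] <- get_attr("anticodon")[j]
        if (!is.na(get_attr("amino_acid")[j])) feats$amino_acid[k] <- get_attr("amino_acid")[j]
      }
    }
  }
  feature_set(feats)
}

#' Write a feature_set back to GFF3
#'
#' Inverse of [read_gff3]: internal 0-based half-open coordinates become
#' 1-based inclusive, tRNA anticodons are emitted as attributes on the tRNA
#' line, CDS carry a `Parent` attribute.
#'
#' @param fs a [feature_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  f <- fs$features
  type <- c(gene = "gene", CDS = "CDS", TE = "transposable_element", tRNA = "tRNA")[f$kind]
  attrs <- sprintf("ID=%s", f$id)
  has_parent <- !is.na(f$parent)
  attrs[has_parent] <- sprintf("%s;Parent=%s", attrs[has_parent], f$parent[has_parent])
  tr <- f$kind == "tRNA"
  attrs[tr] <- sprintf("%s;anticodon=%s;amino_acid=%s;ac_start=%d;ac_end=%d",
                       attrs[tr], f$anticodon[tr], f$amino_acid[tr],
                       as.integer(f$ac_start[tr]) + 1L, as.integer(f$ac_end[tr]))
  lines <- sprintf("%s\tsrnaplast\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   f$chrom, type, f$start + 1L, f$end, f$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read small-RNA read alignments from BED6
#'
#' BED is 0-based half-open, preserved as written. Records whose length
#' (`end - start`) falls outside the global small-RNA bounds of 15-35 nt are
#' rejected and counted (attribute `rejects` of the result).
#'
#' @param path BED6 file (may be empty).
#' @param sample_id library identifier attached to every read.
#' @param use_score use the BED score column as a fractional multi-mapper
#'   weight (default FALSE: every read has weight 1).
#' @param min_len,max_len read-length bounds.
#' @return data.frame of reads (`chrom`, `start`, `end`, `strand`, `length`,
#'   `weight`, `sample_id`) with attribute `rejects` = number of records
#'   dropped by the length filter.
#' @export
read_reads_bed <- function(path, sample_id, use_score = FALSE,
                           min_len = 15L, max_len = 35L) {
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      weight = numeric(0), sample_id = character(0))
  attr(empty, "rejects") <- 0L
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) return(empty)
  gr <- rtracklayer::import(path, format = "bed")
  if (!length(gr)) return(empty)
  w <- if (use_score && !is.null(gr$score)) as.numeric(gr$score) else rep(1, length(gr))
  reads <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", ".",
                    as.character(GenomicRanges::strand(gr))),
    weight = w,
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  reads$length <- reads$end - reads$start
  ok <- reads$length >= min_len & reads$length <= max_len
  out <- reads[ok, c("chrom", "start", "end", "strand", "length", "weight", "sample_id")]
  rownames(out) <- NULL
  attr(out, "rejects") <- sum(!ok)
  out
}

#' Construct a count matrix
#'
#' @param counts numeric matrix, loci in rows (rownames = locus ids), samples
#'   in columns (colnames = sample ids); non-negative.
#' @param meta optional sample metadata data.frame (see [read_sample_meta]);
#'   when supplied, every count column must match a metadata row, and library
#'   sizes come from the metadata where present.
#' @param library_sizes optional named per-sample totals; default column sums.
#' @return an object of class `count_matrix`: list with elements `counts`,
#'   `meta`, `library_sizes`, `size_factors` (NULL until estimated).
#' @export
count_matrix <- function(counts, meta = NULL, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("count matrix needs locus ids as rownames")
  if (is.null(colnames(counts))) stop("count matrix needs sample ids as colnames")
  bad <- which(counts < 0 | !is.finite(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at locus '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  if (!is.null(meta)) {
    meta <- validate_sample_meta(meta)
    unknown <- setdiff(colnames(counts), meta$sample_id)
    if (length(unknown)) stop("count column has no sample metadata: ", unknown[1L])
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
    if (is.null(library_sizes) && !is.null(meta$library_size) &&
        !anyNA(meta$library_size)) {
      library_sizes <- stats::setNames(meta$library_size, meta$sample_id)
    }
  }
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- library_sizes[colnames(counts)]
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  structure(list(counts = counts, meta = meta,
                 library_sizes = library_sizes, size_factors = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d loci x %d samples (median library %.3g)\n",
              nrow(x$counts), ncol(x$counts), stats::median(x$library_sizes)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

validate_sample_meta <- function(meta) {
  meta <- as.data.frame(meta)
  need <- c("sample_id", "generation", "treatment")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(meta$generation %in% c("parent", "offspring"))) stop("generation must be parent/offspring")
  if (!all(meta$treatment %in% c("wounded", "control"))) stop("treatment must be wounded/control")
  if (is.null(meta$timepoint)) meta$timepoint <- NA_character_
  if (is.null(meta$leaf_pair)) meta$leaf_pair <- NA_character_
  if (is.null(meta$maternal_line)) meta$maternal_line <- NA_character_
  off <- meta$generation == "offspring"
  if (any(off & (is.na(meta$maternal_line) | meta$maternal_line == ""))) {
    stop("offspring samples must carry a maternal_line")
  }
  if (any(!off & is.na(meta$timepoint))) stop("parent samples must carry a timepoint")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  meta
}

#' Read a per-locus count table (TSV)
#'
#' First column: locus id; remaining columns: per-sample counts. Counts must
#' be non-negative; a validation error names the offending cell.
#'
#' @param path TSV file.
#' @param meta optional sample metadata (data.frame or path).
#' @return a [count_matrix].
#' @export
read_count_table <- function(path, meta = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table needs a locus id column plus sample columns")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1L]])
  if (is.character(meta)) meta <- read_sample_meta(meta)
  count_matrix(m, meta = meta)
}

#' Read sample metadata (TSV)
#' @param path TSV with columns sample_id, generation, treatment, timepoint,
#'   leaf_pair, maternal_line, library_size.
#' @return validated data.frame.
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(utils::read.delim(path, stringsAsFactors = FALSE,
                                         na.strings = c("NA", "")))
}

#' Read a DMR table (TSV; 0-based half-open coordinates)
#' @param path TSV with columns chrom, start, end, direction (up/down),
#'   context (CG/CHG/CHH/any).
#' @return validated data.frame.
#' @export
read_dmr_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d <- validate_intervals(d, "DMR")
  if (!all(d$direction %in% c("up", "down"))) stop("DMR direction must be up/down")
  if (is.null(d$context)) d$context <- "any"
  d
}

#' Read a DEG table (TSV)
#' @param path TSV with columns gene_id, direction (up/down/none),
#'   mean_expression.
#' @return validated data.frame.
#' @export
read_deg_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "direction") %in% names(d))) {
    stop("DEG table needs gene_id and direction columns")
  }
  if (!all(d$direction %in% c("up", "down", "none"))) stop("DEG direction must be up/down/none")
  d
}

#' Write a results table as TSV
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count_matrix as TSV (locus id first column)
#' @param cm a [count_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- data.frame(locus_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
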