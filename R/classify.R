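# Three-way locus classification by read-length composition, genomic-context
# annotation (CDS/TE overlap, distance class to nearest gene) and tRF
# side-calling relative to the tRNA anticodon.
#
# The dicer rule: a locus is dicer-derived (siRNA) when the fraction of its
# read weight at 20-24 nt is at least 0.8; its size call is the modal length
# among 20-24 (ties broken toward the longer length, i.e. toward the 24-nt
# RdDM class). miRNA labels are upstream annotations and take precedence.

DICER_LENGTHS <- 20:24

#' Classify one locus from its read-length profile
#'
#' @param profile named numeric vector of summed read weights over lengths
#'   15..35 (as from [profile_locus]); total must be positive.
#' @param mirna_flag logical; TRUE when an upstream annotation marks the
#'   locus as a miRNA (precedence over the size rule).
#' @return list with `label` (one of miRNA, siRNA20..siRNA24, ndsRNA),
#'   `dicer_fraction`, `dicer_call` (modal dicer length or NA) and `stratum`
#'   (miRNA / siRNA20_23 / siRNA24 / ndsRNA — the analysis strata).
#' @export
classify_locus <- function(profile, mirna_flag = FALSE) {
  total <- sum(profile)
  if (!isTRUE(total > 0)) stop("unclassifiable locus: profile total is zero")
  lens <- as.integer(names(profile))
  dmass <- sum(profile[lens %in% DICER_LENGTHS])
  frac <- dmass / total
  if (isTRUE(mirna_flag)) {
    return(list(label = "miRNA", dicer_fraction = frac, dicer_call = NA_integer_,
                stratum = "miRNA"))
  }
  if (frac >= 0.8) {
    d <- profile[lens %in% DICER_LENGTHS]
    dl <- lens[lens %in% DICER_LENGTHS]
    best <- max(d)
    call <- max(dl[d == best]) # tie -> longer length
    list(label = sprintf("siRNA%d", call), dicer_fraction = frac,
         dicer_call = as.integer(call),
         stratum = if (call == 24L) "siRNA24" else "siRNA20_23")
  } else {
    list(label = "ndsRNA", dicer_fraction = frac, dicer_call = NA_integer_,
         stratum = "ndsRNA")
  }
}

#' Classify all loci of an srna_loci object
#'
#' @param loci an `srna_loci` object from [call_loci], or a profile matrix
#'   (loci x lengths 15..35).
#' @param mirna_flags logical vector (or character vector of flagged locus
#'   ids); default none.
#' @return data.frame with `locus_id`, `label`, `dicer_fraction`,
#'   `dicer_call`, `stratum`.
#' @export
classify_loci <- function(loci, mirna_flags = NULL) {
  profiles <- if (inherits(loci, "srna_loci")) loci$profiles else as.matrix(loci)
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- sprintf("locus_%d", seq_len(nrow(profiles)))
  flags <- logical(nrow(profiles))
  if (is.character(mirna_flags)) flags <- ids %in% mirna_flags
  else if (is.logical(mirna_flags)) flags <- rep_len(mirna_flags, nrow(profiles))

  lens <- as.integer(colnames(profiles))
  total <- rowSums(profiles)
  if (any(total <= 0)) stop("unclassifiable locus (zero profile total): ",
                            ids[total <= 0][1L])
  dcols <- lens %in% DICER_LENGTHS
  frac <- rowSums(profiles[, dcols, drop = FALSE]) / total
  dmat <- profiles[, dcols, drop = FALSE]
  dlens <- lens[dcols]
  # modal dicer length, ties toward the longer length: scan from 24 down
  ord <- order(dlens, decreasing = TRUE)
  call <- dlens[ord][max.col(dmat[, ord, drop = FALSE], ties.method = "first")]
  label <- ifelse(flags, "miRNA",
                  ifelse(frac >= 0.8, sprintf("siRNA%d", call), "ndsRNA"))
  stratum <- ifelse(flags, "miRNA",
                    ifelse(frac >= 0.8, ifelse(call == 24L, "siRNA24", "siRNA20_23"),
                           "ndsRNA"))
  data.frame(locus_id = ids, label = label, dicer_fraction = frac,
             dicer_call = ifelse(label %in% sprintf("siRNA%d", DICER_LENGTHS),
                                 call, NA_integer_),
             stratum = stratum, stringsAsFactors = FALSE, row.names = NULL)
}

#' Genomic-context annotation of loci
#'
#' For each locus: whether it shares a base with a CDS or a TE, the nearest
#' gene and its edge-to-edge distance, and the distance class
#' (O: overlapping, distance 0; N: near, within `near_bp`; F: far).
#'
#' @param loci data.frame of locus intervals (`chrom`, `start`, `end`), or an
#'   `srna_loci` object.
#' @param features a [feature_set].
#' @param near_bp near/far boundary in bp (default 5000).
#' @return data.frame with `overlaps_cds`, `overlaps_te`, `nearest_gene_id`,
#'   `nearest_gene_distance`, `distance_class`.
#' @export
annotate_context <- function(loci, features, near_bp = 5000L) {
  if (inherits(loci, "srna_loci")) loci <- loci$loci
  stopifnot(inherits(features, "feature_set"))
  f <- features$features
  cds <- f[f$kind == "CDS", , drop = FALSE]
  te <- f[f$kind == "TE", , drop = FALSE]
  genes <- f[f$kind == "gene", , drop = FALSE]
  n <- nrow(loci)
  out <- data.frame(locus_id = if (!is.null(loci$id)) loci$id else seq_len(n),
                    overlaps_cds = logical(n), overlaps_te = logical(n),
                    nearest_gene_id = NA_character_,
                    nearest_gene_distance = NA_real_,
                    distance_class = NA_character_,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  out$overlaps_cds[unique(overlap_pairs(loci, cds)$query)] <- TRUE
  out$overlaps_te[unique(overlap_pairs(loci, te)$query)] <- TRUE
  nd <- nearest_distance(loci, genes)
  out$nearest_gene_id <- genes$id[nd$nearest]
  out$nearest_gene_distance <- nd$distance
  out$distance_class <- ifelse(is.na(nd$distance), "F",
                        ifelse(nd$distance == 0, "O",
                        ifelse(nd$distance <= near_bp, "N", "F")))
  out
}

#' Classify a tRF locus by side relative to the tRNA anticodon
#'
#' Orientation follows the tRNA's strand: on the plus strand a read entirely
#' before the anticodon interval is 5-prime; on the minus strand the genomic
#' end of the tRNA is its 5' end, so the comparison flips. The locus-level
#' side is a weight-majority vote over its reads on the tRNA; ties go to
#' `anticodon_spanning`.
#'
#' @param locus single-row data.frame with `chrom`, `start`, `end`.
#' @param locus_reads data.frame of the locus's reads (`chrom`, `start`,
#'   `end`, `weight`).
#' @param trna_features data.frame of tRNA features (rows of a
#'   [feature_set]'s features with kind "tRNA"), or a feature_set.
#' @return list with `trna_id`, `anticodon`, `amino_acid`, `side`
#'   (five_prime / three_prime / anticodon_spanning),
#'   `fraction_of_locus_reads_on_trna`; or `NA` when the locus overlaps no
#'   tRNA.
#' @export
annotate_trf <- function(locus, locus_reads, trna_features) {
  if (inherits(trna_features, "feature_set")) {
    trna_features <- trna_features$features[trna_features$features$kind == "tRNA", ,
                                            drop = FALSE]
  }
  hits <- overlap_pairs(as.data.frame(locus), trna_features)
  if (!nrow(hits)) return(NA)
  # if several tRNAs overlap, take the one with most read weight on it
  best <- NULL; best_w <- -1
  for (k in unique(hits$subject)) {
    tr <- trna_features[k, ]
    on <- locus_reads$chrom == tr$chrom & locus_reads$start < tr$end &
      locus_reads$end > tr$start
    wsum <- sum(locus_reads$weight[on])
    if (wsum > best_w) { best <- k; best_w <- wsum }
  }
  tr <- trna_features[best, ]
  on <- locus_reads$chrom == tr$chrom & locus_reads$start < tr$end &
    locus_reads$end > tr$start
  r <- locus_reads[on, , drop = FALSE]
  total_w <- sum(locus_reads$weight)
  if (!nrow(r)) {
    return(list(trna_id = tr$id, anticodon = tr$anticodon,
                amino_acid = tr$amino_acid, side = "anticodon_spanning",
                fraction_of_locus_reads_on_trna = 0))
  }
  if (identical(tr$strand, "-")) {
    five <- r$start >= tr$ac_end    # genomically after the anticodon
    three <- r$end <= tr$ac_start
  } else {
    five <- r$end <= tr$ac_start    # entirely before the anticodon
    three <- r$start >= tr$ac_end
  }
  w5 <- sum(r$weight[five]); w3 <- sum(r$weight[three])
  wspan <- sum(r$weight) - w5 - w3
  side <- if (w5 > w3 && w5 > wspan) "five_prime"
          else if (w3 > w5 && w3 > wspan) "three_prime"
          else "anticodon_spanning"
  list(trna_id = tr$id, anticodon = tr$anticodon, amino_acid = tr$amino_acid,
       side = side,
       fraction_of_locus_reads_on_trna = sum(r$weight) / total_w)
}

#' tRF annotation for all loci of an srna_loci object
#'
#' @param loci an `srna_loci` object.
#' @param reads the read table the loci were called from.
#' @param features a [feature_set] (its tRNA features are used).
#' @return data.frame with one row per tRF locus: `locus_id`, `trna_id`,
#'   `anticodon`, `amino_acid`, `side`, `fraction_on_trna`. Loci overlapping
#'   no tRNA are absent.
#' @export
annotate_trf_all <- function(loci, reads, features) {
  stopifnot(inherits(loci, "srna_loci"))
  trna <- features$features[features$features$kind == "tRNA", , drop = FALSE]
  hits <- overlap_pairs(loci$loci, trna)
  rows <- lapply(unique(hits$query), function(i) {
    loc <- loci$loci[i, ]
    on <- reads$chrom == loc$chrom & reads$start < loc$end & reads$end > loc$start
    ann <- annotate_trf(loc, reads[on, , drop = FALSE], trna)
    if (!is.list(ann)) return(NULL)
    data.frame(locus_id = loc$id, trna_id = ann$trna_id,
               anticodon = ann$anticodon, amino_acid = ann$amino_acid,
               side = ann$side, fraction_on_trna = ann$fraction_of_locus_reads_on_trna,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(locus_id = character(0), trna_id = character(0),
                      anticodon = character(0), amino_acid = character(0),
                      side = character(0), fraction_on_trna = numeric(0))
  }
  out
}
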