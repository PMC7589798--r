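# Synthetic-data generator. Emulates the statistical structure of a
# wounding × generation small-RNA study: 34 libraries over {1 h 2nd leaf,
# 72 h 2nd leaf, 72 h 3rd leaf} x {wounded, control} (3 + 3 each) plus 16
# offspring second-leaf samples (2 per maternal line, 4 + 4 lines); seven
# locus classes with class-specific length and expression distributions;
# wound LFCs concentrated in nd-sRNA loci at the 72 h wounded leaf; a
# planted negative parent-offspring LFC correlation; tRF loci inside tRNA
# genes with a planted 5'/3' side; DMRs whose overlap group biases the
# direction of methylation change; and DEG tables with sRNA-overlap-
# dependent DE rates.
#
# Geometry is slot-based: each locus owns a 30 kb slot; its companion gene,
# TE and (for tRF loci) tRNA are placed inside the slot so that the nearest
# gene of every locus is its own slot's gene and the planted O/N/F distance
# class is exact by construction.

SLOT <- 30000L

TRNA_CATALOGUE <- data.frame(
  amino_acid = c("Leu", "Gly", "Ala", "Gln", "Ser", "Arg",
                 "Thr", "Val", "Ile", "Pro", "Lys", "Met"),
  anticodon = c("CAA", "CCC", "GGC", "TTG", "GCT", "ACG",
                "TGT", "TAC", "GAT", "TGG", "CTT", "CAT"),
  stringsAsFactors = FALSE
)

CLASS_LABELS <- c("miRNA", "siRNA20", "siRNA21", "siRNA22", "siRNA23",
                  "siRNA24", "ndsRNA")

#' Simulation parameters
#'
#' Defaults are the study conditions: class mix, class mean lengths and
#' log10(rpm) from the reference class-summary table; planted DMR
#' up-proportions 0.659 (siRNA) / 0.418 (ndsRNA) / 0.488 (no overlap);
#' DE rates 0.132 (sRNA-overlapping genes) vs 0.084; parent-offspring LFC
#' correlation -0.2 for nd-sRNA loci; NB dispersion 0.1; maternal-line
#' random effect sd 0.2 (natural-log scale).
#'
#' @param seed integer seed; every simulator derives its streams from it.
#' @param profile "tiny" (~200 loci, small libraries; includes per-read
#'   simulation) or "paper-shaped" (full-size locus set, counts only), or
#'   NULL for the raw defaults.
#' @param ... overrides of any default listed below.
#' @return list of parameters (class `sim_params`).
#' @export
sim_params <- function(seed = 20201013L, profile = NULL, ...) {
  p <- list(
    seed = as.integer(seed),
    n_loci = 29884L,
    n_chroms = 4L,
    library_size = 5e6,
    reads_per_library = 2e4, # per-read simulation only (tiny profile)
    library_size_cv = 0.15,
    class_counts = stats::setNames(
      c(44, 10, 226, 411, 50, 25412, 3775), CLASS_LABELS),
    length_mean = stats::setNames(
      c(227, 200, 601, 501, 254, 406, 774), CLASS_LABELS),
    length_sdlog = 0.6,
    expr_log10rpm_mean = stats::setNames(
      c(1.4, 0.46, 0.78, 0.76, 0.39, 0.36, 0.66), CLASS_LABELS),
    expr_log10rpm_sd = 0.45,
    te_rate = stats::setNames(
      c(0.296, 0.667, 0.516, 0.787, 0.875, 0.90, 0.308), CLASS_LABELS),
    context_O = stats::setNames(
      c(0.093, 0.001, 0.453, 0.126, 0.125, 0.094, 0.627), CLASS_LABELS),
    context_N = stats::setNames(
      c(0.50, 0.60, 0.35, 0.55, 0.55, 0.675, 0.25), CLASS_LABELS),
    nb_dispersion = 0.1,
    maternal_sd = 0.2,
    # wound response: fraction of loci responsive at 72 h in the wounded
    # leaf, by class; magnitude and sign mix of the planted LFCs
    responsive_frac = stats::setNames(
      c(10 / 44, rep(5 / 26052, 5), 377 / 3775), CLASS_LABELS),
    lfc_mean = 1.6, lfc_sd = 0.5, up_frac = 328 / 377,
    retained_1h_frac = 53 / 377,
    parent_offspring_r = -0.2,
    offspring_lfc_sd = 0.3,
    n_trf = 34L, trf_five_prime = 23L,
    n_bg_trna = 80L,
    # DMR / DEG association structure
    n_dmrs = 3731L,
    dmr_group_prob = c(none = 0.55, siRNA = 0.30, ndsRNA = 0.15),
    dmr_up_prob = c(none = 0.488, siRNA = 0.659, ndsRNA = 0.418),
    deg_rate_overlap = 0.132, deg_rate_background = 0.084,
    deg_expr_slope = -0.7, deg_class_up = c(none = 0, siRNA = -0.7, ndsRNA = 0.7),
    gene_near_bp = 5000L
  )
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("tiny", "paper-shaped"))
    if (profile == "tiny") {
      p$n_loci <- 200L
      p$n_chroms <- 2L
      p$library_size <- 2e6
      p$n_dmrs <- 120L
      p$n_trf <- 8L
      p$trf_five_prime <- 5L
      p$n_bg_trna <- 10L
    }
    p$profile <- profile
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown simulation parameter: ", unknown[1L])
  p[names(over)] <- over
  class(p) <- "sim_params"
  p
}

#' The 34-sample study design
#'
#' 3 wounded + 3 control libraries for each parent cell (1 h 2nd leaf,
#' 72 h 2nd leaf, 72 h 3rd leaf) and 16 offspring 2nd-leaf libraries
#' (4 wounded-line + 4 control-line maternal lines, 2 sibs each).
#'
#' @param params a [sim_params] list (used for library sizes).
#' @return sample metadata data.frame (see [read_sample_meta]).
#' @export
design_meta <- function(params = sim_params()) {
  cells <- expand.grid(treatment = c("wounded", "control"),
                       cell = c("1h_second", "72h_second", "72h_third"),
                       rep = 1:3, stringsAsFactors = FALSE)
  parent <- data.frame(
    generation = "parent", treatment = cells$treatment,
    timepoint = sub("_.*", "", cells$cell),
    leaf_pair = ifelse(grepl("second", cells$cell), "second", "third"),
    maternal_line = NA_character_, stringsAsFactors = FALSE)
  off <- expand.grid(treatment = c("wounded", "control"),
                     line = 1:4, sib = 1:2, stringsAsFactors = FALSE)
  offspring <- data.frame(
    generation = "offspring", treatment = off$treatment,
    timepoint = NA_character_, leaf_pair = "second",
    maternal_line = sprintf("%s_L%d", substr(off$treatment, 1, 1), off$line),
    stringsAsFactors = FALSE)
  meta <- rbind(parent, offspring)
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  meta$library_size <- params$library_size
  meta[, c("sample_id", "generation", "treatment", "timepoint",
           "leaf_pair", "maternal_line", "library_size")]
}

#' Simulate the genome annotation and locus truth table
#'
#' Places loci in 30 kb slots across chromosomes; assigns each locus a
#' class, length and baseline expression; plants a gene (with CDS) at the
#' planted O/N/F distance, a TE overlap at the class rate, and tRNA genes
#' (with anticodon intervals from a 12-isoacceptor catalogue) around the
#' designated tRF loci, plus background tRNAs.
#'
#' @param params a [sim_params] list.
#' @return list (class `sim_annotation`) with `params`, `features` (a
#'   [feature_set]) and `loci` (truth data.frame: interval, class, stratum,
#'   planted context, TE flag, gene id, tRF flag/side/tRNA, baseline rpm).
#' @export
simulate_annotation <- function(params = sim_params()) {
  set.seed(params$seed + 1L)
  n <- params$n_loci
  pool <- rep(CLASS_LABELS, times = pmax(
    1L, round(params$class_counts / sum(params$class_counts) * n)))
  if (length(pool) < n) pool <- c(pool, rep("siRNA24", n - length(pool)))
  cls <- sample(pool)[1:n]

  # class-conditional lengths (lognormal around class means, floored)
  mlen <- params$length_mean[cls]
  len <- round(stats::rlnorm(n, log(mlen) - params$length_sdlog^2 / 2,
                             params$length_sdlog))
  len <- pmin(pmax(len, 40L), 6000L)
  log10rpm <- stats::rnorm(n, params$expr_log10rpm_mean[cls],
                           params$expr_log10rpm_sd)

  # slots round-robin over chromosomes
  slot_i <- (seq_len(n) - 1L) %/% params$n_chroms
  chrom_i <- ((seq_len(n) - 1L) %% params$n_chroms) + 1L
  chrom <- sprintf("chr%d", chrom_i)
  slot0 <- slot_i * SLOT
  ls <- slot0 + 4000L + sample.int(2000L, n, replace = TRUE)

  # tRF loci: drawn from nd-sRNA loci, re-shaped to sit inside a 75 bp tRNA
  nds_idx <- which(cls == "ndsRNA")
  n_trf <- min(params$n_trf, length(nds_idx))
  trf_idx <- sample(nds_idx, n_trf)
  trf <- logical(n); trf[trf_idx] <- TRUE
  trf_side <- rep(NA_character_, n)
  trf_side[trf_idx] <- sample(c(rep("five_prime", min(params$trf_five_prime, n_trf)),
                                rep("three_prime", max(0L, n_trf - params$trf_five_prime))))
  trna_strand <- rep(NA_character_, n)
  trna_strand[trf_idx] <- sample(c("+", "-"), n_trf, replace = TRUE)
  ls[trf_idx] <- slot0[trf_idx] + 5000L
  len[trf_idx] <- 75L
  trna_id <- rep(NA_character_, n)
  trna_id[trf_idx] <- sprintf("trna_%03d", seq_len(n_trf))
  le <- ls + len

  # planted context and companion gene
  pO <- params$context_O[cls]; pN <- params$context_N[cls]
  u <- stats::runif(n)
  context <- ifelse(u < pO, "O", ifelse(u < pO + pN, "N", "F"))
  gap <- numeric(n)
  gap[context == "N"] <- round(stats::runif(sum(context == "N"), 200, 4800))
  gap[context == "F"] <- round(stats::runif(sum(context == "F"), 5500, 9000))
  gene_len <- round(stats::runif(n, 1000, 2000))
  gs <- ifelse(context == "O", pmax(slot0 + 200L, ls - round(gene_len / 3)),
               le + gap)
  ge <- gs + gene_len
  gene_id <- sprintf("gene_%05d", seq_len(n))

  te <- stats::runif(n) < params$te_rate[cls]
  tes <- pmax(slot0 + 100L, ls - round(stats::runif(n, 10, 200)))
  tee <- le + round(stats::runif(n, 10, 200))

  loci <- data.frame(
    id = sprintf("locus_%05d", seq_len(n)),
    chrom = chrom, start = ls, end = le, length = le - ls, slot = slot0,
    class = cls, stratum = ifelse(cls == "miRNA", "miRNA",
                           ifelse(cls == "ndsRNA", "ndsRNA",
                           ifelse(cls == "siRNA24", "siRNA24", "siRNA20_23"))),
    context = context, te = te, gene_id = gene_id,
    trf = trf, trf_side = trf_side, trna_id = trna_id,
    log10rpm = log10rpm, base_rpm = 10^log10rpm,
    stringsAsFactors = FALSE)

  # feature table: genes + CDS children + TEs + tRNAs
  genes <- data.frame(chrom = chrom, start = gs, end = ge,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      kind = "gene", id = gene_id, parent = NA_character_,
                      stringsAsFactors = FALSE)
  cds <- data.frame(chrom = chrom, start = gs + 60L, end = ge - 60L,
                    strand = genes$strand, kind = "CDS",
                    id = sprintf("cds_%05d", seq_len(n)), parent = gene_id,
                    stringsAsFactors = FALSE)
  te_df <- data.frame(chrom = chrom[te], start = tes[te], end = tee[te],
                      strand = rep(".", sum(te)), kind = rep("TE", sum(te)),
                      id = sprintf("te_%05d", seq_len(sum(te))),
                      parent = rep(NA_character_, sum(te)), stringsAsFactors = FALSE)
  iso <- TRNA_CATALOGUE[sample.int(nrow(TRNA_CATALOGUE), n_trf, replace = TRUE), ]
  trna_df <- data.frame(chrom = chrom[trf_idx], start = ls[trf_idx],
                        end = ls[trf_idx] + 75L,
                        strand = trna_strand[trf_idx], kind = "tRNA",
                        id = trna_id[trf_idx], parent = NA_character_,
                        anticodon = iso$anticodon, amino_acid = iso$amino_acid,
                        ac_start = ls[trf_idx] + 33L, ac_end = ls[trf_idx] + 36L,
                        stringsAsFactors = FALSE)
  # background tRNAs in slot spacers
  nbg <- params$n_bg_trna
  bg_slot <- sample(unique(slot0), min(nbg, length(unique(slot0))))
  bg_chrom <- sprintf("chr%d", sample.int(params$n_chroms, length(bg_slot), replace = TRUE))
  bgs <- bg_slot + 26000L + sample.int(1000L, length(bg_slot), replace = TRUE)
  iso_bg <- TRNA_CATALOGUE[sample.int(nrow(TRNA_CATALOGUE), length(bg_slot),
                                      replace = TRUE), ]
  bg_df <- data.frame(chrom = bg_chrom, start = bgs, end = bgs + 75L,
                      strand = sample(c("+", "-"), length(bg_slot), replace = TRUE),
                      kind = "tRNA",
                      id = sprintf("trna_bg_%03d", seq_along(bg_slot)),
                      parent = NA_character_, anticodon = iso_bg$anticodon,
                      amino_acid = iso_bg$amino_acid,
                      ac_start = bgs + 33L, ac_end = bgs + 36L,
                      stringsAsFactors = FALSE)
  pad_cols <- function(df) {
    for (col in c("anticodon", "amino_acid")) {
      if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, nrow(df))
    }
    for (col in c("ac_start", "ac_end")) {
      if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, nrow(df))
    }
    df
  }
  feats <- rbind(pad_cols(genes), pad_cols(cds), pad_cols(te_df),
                 trna_df, bg_df)
  structure(list(params = params, features = feature_set(feats), loci = loci),
            class = "sim_annotation")
}

# planted per-contrast LFC truth, appended to the locus table
plant_lfcs <- function(sim) {
  params <- sim$params
  loci <- sim$loci
  set.seed(params$seed + 2L)
  n <- nrow(loci)
  draw_lfc <- function(m) {
    sgn <- ifelse(stats::runif(m) < params$up_frac, 1, -1)
    sgn * stats::rnorm(m, params$lfc_mean, params$lfc_sd)
  }
  resp <- stats::runif(n) < params$responsive_frac[loci$class]
  lfc72 <- numeric(n)
  lfc72[resp] <- draw_lfc(sum(resp))
  keep1h <- resp & stats::runif(n) < params$retained_1h_frac
  lfc1 <- numeric(n)
  lfc1[keep1h] <- 0.8 * lfc72[keep1h] + stats::rnorm(sum(keep1h), 0, 0.2)
  lfc3 <- numeric(n) # no planted third-leaf response
  # offspring LFC: correlated with the 72 h response within nd-sRNA loci
  lfc_off <- numeric(n)
  nds <- loci$class == "ndsRNA"
  r <- params$parent_offspring_r
  s_off <- params$offspring_lfc_sd
  x <- lfc72[nds]
  if (stats::sd(x) > 0) {
    z <- (x - mean(x)) / stats::sd(x)
    lfc_off[nds] <- r * s_off * z + sqrt(1 - r^2) * s_off * stats::rnorm(sum(nds))
  } else {
    lfc_off[nds] <- stats::rnorm(sum(nds), 0, s_off)
  }
  loci$responsive_72h <- resp
  loci$lfc_1h <- lfc1
  loci$lfc_72h2 <- lfc72
  loci$lfc_72h3 <- lfc3
  loci$lfc_offspring <- lfc_off
  sim$loci <- loci
  sim
}

#' Simulate the 34-library count matrix
#'
#' Draws NB counts (dispersion `nb_dispersion`; the limit 0 gives Poisson)
#' with mean = baseline x size factor x 2^(planted LFC x wounded), plus a
#' lognormal maternal-line random effect (sd `maternal_sd`) for offspring
#' samples. Plants the wound LFCs (concentrated in nd-sRNA loci at 72 h,
#' 1 h effects a correlated subset) and the negative parent-offspring LFC
#' correlation; the realized truth is appended to the locus table.
#'
#' @param sim a `sim_annotation` from [simulate_annotation].
#' @return the input list, extended with `meta`, `cm` (a [count_matrix])
#'   and truth columns `lfc_1h`, `lfc_72h2`, `lfc_72h3`, `lfc_offspring`,
#'   `responsive_72h` on `loci`.
#' @export
simulate_counts <- function(sim) {
  stopifnot(inherits(sim, "sim_annotation"))
  params <- sim$params
  sim <- plant_lfcs(sim)
  loci <- sim$loci
  set.seed(params$seed + 3L)
  meta <- design_meta(params)
  s <- nrow(meta)
  n <- nrow(loci)
  lib <- round(params$library_size *
                 stats::rlnorm(s, -params$library_size_cv^2 / 2, params$library_size_cv))
  meta$library_size <- lib
  sf_true <- lib / mean(lib)
  base <- loci$base_rpm * params$library_size / 1e6

  lfc_for_cell <- function(m1) {
    if (m1$generation == "offspring") return(loci$lfc_offspring)
    if (m1$timepoint == "1h") return(loci$lfc_1h)
    if (m1$leaf_pair == "third") return(loci$lfc_72h3)
    loci$lfc_72h2
  }
  line_eff <- list()
  counts <- matrix(0, n, s, dimnames = list(loci$id, meta$sample_id))
  for (j in seq_len(s)) {
    m1 <- meta[j, ]
    wounded <- m1$treatment == "wounded"
    mu <- base * sf_true[j]
    if (wounded) mu <- mu * 2^lfc_for_cell(m1)
    if (m1$generation == "offspring") {
      ln <- m1$maternal_line
      if (is.null(line_eff[[ln]])) {
        line_eff[[ln]] <- exp(stats::rnorm(n, 0, params$maternal_sd))
      }
      mu <- mu * line_eff[[ln]]
    }
    counts[, j] <- if (params$nb_dispersion <= 0) stats::rpois(n, mu)
                   else stats::rnbinom(n, size = 1 / params$nb_dispersion, mu = mu)
  }
  sim$meta <- meta
  sim$cm <- count_matrix(counts, meta = meta)
  sim
}

# class-conditional read-length sampler
sample_lengths <- function(class, m) {
  lens <- 15:35
  w <- switch(class,
    miRNA = { x <- rep(0.05 / 16, 21); names(x) <- lens
              x["21"] <- 0.80; x["20"] <- 0.075; x["22"] <- 0.075; x },
    ndsRNA = { x <- rep(0.6 / 16, 21); names(x) <- lens
               x[as.character(20:24)] <- 0.4 / 5; x },
    { sz <- as.integer(sub("siRNA", "", class))
      x <- rep(0.05 / 16, 21); names(x) <- lens
      x[as.character(20:24)] <- 0.025
      x[as.character(sz)] <- 0.85; x })
  sample(lens, m, replace = TRUE, prob = w)
}

#' Simulate per-sample read alignments (BED-ready)
#'
#' Allocates each library's reads over loci in proportion to baseline
#' abundance times the planted treatment effect, draws read lengths from
#' class-conditional distributions (siRNA classes: 0.85 of the mass at the
#' class length, 0.95 in 20-24 nt; nd-sRNA: broad 15-35 mixture with dicer
#' mass 0.4), places reads uniformly inside the locus, and places tRF-locus
#' reads strictly 5' or 3' of the tRNA anticodon according to the planted
#' side and tRNA strand. Total reads per sample equal the configured
#' library size.
#'
#' @param sim a `sim_annotation`, after [simulate_counts] when planted
#'   effects should influence allocation (otherwise effects are planted
#'   first).
#' @param library_size reads per library (default `params$reads_per_library`).
#' @return the input list extended with `reads` (data.frame of all samples'
#'   reads: chrom, start, end, strand, length, weight, sample_id).
#' @export
simulate_reads <- function(sim, library_size = NULL) {
  stopifnot(inherits(sim, "sim_annotation"))
  params <- sim$params
  if (is.null(sim$loci$lfc_72h2)) sim <- plant_lfcs(sim)
  loci <- sim$loci
  meta <- if (!is.null(sim$meta)) sim$meta else design_meta(params)
  if (is.null(library_size)) library_size <- params$reads_per_library
  set.seed(params$seed + 4L)
  n <- nrow(loci)
  trna <- sim$features$features[sim$features$features$kind == "tRNA", ]
  tr_row <- match(loci$trna_id, trna$id)

  out <- vector("list", nrow(meta))
  for (j in seq_len(nrow(meta))) {
    m1 <- meta[j, ]
    wounded <- m1$treatment == "wounded"
    w <- loci$base_rpm
    if (wounded) {
      eff <- if (m1$generation == "offspring") loci$lfc_offspring
             else if (m1$timepoint == "1h") loci$lfc_1h
             else if (m1$leaf_pair == "third") loci$lfc_72h3
             else loci$lfc_72h2
      w <- w * 2^eff
    }
    alloc <- as.vector(stats::rmultinom(1, size = library_size, prob = w))
    li <- rep.int(seq_len(n), alloc)
    m <- length(li)
    len <- integer(m)
    for (cl in unique(loci$class)) {
      ii <- which(loci$class[li] == cl)
      if (length(ii)) len[ii] <- sample_lengths(cl, length(ii))
    }
    # tRF loci: lengths 19-30, placed on the planted side of the anticodon
    is_trf <- loci$trf[li]
    len[is_trf] <- sample(19:30, sum(is_trf), replace = TRUE)
    start <- loci$start[li] +
      floor(stats::runif(m) * pmax(1, loci$length[li] - len + 1))
    if (any(is_trf)) {
      k <- which(is_trf)
      tr <- trna[tr_row[li[k]], ]
      side <- loci$trf_side[li[k]]
      # genomic region of the planted side, strand-oriented
      minus <- tr$strand == "-"
      lo <- ifelse((side == "five_prime") != minus, tr$start, tr$ac_end)
      hi <- ifelse((side == "five_prime") != minus, tr$ac_start, tr$end)
      len[k] <- pmin(len[k], hi - lo)
      start[k] <- lo + floor(stats::runif(length(k)) * (hi - lo - len[k] + 1))
    }
    out[[j]] <- data.frame(chrom = loci$chrom[li], start = start,
                           end = start + len, strand = ".",
                           length = len, weight = 1,
                           sample_id = m1$sample_id, stringsAsFactors = FALSE)
  }
  sim$reads <- do.call(rbind, out)
  sim
}

#' Simulate DMR and DEG tables with planted associations
#'
#' DMRs are assigned an overlap group (none / siRNA / ndsRNA) with the
#' configured probabilities; siRNA-group DMRs are placed overlapping a
#' 24-nt siRNA locus, ndsRNA-group DMRs overlapping an nd-sRNA locus, and
#' no-overlap DMRs in slot spacer regions; methylation direction is drawn
#' per group with the configured up-probabilities. DEG status is drawn per
#' gene with the configured rate given realized sRNA-locus proximity
#' (within `gene_near_bp`), and direction from a logistic model in
#' log(mean expression) and overlap class.
#'
#' @param sim a `sim_annotation` (after [simulate_annotation]).
#' @return the input list extended with `dmrs`, `degs` (data.frames; the
#'   DMR table carries a truth column `group`) and a completed
#'   [feature_set] in `features`.
#' @export
simulate_dmr_deg <- function(sim) {
  stopifnot(inherits(sim, "sim_annotation"))
  params <- sim$params
  loci <- sim$loci
  set.seed(params$seed + 5L)
  nd <- params$n_dmrs
  group <- sample(names(params$dmr_group_prob), nd, replace = TRUE,
                  prob = params$dmr_group_prob)
  si_pool <- which(loci$class == "siRNA24")
  if (!length(si_pool)) si_pool <- which(grepl("^siRNA", loci$class))
  nds_pool <- which(loci$class == "ndsRNA")
  width <- round(stats::runif(nd, 100, 600))
  chrom <- character(nd); start <- integer(nd)
  for (i in seq_len(nd)) {
    if (group[i] == "siRNA" && length(si_pool)) {
      k <- sample(si_pool, 1)
    } else if (group[i] == "ndsRNA" && length(nds_pool)) {
      k <- sample(nds_pool, 1)
    } else {
      group[i] <- "none"
      k <- sample.int(nrow(loci), 1)
      chrom[i] <- loci$chrom[k]
      start[i] <- loci$slot[k] + 23000L + sample.int(1500L, 1)
      next
    }
    chrom[i] <- loci$chrom[k]
    centre <- loci$start[k] + sample.int(max(1L, loci$length[k]), 1)
    start[i] <- max(0L, centre - width[i] %/% 2L)
  }
  up <- stats::runif(nd) < params$dmr_up_prob[group]
  dmrs <- data.frame(chrom = chrom, start = start, end = start + width,
                     strand = ".", direction = ifelse(up, "up", "down"),
                     context = sample(c("CG", "CHG", "CHH"), nd, replace = TRUE,
                                      prob = c(0.2, 0.2, 0.6)),
                     group = group, stringsAsFactors = FALSE)

  # DEGs: proximity of each gene to its sRNA locus decides the DE rate
  genes <- sim$features$features[sim$features$features$kind == "gene", ]
  ndist <- nearest_distance(genes, loci)
  near <- !is.na(ndist$distance) & ndist$distance <= params$gene_near_bp
  near_class <- rep("none", nrow(genes))
  near_class[near] <- ifelse(grepl("^siRNA", loci$class[ndist$nearest[near]]),
                             "siRNA", "ndsRNA")
  mean_expr <- 10^stats::rnorm(nrow(genes), 2, 0.8)
  de <- stats::runif(nrow(genes)) <
    ifelse(near, params$deg_rate_overlap, params$deg_rate_background)
  z <- scale(log(mean_expr))[, 1]
  p_up <- stats::plogis(params$deg_expr_slope * z +
                          params$deg_class_up[near_class])
  direction <- ifelse(de, ifelse(stats::runif(nrow(genes)) < p_up, "up", "down"),
                      "none")
  degs <- data.frame(gene_id = genes$id, direction = direction,
                     mean_expression = mean_expr,
                     overlap_class = near_class, stringsAsFactors = FALSE)
  sim$dmrs <- dmrs
  sim$degs <- degs
  sim$features <- feature_set(sim$features$features,
                              dmrs = dmrs[, c("chrom", "start", "end", "strand",
                                              "direction", "context")],
                              degs = degs[, c("gene_id", "direction",
                                              "mean_expression")])
  sim
}

#' Build a complete synthetic input bundle
#'
#' Runs annotation, count, DMR/DEG (and, for the tiny profile, per-read)
#' simulation, and optionally writes the bundle to disk as plain-text files
#' (GFF3, per-sample BED, TSV counts/metadata/DMRs/DEGs, truth table, YAML
#' manifest).
#'
#' @param profile "tiny" (end-to-end in seconds, includes reads) or
#'   "paper-shaped" (full-size locus set, counts only).
#' @param seed integer seed.
#' @param outdir optional output directory.
#' @param ... further [sim_params] overrides.
#' @return the simulation bundle (invisible when written to disk): list with
#'   `params`, `features`, `loci` (truth), `meta`, `cm`, `dmrs`, `degs` and
#'   (tiny) `reads`.
#' @export
make_fixture <- function(profile = c("tiny", "paper-shaped"),
                         seed = 20201013L, outdir = NULL, ...) {
  profile <- match.arg(profile)
  sim <- simulate_annotation(sim_params(seed = seed, profile = profile, ...))
  sim <- simulate_counts(sim)
  sim <- simulate_dmr_deg(sim)
  if (profile == "tiny") sim <- simulate_reads(sim)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_gff3(sim$features, file.path(outdir, "annotation.gff3"))
    write_count_table(sim$cm, file.path(outdir, "counts.tsv"))
    write_results(sim$meta, file.path(outdir, "samples.tsv"))
    write_results(sim$dmrs[, c("chrom", "start", "end", "direction", "context")],
                  file.path(outdir, "dmrs.tsv"))
    write_results(sim$degs[, c("gene_id", "direction", "mean_expression")],
                  file.path(outdir, "degs.tsv"))
    write_results(sim$loci, file.path(outdir, "truth_loci.tsv"))
    if (!is.null(sim$reads)) {
      for (sid in unique(sim$reads$sample_id)) {
        r <- sim$reads[sim$reads$sample_id == sid, ]
        bed <- data.frame(r$chrom, r$start, r$end, ".", 0, ".")
        utils::write.table(bed, file.path(outdir, sprintf("reads_%s.bed", sid)),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
    }
    manifest <- list(profile = profile, seed = seed,
                     n_loci = nrow(sim$loci), n_samples = nrow(sim$meta),
                     n_dmrs = nrow(sim$dmrs), n_genes = nrow(sim$degs))
    writeLines(yaml::as.yaml(manifest), file.path(outdir, "manifest.yaml"))
    return(invisible(sim))
  }
  sim
}
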