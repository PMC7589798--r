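# Association models linking sRNA loci and their wound plasticity to
# transgenerational DMRs and DEGs: LFC correlations, the joint parental ->
# offspring LFC regression, DMR overlap/direction models, DEG overlap and
# direction models, the LFC/expression-change factorial, tail-outlier
# enrichment and the class ANOVAs. Standard model fits go through
# stats::lm/glm/aov/chisq.test/phyper; this layer fixes the encodings
# (term coding, LR chi-squares, Type-II sums of squares) and wraps every
# result in a common `assoc_result`.

#' Construct an association-test result
#'
#' @param test_name short identifier of the test.
#' @param statistic test statistic (chi-square, F, t or r as appropriate).
#' @param df degrees of freedom (may be a vector, e.g. c(df1, df2) for F).
#' @param p p-value.
#' @param estimates named list of term -> c(effect, se) (or a data.frame of
#'   per-term results).
#' @param n number of observations used.
#' @param flag optional character note (e.g. "separation").
#' @return object of class `assoc_result`.
#' @export
assoc_result <- function(test_name, statistic, df, p, estimates = NULL,
                         n = NA_integer_, flag = NULL) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p = p, estimates = estimates, n = n, flag = flag),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.3g, n = %s%s\n",
              x$test_name, x$statistic, paste(x$df, collapse = ","),
              x$p, x$n,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  if (is.data.frame(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Pearson correlation of log fold changes between two contrasts
#'
#' @param lfc_a,lfc_b paired LFC vectors (same loci, two contrasts).
#' @return [assoc_result] with r as the estimate and the t statistic
#'   \eqn{t = r sqrt(n-2) / sqrt(1-r^2)}.
#' @export
lfc_correlation <- function(lfc_a, lfc_b) {
  ok <- is.finite(lfc_a) & is.finite(lfc_b)
  lfc_a <- lfc_a[ok]; lfc_b <- lfc_b[ok]
  n <- length(lfc_a)
  if (n < 3) stop("need at least 3 complete LFC pairs")
  ct <- stats::cor.test(lfc_a, lfc_b, method = "pearson")
  assoc_result("lfc_correlation", statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               estimates = list(r = c(effect = unname(ct$estimate), se = NA)),
               n = n)
}

#' One-sample t statistic
#'
#' Either from a raw vector (`one_sample_t(x)`) or from printed summary
#' statistics via the closed form \eqn{t = mean / (sd / sqrt(n))}.
#'
#' @param x numeric vector (raw-vector variant).
#' @param mean,sd,n summary-statistic variant (used when `x` is missing).
#' @param mu null value (default 0).
#' @return [assoc_result] with the t statistic and a two-sided p.
#' @export
one_sample_t <- function(x, mean = NULL, sd = NULL, n = NULL, mu = 0) {
  if (!missing(x)) {
    x <- x[is.finite(x)]
    mean <- base::mean(x); sd <- stats::sd(x); n <- length(x)
  }
  stopifnot(n >= 2, sd >= 0)
  t <- (mean - mu) / (sd / sqrt(n))
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  assoc_result("one_sample_t", statistic = t, df = n - 1, p = p,
               estimates = list(mean = c(effect = mean, se = sd / sqrt(n))),
               n = n)
}

#' Joint model of offspring LFC on parental 2nd- and 3rd-leaf LFCs
#'
#' Ordinary least squares `lfc_offspring ~ lfc_2nd + lfc_3rd` with per-term
#' t tests.
#'
#' @param lfc_2nd,lfc_3rd,lfc_offspring LFC vectors over a common locus set.
#' @return [assoc_result]; `estimates` is a data.frame with one row per term
#'   (estimate, se, t, p).
#' @export
offspring_lfc_model <- function(lfc_2nd, lfc_3rd, lfc_offspring) {
  d <- data.frame(off = lfc_offspring, l2 = lfc_2nd, l3 = lfc_3rd)
  d <- d[stats::complete.cases(d), ]
  fit <- stats::lm(off ~ l2 + l3, data = d)
  if (fit$rank < 3) stop("rank-deficient design: parental LFCs are collinear")
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co$term <- c("intercept", "lfc_2nd", "lfc_3rd")
  fstat <- sm$fstatistic
  assoc_result("offspring_lfc_model", statistic = unname(fstat[1]),
               df = unname(fstat[2:3]),
               p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
               estimates = co[, c("term", "estimate", "se", "t", "p")],
               n = nrow(d))
}

# per-term likelihood-ratio chi-squares by single-term deletion
drop_term_lrt <- function(fit) {
  dr <- stats::drop1(fit, test = "LRT")
  dr <- dr[-1L, , drop = FALSE] # remove <none> row
  data.frame(term = rownames(dr), df = dr$Df, lr_chisq = dr$LRT,
             p = dr[["Pr(>Chi)"]], row.names = NULL)
}

#' Logistic model of DMR overlap on locus size, gene distance and class
#'
#' Binomial GLM (logit) of whether a locus overlaps a DMR, with terms
#' log(locus length), distance class (O/N/F) and sRNA class (dicer vs
#' non-dicer), each tested by a likelihood-ratio chi-square (single-term
#' deletion). Complete separation is flagged, not silently reported.
#'
#' @param overlaps_dmr 0/1 or logical response per locus.
#' @param length locus lengths (bp).
#' @param distance_class factor O/N/F per locus.
#' @param srna_class factor, e.g. "dicer"/"nondicer" (any 2+ level coding).
#' @return [assoc_result]; `estimates` holds both the coefficient table and
#'   the per-term LR tests; `statistic`/`p` are the class-term LR chi-square
#'   and p.
#' @export
dmr_overlap_logistic <- function(overlaps_dmr, length, distance_class, srna_class) {
  d <- data.frame(y = as.integer(as.logical(overlaps_dmr)),
                  log_len = log(length),
                  dist = factor(distance_class),
                  class = factor(srna_class))
  flag <- NULL
  if (length(unique(d$y)) < 2) {
    return(assoc_result("dmr_overlap_logistic", statistic = NA_real_, df = NA,
                        p = NA_real_, n = nrow(d), flag = "degenerate: all responses identical"))
  }
  fit <- suppressWarnings(stats::glm(y ~ log_len + dist + class, data = d,
                                     family = stats::binomial()))
  mu <- stats::fitted(fit)
  if (any(mu > 1 - 1e-8) || any(mu < 1e-8) || any(abs(stats::coef(fit)) > 15,
                                                  na.rm = TRUE)) {
    flag <- "possible separation"
  }
  terms <- suppressWarnings(drop_term_lrt(fit))
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "z", "p")
  co$term <- rownames(co)
  cls <- terms[terms$term == "class", ]
  assoc_result("dmr_overlap_logistic", statistic = cls$lr_chisq, df = cls$df,
               p = cls$p,
               estimates = list(coefficients = co[, c("term", "estimate", "se", "z", "p")],
                                terms = terms),
               n = nrow(d), flag = flag)
}

#' Chi-square test of DMR methylation direction by sRNA-overlap group
#'
#' Contingency chi-square (no continuity correction) of direction (up/down)
#' against overlap group (none / siRNA / ndsRNA), with per-group
#' up-proportions.
#'
#' @param direction factor/character of DMR methylation direction (up/down).
#' @param overlap_group factor/character grouping of each DMR.
#' @return [assoc_result]; `estimates$up_proportion` is the named per-group
#'   proportion up-methylated.
#' @export
direction_chisq <- function(direction, overlap_group) {
  tab <- table(factor(overlap_group), factor(direction, levels = c("up", "down")))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  up <- tab[, "up"] / rowSums(tab)
  assoc_result("direction_chisq", statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               estimates = list(up_proportion = up, table = tab),
               n = sum(tab))
}

#' Linear model of sRNA LFC on nearest-DMR methylation direction
#'
#' For loci within `window` of a DMR: `lfc ~ direction` (direction of the
#' nearest DMR), F-tested.
#'
#' @param lfc per-locus LFC.
#' @param direction per-locus direction of the nearest DMR within the
#'   window (up/down); NA excludes the locus (no DMR within the window).
#' @return [assoc_result] with the F statistic and the estimated mean shift
#'   (up minus down).
#' @export
lfc_vs_direction_glm <- function(lfc, direction) {
  d <- data.frame(lfc = lfc, dir = factor(direction, levels = c("down", "up")))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$dir)) < 2) {
    return(assoc_result("lfc_vs_direction", statistic = NA_real_, df = NA,
                        p = NA_real_, n = nrow(d),
                        flag = "degenerate: single direction level"))
  }
  fit <- stats::lm(lfc ~ dir, data = d)
  an <- stats::anova(fit)
  shift <- stats::coef(fit)[["dirup"]]
  se <- summary(fit)$coefficients["dirup", 2]
  assoc_result("lfc_vs_direction", statistic = an$`F value`[1],
               df = an$Df, p = an$`Pr(>F)`[1],
               estimates = list(shift_up_minus_down = c(effect = shift, se = se)),
               n = nrow(d))
}

#' 2x2 association of differential expression with sRNA-locus overlap
#'
#' Chi-square (no continuity correction) of gene DE status against
#' sRNA-locus overlap status, with the per-group DE proportions and the
#' odds ratio ad/bc.
#'
#' @param de logical per gene: differentially expressed.
#' @param overlaps logical per gene: overlaps (within 5 kb of) an sRNA locus.
#' @return [assoc_result].
#' @export
deg_overlap_rate <- function(de, overlaps) {
  de <- as.logical(de); overlaps <- as.logical(overlaps)
  tab <- table(factor(overlaps, levels = c(FALSE, TRUE)),
               factor(de, levels = c(FALSE, TRUE)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  prop <- tab[, "TRUE"] / rowSums(tab)
  names(prop) <- c("no_overlap", "overlap")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  assoc_result("deg_overlap_rate", statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               estimates = list(de_rate = prop, odds_ratio = or, table = tab),
               n = sum(tab))
}

#' Logistic model of DEG direction on expression and sRNA overlap class
#'
#' Binomial GLM of direction (up vs down; non-DE genes are excluded) on
#' log(mean expression) and sRNA-overlap class (none / siRNA / ndsRNA);
#' per-term likelihood-ratio chi-squares.
#'
#' @param direction per-gene direction (up/down; others dropped).
#' @param mean_expression per-gene control mean expression (> 0).
#' @param overlap_class per-gene factor none/siRNA/ndsRNA.
#' @return [assoc_result]; `estimates$terms` carries the per-term LR tests.
#' @export
direction_by_class_expression_model <- function(direction, mean_expression,
                                                overlap_class) {
  keep <- direction %in% c("up", "down")
  d <- data.frame(y = as.integer(direction[keep] == "up"),
                  log_expr = log(mean_expression[keep]),
                  class = factor(overlap_class[keep]))
  d <- d[is.finite(d$log_expr), ]
  if (nlevels(droplevels(d$class)) < 2) {
    warning("single overlap class: class term dropped")
    fit <- stats::glm(y ~ log_expr, data = d, family = stats::binomial())
  } else {
    fit <- stats::glm(y ~ log_expr + class, data = d, family = stats::binomial())
  }
  terms <- drop_term_lrt(fit)
  expr_row <- terms[terms$term == "log_expr", ]
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "z", "p")
  co$term <- rownames(co)
  assoc_result("direction_by_class_expression",
               statistic = expr_row$lr_chisq, df = expr_row$df, p = expr_row$p,
               estimates = list(coefficients = co[, c("term", "estimate", "se", "z", "p")],
                                terms = terms),
               n = nrow(d))
}

#' Factorial model of sRNA LFC on mRNA transgenerational change and type
#'
#' OLS of sRNA LFC on mRNA transgenerational expression change (up/none/
#' down), sRNA locus type (siRNA/ndsRNA) and their interaction, with partial
#' (Type-II) sums of squares per term (sequential Type-I available via
#' `ss_type = "I"`). Fitted separately by the caller for overlapping and
#' near (<5 kb, non-overlapping) locus sets and per contrast.
#'
#' @param lfc per-pair sRNA LFC (response).
#' @param tgen_change factor up/none/down (mRNA change in progeny of wounded
#'   plants).
#' @param srna_type factor siRNA/ndsRNA.
#' @param ss_type "II" (default) or "I".
#' @return [assoc_result]; `estimates$terms` has SS, df, F, p per term, plus
#'   the full-model F.
#' @export
table2_model <- function(lfc, tgen_change, srna_type, ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  d <- data.frame(lfc = lfc,
                  tgen = factor(tgen_change, levels = c("none", "down", "up")),
                  type = factor(srna_type))
  d <- d[stats::complete.cases(d), ]
  d$tgen <- droplevels(d$tgen)
  fit <- stats::lm(lfc ~ tgen * type, data = d)
  if (ss_type == "II") {
    an <- car::Anova(fit, type = "II")
    terms <- data.frame(term = rownames(an), ss = an$`Sum Sq`, df = an$Df,
                        F = an$`F value`, p = an$`Pr(>F)`, row.names = NULL)
  } else {
    an <- stats::anova(fit)
    terms <- data.frame(term = rownames(an), ss = an$`Sum Sq`, df = an$Df,
                        F = an$`F value`, p = an$`Pr(>F)`, row.names = NULL)
  }
  terms <- terms[terms$term != "Residuals", ]
  sm <- summary(fit)
  fstat <- sm$fstatistic
  ix <- grepl(":", terms$term)
  assoc_result("table2_model",
               statistic = unname(fstat[1]), df = unname(fstat[2:3]),
               p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
               estimates = list(terms = terms,
                                interaction_F = terms$F[ix],
                                interaction_p = terms$p[ix]),
               n = nrow(d))
}

#' Hypergeometric enrichment of an annotation in an LFC tail
#'
#' Tests whether membership in an annotation category is over-represented
#' among loci in the chosen LFC tail (upper or lower `tail_q` quantile) with
#' a hypergeometric upper-tail test.
#'
#' @param lfc per-locus LFC.
#' @param member logical per locus: annotation-category membership.
#' @param tail_q tail fraction (default 0.05).
#' @param side "upper" or "lower" LFC tail.
#' @return [assoc_result]; `estimates` records tail size, draws and overlap.
#' @export
outlier_enrichment <- function(lfc, member, tail_q = 0.05,
                               side = c("upper", "lower")) {
  side <- match.arg(side)
  ok <- is.finite(lfc)
  lfc <- lfc[ok]; member <- as.logical(member[ok])
  n <- length(lfc)
  k <- max(1L, floor(tail_q * n))
  ord <- order(lfc, decreasing = (side == "upper"))
  tail_idx <- ord[seq_len(k)]
  x <- sum(member[tail_idx])
  K <- sum(member)
  p <- stats::phyper(x - 1, K, n - K, k, lower.tail = FALSE)
  assoc_result("outlier_enrichment", statistic = x, df = NA, p = p,
               estimates = list(tail_size = k, n_member = K, overlap = x,
                                expected = k * K / n, side = side),
               n = n)
}

#' One-way ANOVA of a per-locus (or per-gene) quantity across classes
#'
#' @param values numeric response (e.g. log10 rpm, locus length, expression,
#'   methylation level).
#' @param labels class labels (must have >= 2 levels).
#' @return [assoc_result] with F, (df1, df2) and p.
#' @export
class_anova <- function(values, labels) {
  d <- data.frame(y = values, g = factor(labels))
  d <- d[stats::complete.cases(d), ]
  d$g <- droplevels(d$g)
  if (nlevels(d$g) < 2) stop("ANOVA needs >= 2 classes (df = 0 otherwise)")
  an <- stats::anova(stats::aov(y ~ g, data = d))
  assoc_result("class_anova", statistic = an$`F value`[1], df = an$Df,
               p = an$`Pr(>F)`[1],
               estimates = list(group_means = tapply(d$y, d$g, mean)),
               n = nrow(d))
}

#' Direction of the nearest DMR within a window, per locus
#'
#' Helper for the LFC-vs-methylation-direction model: finds for each locus
#' the nearest DMR and returns its direction when the edge-to-edge distance
#' is within `window` (default 20 kb), NA otherwise.
#'
#' @param loci data.frame of locus intervals.
#' @param dmrs DMR table (chrom/start/end/direction).
#' @param window maximum distance in bp (default 20000).
#' @return character vector (up/down/NA) per locus.
#' @export
nearest_dmr_direction <- function(loci, dmrs, window = 20000L) {
  nd <- nearest_distance(loci, dmrs)
  dir <- rep(NA_character_, nrow(loci))
  ok <- !is.na(nd$distance) & nd$distance <= window
  dir[ok] <- dmrs$direction[nd$nearest[ok]]
  dir
}
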