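test_that("LFC correlation matches the closed-form t transform", {
  x <- c(1, 2, 3, 4, 5)
  r1 <- lfc_correlation(x, x * 2 + 1)
  expect_equal(unname(r1$estimates$r["effect"]), 1)

  set.seed(4)
  a <- rnorm(315); b <- 0.23 * a + rnorm(315)
  res <- lfc_correlation(a, b)
  r <- res$estimates$r[["effect"]]
  n <- res$n
  expect_equal(res$statistic, r * sqrt(n - 2) / sqrt(1 - r^2), tolerance = 1e-10)
  expect_equal(res$df, n - 2)
  # at the printed precision: r = 0.23, n = 315 gives t = 4.18
  expect_equal(round(0.23 * sqrt(313) / sqrt(1 - 0.23^2), 2), 4.18)
})

test_that("the one-sample t reproduces the closed form from summaries", {
  expect_equal(one_sample_t(mean = 0, sd = 2, n = 50)$statistic, 0)
  expect_equal(one_sample_t(mean = 1, sd = 1, n = 100)$statistic, 10)
  t_trf <- one_sample_t(mean = -0.32, sd = 0.41, n = 315)$statistic
  expect_equal(round(t_trf, 2), -13.85)
  set.seed(1)
  x <- rnorm(40, 0.5)
  expect_equal(one_sample_t(x)$statistic,
               unname(t.test(x)$statistic))
})

test_that("the joint offspring model recovers planted parental coefficients", {
  set.seed(6)
  l2 <- rnorm(315); l3 <- rnorm(315)
  off <- -0.5 * l2 + 0.3 * l3 + rnorm(315, 0, 0.1)
  m <- offspring_lfc_model(l2, l3, off)
  est <- m$estimates
  expect_true(abs(est$estimate[est$term == "lfc_2nd"] + 0.5) < 0.05)
  expect_true(abs(est$estimate[est$term == "lfc_3rd"] - 0.3) < 0.05)
  expect_error(offspring_lfc_model(l2, 2 * l2, off), "collinear")
})

test_that("the DMR overlap logistic model recovers a planted class effect", {
  set.seed(8)
  n <- 5000
  cls <- sample(c("dicer", "nondicer"), n, replace = TRUE)
  len <- exp(rnorm(n, 6, 0.5))
  dist <- sample(c("O", "N", "F"), n, replace = TRUE)
  eta <- -2.5 + 1.2 * (cls == "nondicer") + 0.3 * scale(log(len))[, 1]
  y <- rbinom(n, 1, plogis(eta))
  res <- dmr_overlap_logistic(y, len, dist, cls)
  co <- res$estimates$coefficients
  b <- co$estimate[grepl("^class", co$term)]
  expect_true(abs(b - 1.2) < 0.2)
  expect_true(res$p < 1e-6)
  expect_equal(sort(res$estimates$terms$term), sort(c("log_len", "dist", "class")))

  # all loci overlapping: degenerate, flagged rather than tested
  resdeg <- dmr_overlap_logistic(rep(1, 100), len[1:100], dist[1:100], cls[1:100])
  expect_match(resdeg$flag, "degenerate")
})

test_that("the direction chi-square equals the hand formula and flags balance", {
  bal <- direction_chisq(rep(c("up", "down"), each = 150),
                         rep(c("none", "siRNA", "ndsRNA"), 100))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)

  dirs <- c(rep("up", 488), rep("down", 512), rep("up", 418), rep("down", 582),
            rep("up", 659), rep("down", 341))
  grp <- rep(c("none", "ndsRNA", "siRNA"), each = 1000)
  res <- direction_chisq(dirs, grp)
  # hand computation of sum (O-E)^2 / E
  O <- rbind(c(488, 512), c(418, 582), c(659, 341))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E))
  expect_equal(unname(res$estimates$up_proportion[c("none", "ndsRNA", "siRNA")]),
               c(0.488, 0.418, 0.659))
})

test_that("chi-square p matches a permutation null on a small table", {
  set.seed(15)
  dirs <- c(rep("up", 30), rep("down", 20), rep("up", 12), rep("down", 38))
  grp <- rep(c("a", "b"), each = 50)
  res <- direction_chisq(dirs, grp)
  B <- 10000
  stat0 <- replicate(B, direction_chisq(sample(dirs), grp)$statistic)
  p_perm <- (1 + sum(stat0 >= res$statistic - 1e-12)) / (B + 1)
  expect_true(abs(res$p - p_perm) < 3 * sqrt(p_perm * (1 - p_perm) / B) + 0.005)
})

test_that("LFC vs methylation direction recovers a planted mean shift", {
  set.seed(16)
  dir <- sample(c("up", "down"), 600, replace = TRUE)
  lfc <- 0.4 * (dir == "up") + rnorm(600, 0, 0.5)
  res <- lfc_vs_direction_glm(lfc, dir)
  expect_true(abs(res$estimates$shift_up_minus_down[["effect"]] - 0.4) < 0.1)
  expect_true(res$p < 0.001)
  single <- lfc_vs_direction_glm(lfc, rep("up", 600))
  expect_match(single$flag, "single direction")
})

test_that("the DEG 2x2 reports exact odds ratio and planted rates", {
  set.seed(17)
  n <- 10000
  ov <- runif(n) < 0.4
  de <- runif(n) < ifelse(ov, 0.132, 0.084)
  res <- deg_overlap_rate(de, ov)
  expect_true(abs(res$estimates$de_rate[["overlap"]] - 0.132) < 0.01)
  expect_true(abs(res$estimates$de_rate[["no_overlap"]] - 0.084) < 0.01)
  tab <- res$estimates$table
  expect_equal(res$estimates$odds_ratio,
               (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
})

test_that("the DEG direction model recovers a planted expression slope", {
  set.seed(18)
  n <- 2000
  expr <- exp(rnorm(n, 3, 1))
  cls <- sample(c("none", "siRNA", "ndsRNA"), n, replace = TRUE)
  pup <- plogis(3 - 1.0 * log(expr))
  dir <- ifelse(runif(n) < pup, "up", "down")
  res <- direction_by_class_expression_model(dir, expr, cls)
  co <- res$estimates$coefficients
  expect_true(abs(co$estimate[co$term == "log_expr"] + 1.0) < 0.15)
  expect_warning(direction_by_class_expression_model(dir, expr, rep("none", n)),
                 "single overlap class")
})

test_that("the factorial LFC model has df (2,1,2) and detects interactions", {
  set.seed(20)
  n <- 7000
  tgen <- sample(c("up", "none", "down"), n, replace = TRUE)
  type <- sample(c("siRNA", "ndsRNA"), n, replace = TRUE)
  eff <- ifelse(type == "ndsRNA" & tgen == "down", 0.4,
                ifelse(type == "ndsRNA" & tgen == "up", -0.4, 0))
  lfc <- eff + rnorm(n, 0, 1)
  res <- table2_model(lfc, tgen, type)
  terms <- res$estimates$terms
  expect_equal(terms$df[match(c("tgen", "type", "tgen:type"), terms$term)],
               c(2, 1, 2))
  expect_true(res$estimates$interaction_p < 0.001)
  # Type-I (sequential) SS is available and agrees on a balanced design
  res1 <- table2_model(lfc, tgen, type, ss_type = "I")
  expect_equal(res1$estimates$terms$df, terms$df[match(res1$estimates$terms$term, terms$term)])
})

test_that("hypergeometric tail enrichment equals exhaustive enumeration", {
  set.seed(21)
  # perfectly tail-concentrated membership attains the minimal p
  lfc <- seq_len(40)
  member <- lfc > 38
  res <- outlier_enrichment(lfc, member, tail_q = 0.05, side = "upper")
  expect_equal(res$p, 1 / choose(40, 2), tolerance = 1e-12)

  # exhaustive enumeration over all tail subsets, n <= 30
  for (rep in 1:5) {
    n <- sample(10:18, 1)
    k <- sample(2:4, 1)
    member <- runif(n) < 0.3
    lfc <- rnorm(n)
    res <- outlier_enrichment(lfc, member, tail_q = k / n, side = "upper")
    x <- res$estimates$overlap
    sets <- utils::combn(n, k)
    cnt <- sum(apply(sets, 2, function(s) sum(member[s]) >= x))
    expect_equal(res$p, cnt / ncol(sets), tolerance = 1e-10)
  }
})

test_that("the class ANOVA matches the hand formula and flags single groups", {
  y <- c(1, 2, 3, 4, 5, 6, 8, 9, 10)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- class_anova(y, g)
  gm <- tapply(y, g, mean); n_g <- 3
  ssb <- sum(n_g * (gm - mean(y))^2)
  ssw <- sum((y - rep(gm, each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic, f_hand)
  expect_equal(res$df, c(2, 6))

  set.seed(22)
  y2 <- c(rnorm(50), rnorm(50), rnorm(50, 3))
  res2 <- class_anova(y2, rep(c("a", "b", "c"), each = 50))
  expect_true(res2$p < 0.001)
  expect_error(class_anova(rnorm(10), rep("a", 10)), "2 classes")
})

test_that("nearest DMR direction honours the 20 kb window", {
  loci <- data.frame(chrom = "c1", start = c(0, 50000, 100000),
                     end = c(100, 50100, 100100))
  dmrs <- data.frame(chrom = "c1", start = c(5000, 76000), end = c(5200, 76200),
                     direction = c("up", "down"))
  d <- nearest_dmr_direction(loci, dmrs, window = 20000)
  expect_equal(d, c("up", NA, NA))
  # exclusion count equals the brute-force recount
  bf <- bf_nearest(loci, dmrs)
  expect_equal(sum(is.na(d)), sum(bf$distance > 20000))
})
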