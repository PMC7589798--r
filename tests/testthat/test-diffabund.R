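test_that("size factors respect scaling symmetry and match DESeq2's estimator", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3,
              dimnames = list(paste0("l", 1:3), c("a", "b")))
  sf <- size_factors(m)
  expect_equal(unname(sf[1] / sf[2]), 1)

  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  rownames(m2) <- paste0("l", 1:3)
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[2] / sf2[1]), 2)

  skip_if_not_installed("DESeq2")
  set.seed(5)
  nb <- matrix(rnbinom(500 * 6, size = 5,
                       mu = outer(runif(500, 20, 200), c(1, 1.3, 0.7, 1, 1.1, 0.9))),
               500, 6, dimnames = list(paste0("L", 1:500), paste0("s", 1:6)))
  got <- size_factors(nb)
  want <- DESeq2::estimateSizeFactorsForMatrix(nb)
  expect_true(all(abs(got / want - 1) < 0.05))
})

test_that("the mean-RPM filter keeps the inclusive boundary and drops zero loci", {
  m <- rbind(keep = c(15, 15, 5, 5), zero = c(0, 0, 0, 0), high = rep(100, 4))
  colnames(m) <- paste0("s", 1:4)
  cm <- count_matrix(m, library_sizes = stats::setNames(rep(5e6, 4), paste0("s", 1:4)))
  # keep: rpm = (3,3,1,1), mean exactly 2
  expect_equal(unname(mean_rpm(cm)["keep"]), 2)
  f <- filter_rpm(cm, min_rpm = 2)
  expect_identical(rownames(f$counts), c("keep", "high"))
})

test_that("BH adjustment matches the textbook step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(42)
  for (rep in 1:200) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bf_bh(p))
  }
})

test_that("identical counts across treatments give lfc 0 and p 1", {
  meta <- parent_meta_3v3()
  Y <- matrix(rep(10, 6), 1, dimnames = list("a", meta$sample_id))
  r <- nb_lrt(Y, meta, sf = rep(1, 6), dispersion = 0.1)
  expect_equal(r$lfc, 0)
  expect_equal(r$stat, 0)
  expect_equal(r$p, 1)
})

test_that("planted log2 fold changes are recovered without material bias", {
  set.seed(7)
  meta <- parent_meta_3v3()
  n <- 500
  mu0 <- exp(runif(n, log(5), log(500)))
  mu <- outer(mu0, c(1, 1, 1, 4, 4, 4)) # lfc = 2 for wounded samples
  Y <- matrix(rnbinom(n * 6, size = 10, mu = mu), n, 6,
              dimnames = list(paste0("L", 1:n), meta$sample_id))
  r <- nb_lrt(Y, meta, sf = rep(1, 6))
  expect_true(abs(mean(r$lfc) - 2) < 0.15)
  expect_true(all(r$stat >= 0))
  expect_true(all(r$p > 0 & r$p <= 1, na.rm = TRUE))
})

test_that("dispersion estimates recover a constant simulated dispersion", {
  set.seed(11)
  meta <- parent_meta_3v3()
  n <- 3000
  mu0 <- exp(runif(n, log(20), log(500)))
  Y <- matrix(rnbinom(n * 6, size = 1 / 0.2, mu = rep(mu0, 6)), n, 6)
  a <- estimate_dispersions(Y, rep(1, 6), meta$treatment)
  expect_true(abs(mean(a) - 0.2) < 0.05)
})

test_that("the nested maternal-line design estimates the treatment effect", {
  set.seed(19)
  meta <- design_meta()[19:34, ] # offspring block
  n <- 400
  mu0 <- exp(runif(n, log(20), log(300)))
  lines <- unique(meta$maternal_line)
  le <- matrix(rnorm(n * length(lines), 0, 0.25), n, length(lines),
               dimnames = list(NULL, lines))
  mu <- sapply(seq_len(nrow(meta)), function(j) {
    mu0 * 2^(1.5 * (meta$treatment[j] == "wounded")) * exp(le[, meta$maternal_line[j]])
  })
  Y <- matrix(rnbinom(n * 16, size = 10, mu = mu), n, 16,
              dimnames = list(paste0("L", 1:n), meta$sample_id))
  r <- nb_lrt(Y, meta, nested_maternal = TRUE, sf = rep(1, 16))
  expect_true(abs(mean(r$lfc) - 1.5) < 0.15)
  # the full design carries intercept + treatment + 6 line contrasts
  expect_equal(ncol(srnaplast:::build_design(meta, TRUE)$full), 8)
  expect_equal(unique(r$df), 1)
})

test_that("contrasts select the right samples and q is monotone in p within strata", {
  sim <- make_fixture("tiny", seed = 23)
  classes <- data.frame(locus_id = sim$loci$id, label = sim$loci$class,
                        stratum = sim$loci$stratum)
  res <- run_contrasts(sim$cm, classes)
  expect_setequal(names(res),
                  c("parent_1h_leaf2", "parent_72h_leaf2", "parent_72h_leaf3",
                    "offspring_leaf2"))
  for (nm in names(res)) {
    r <- res[[nm]]
    for (st in unique(r$stratum)) {
      rs <- r[r$stratum == st & !is.na(r$p), ]
      o <- order(rs$p)
      expect_true(all(diff(rs$q[o]) >= -1e-12))
      expect_true(all(rs$q >= rs$p - 1e-12))
    }
  }
  # planted 72 h responders are found, and only in the right contrast direction
  r72 <- res$parent_72h_leaf2
  resp <- sim$loci$id[sim$loci$responsive_72h]
  if (length(intersect(resp, r72$locus_id)) >= 2) {
    truth <- stats::setNames(sim$loci$lfc_72h2, sim$loci$id)
    est <- stats::setNames(r72$lfc, r72$locus_id)
    common <- intersect(resp, r72$locus_id)
    expect_true(cor(truth[common], est[common]) > 0.8)
  }
})
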