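test_that("the generator is deterministic given the seed", {
  a <- make_fixture("tiny", seed = 31)
  b <- make_fixture("tiny", seed = 31)
  expect_identical(a$loci, b$loci)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$dmrs, b$dmrs)
  expect_identical(a$reads, b$reads)
  c2 <- make_fixture("tiny", seed = 32)
  expect_false(identical(a$cm$counts, c2$cm$counts))
})

test_that("fixture files are byte-identical across reruns", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixture("tiny", seed = 33, outdir = d1, n_loci = 60L,
               reads_per_library = 3000)
  make_fixture("tiny", seed = 33, outdir = d2, n_loci = 60L,
               reads_per_library = 3000)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("24-nt siRNA loci overlap TEs at the configured rate", {
  sim <- simulate_annotation(sim_params(seed = 35, n_loci = 5000L))
  si24 <- sim$loci[sim$loci$class == "siRNA24", ]
  te <- sim$features$features[sim$features$features$kind == "TE", ]
  ov <- srnaplast:::overlap_pairs(si24, te)
  frac <- length(unique(ov$query)) / nrow(si24)
  expect_true(abs(frac - 0.90) < 0.03)
})

test_that("a zero TE rate produces no TE overlaps", {
  p <- sim_params(seed = 36, profile = "tiny",
                  te_rate = stats::setNames(rep(0, 7), srnaplast:::CLASS_LABELS))
  sim <- simulate_annotation(p)
  te <- sim$features$features[sim$features$features$kind == "TE", ]
  expect_equal(nrow(te), 0)
})

test_that("the planted parent-offspring LFC correlation is realized", {
  p <- sim_params(seed = 37, n_loci = 2100L,
                  class_counts = stats::setNames(c(1, 1, 1, 1, 1, 95, 2000),
                                                 srnaplast:::CLASS_LABELS))
  sim <- srnaplast:::plant_lfcs(simulate_annotation(p))
  nds <- sim$loci$class == "ndsRNA"
  expect_true(sum(nds) >= 1900)
  r <- cor(sim$loci$lfc_72h2[nds], sim$loci$lfc_offspring[nds])
  expect_true(abs(r - (-0.2)) < 0.05)
})

test_that("zero dispersion gives Poisson-like variance", {
  p <- sim_params(seed = 38, profile = "tiny", n_loci = 1000L,
                  nb_dispersion = 0, library_size_cv = 0, maternal_sd = 0,
                  responsive_frac = stats::setNames(rep(0, 7), srnaplast:::CLASS_LABELS),
                  parent_offspring_r = 0, offspring_lfc_sd = 0)
  sim <- simulate_counts(simulate_annotation(p))
  Y <- sim$cm$counts # all samples share mu per locus (no effects, no sf noise)
  m <- rowMeans(Y); v <- apply(Y, 1, var)
  ok <- m > 1
  expect_true(abs(mean(v[ok] / m[ok]) - 1) < 0.1)
})

test_that("simulated read totals match the configured library size", {
  sim <- make_fixture("tiny", seed = 39, n_loci = 80L, reads_per_library = 5000)
  tab <- table(sim$reads$sample_id)
  expect_true(all(tab == 5000))
  expect_true(all(sim$reads$length >= 15 & sim$reads$length <= 35))
})

test_that("classification round-trips on simulated reads with zero errors", {
  sim <- make_fixture("tiny", seed = 40)
  called <- call_loci(sim$reads, sample_ids = sim$meta$sample_id)
  # map called loci to planted loci by overlap
  ov <- srnaplast:::overlap_pairs(called$loci, sim$loci)
  truth_of <- rep(NA_integer_, nrow(called$loci))
  truth_of[ov$query] <- ov$subject
  expect_true(!anyNA(truth_of))
  mirna_ids <- called$loci$id[sim$loci$class[truth_of] == "miRNA"]
  cl <- classify_loci(called, mirna_flags = mirna_ids)
  expect_identical(cl$stratum, sim$loci$stratum[truth_of])
  expect_identical(cl$label, sim$loci$class[truth_of])
})

test_that("planted tRF sides are recovered with zero errors", {
  sim <- make_fixture("tiny", seed = 41)
  called <- call_loci(sim$reads, sample_ids = sim$meta$sample_id)
  trf <- annotate_trf_all(called, sim$reads, sim$features)
  truth <- sim$loci[sim$loci$trf, ]
  expect_equal(nrow(trf), nrow(truth))
  # match on tRNA id
  m <- match(trf$trna_id, truth$trna_id)
  expect_true(!anyNA(m))
  expect_identical(trf$side, truth$trf_side[m])
})

test_that("DMR intervals lie inside simulated chromosomes and groups are planted", {
  sim <- simulate_dmr_deg(simulate_annotation(sim_params(seed = 42, profile = "tiny")))
  expect_true(all(sim$dmrs$start >= 0))
  expect_true(all(sim$dmrs$end > sim$dmrs$start))
  # realized overlap group equals the planted group
  grp <- rep("none", nrow(sim$dmrs))
  ov <- srnaplast:::overlap_pairs(sim$dmrs, sim$loci)
  lab <- sim$loci$class[ov$subject]
  grp[unique(ov$query[grepl("^siRNA", lab)])] <- "siRNA"
  nd <- setdiff(unique(ov$query[lab == "ndsRNA"]), which(grp == "siRNA"))
  grp[nd] <- "ndsRNA"
  expect_identical(grp, sim$dmrs$group)
})

test_that("truth tables cover the planted quantities", {
  sim <- make_fixture("tiny", seed = 43)
  expect_true(all(c("class", "stratum", "context", "te", "trf", "trf_side",
                    "log10rpm", "lfc_1h", "lfc_72h2", "lfc_72h3",
                    "lfc_offspring", "responsive_72h") %in% names(sim$loci)))
  expect_true(all(c("group", "direction") %in% names(sim$dmrs)))
  expect_true(all(c("direction", "mean_expression", "overlap_class") %in%
                    names(sim$degs)))
})
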