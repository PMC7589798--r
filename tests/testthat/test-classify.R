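prof <- function(...) {
  x <- stats::setNames(rep(0, 21), 15:35)
  v <- c(...)
  x[names(v)] <- v
  x
}

test_that("the 80% dicer rule, tie-break and miRNA precedence apply", {
  r <- classify_locus(prof("24" = 90, "30" = 10))
  expect_equal(r$label, "siRNA24")
  expect_equal(r$dicer_fraction, 0.9)
  expect_equal(r$stratum, "siRNA24")

  r2 <- classify_locus(prof("21" = 40, "30" = 60))
  expect_equal(r2$label, "ndsRNA")
  expect_equal(r2$dicer_fraction, 0.4)

  # modal-size tie broken toward the longer length
  r3 <- classify_locus(prof("21" = 50, "22" = 50))
  expect_equal(r3$label, "siRNA22")

  # boundary exactly 0.8 is classified siRNA
  r4 <- classify_locus(prof("23" = 80, "30" = 20))
  expect_equal(r4$label, "siRNA23")

  # upstream miRNA flag takes precedence over any profile
  r5 <- classify_locus(prof("30" = 100), mirna_flag = TRUE)
  expect_equal(r5$label, "miRNA")

  expect_error(classify_locus(prof()), "zero")
})

test_that("vectorised classification agrees with the scalar rule and partitions loci", {
  set.seed(12)
  profs <- matrix(rpois(50 * 21, 3), 50, 21, dimnames = list(NULL, 15:35))
  profs <- profs + 1 # no zero totals
  flags <- seq_len(50) %in% sample.int(50, 5)
  tab <- classify_loci(profs, mirna_flags = flags)
  expect_equal(nrow(tab), 50)
  for (i in seq_len(50)) {
    one <- classify_locus(profs[i, ], mirna_flag = flags[i])
    expect_equal(tab$label[i], one$label)
    expect_equal(tab$dicer_fraction[i], one$dicer_fraction)
  }
  # labels partition the locus set
  expect_true(all(table(tab$label) >= 0))
  expect_equal(sum(table(tab$label)), 50)
})

test_that("context annotation assigns O/N/F by edge-to-edge gene distance", {
  feats <- feature_set(data.frame(
    chrom = "c1",
    start = c(150, 4000, 10000, 160, 500),
    end = c(400, 5000, 11000, 390, 650),
    strand = "+", kind = c("gene", "gene", "gene", "CDS", "TE"),
    id = c("gA", "gB", "gC", "cdsA", "teA"),
    parent = c(NA, NA, NA, "gA", NA)))
  loci <- data.frame(id = c("L1", "L2", "L3"), chrom = "c1",
                     start = c(100, 600, 20000), end = c(200, 700, 20100))
  ctx <- annotate_context(loci, feats)
  expect_equal(ctx$distance_class, c("O", "N", "F"))
  expect_equal(ctx$nearest_gene_distance, c(0, 200, 9000))
  expect_equal(ctx$nearest_gene_id[1:2], c("gA", "gA"))
  expect_true(ctx$overlaps_cds[1])
  expect_true(ctx$overlaps_te[2])
  expect_false(any(ctx$overlaps_te[c(1, 3)]))
})

test_that("context annotation agrees with a brute-force nearest scan", {
  set.seed(33)
  genes <- random_intervals(120)
  genes$kind <- "gene"; genes$id <- sprintf("g%d", seq_len(nrow(genes)))
  genes$strand <- "+"
  fs <- feature_set(genes)
  loci <- random_intervals(150)
  loci$id <- sprintf("L%d", seq_len(nrow(loci)))
  ctx <- annotate_context(loci, fs)
  want <- bf_nearest(loci, genes)
  expect_equal(ctx$nearest_gene_distance, want$distance)
  cls <- ifelse(want$distance == 0, "O", ifelse(want$distance <= 5000, "N", "F"))
  cls[is.na(want$distance)] <- "F"
  expect_equal(ctx$distance_class, cls)
})

trna_plus <- data.frame(chrom = "c1", start = 1000, end = 1075, strand = "+",
                        kind = "tRNA", id = "t1", parent = NA,
                        anticodon = "CAA", amino_acid = "Leu",
                        ac_start = 1033, ac_end = 1036)

trf_read <- function(start, end, w = 1) {
  data.frame(chrom = "c1", start = start, end = end, strand = ".",
             length = end - start, weight = w, sample_id = "s1")
}

test_that("tRF side-calling is anticodon- and strand-aware", {
  loc <- data.frame(chrom = "c1", start = 1000, end = 1075)
  expect_equal(annotate_trf(loc, trf_read(1000, 1025), trna_plus)$side, "five_prime")
  expect_equal(annotate_trf(loc, trf_read(1040, 1070), trna_plus)$side, "three_prime")
  expect_equal(annotate_trf(loc, trf_read(1030, 1050), trna_plus)$side, "anticodon_spanning")

  # minus strand: the genomic end of the tRNA is its 5' end
  trna_minus <- trna_plus; trna_minus$strand <- "-"
  expect_equal(annotate_trf(loc, trf_read(1040, 1070), trna_minus)$side, "five_prime")
  expect_equal(annotate_trf(loc, trf_read(1000, 1025), trna_minus)$side, "three_prime")

  # majority vote over read weight; ties go to anticodon_spanning
  rr <- rbind(trf_read(1000, 1025, 2), trf_read(1040, 1070, 1))
  expect_equal(annotate_trf(loc, rr, trna_plus)$side, "five_prime")
  rr2 <- rbind(trf_read(1000, 1025, 1), trf_read(1040, 1070, 1))
  expect_equal(annotate_trf(loc, rr2, trna_plus)$side, "anticodon_spanning")

  # no overlapping tRNA is NA, not an error
  far <- data.frame(chrom = "c1", start = 5000, end = 5100)
  expect_true(is.na(suppressWarnings(annotate_trf(far, trf_read(5000, 5025), trna_plus)))[1])
})
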