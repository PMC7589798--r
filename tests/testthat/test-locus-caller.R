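read_row <- function(chrom, start, end, sample = "sA", w = 1) {
  data.frame(chrom = chrom, start = start, end = end, strand = ".",
             length = end - start, weight = w, sample_id = sample,
             stringsAsFactors = FALSE)
}

test_that("reads merge into one locus iff the gap is at most pad", {
  r <- rbind(read_row("c1", 100, 121), read_row("c1", 150, 171))
  one <- call_loci(r, pad = 75, min_reads = 1)
  expect_equal(nrow(one$loci), 1)
  expect_equal(one$loci$start, 100)
  expect_equal(one$loci$end, 171)

  r2 <- rbind(read_row("c1", 100, 121), read_row("c1", 300, 321))
  two <- call_loci(r2, pad = 75, min_reads = 1)
  expect_equal(nrow(two$loci), 2)

  # boundary: gap exactly pad merges, pad+1 does not
  r3 <- rbind(read_row("c1", 100, 121), read_row("c1", 196, 217)) # gap 75
  expect_equal(nrow(call_loci(r3, pad = 75, min_reads = 1)$loci), 1)
  r4 <- rbind(read_row("c1", 100, 121), read_row("c1", 197, 218)) # gap 76
  expect_equal(nrow(call_loci(r4, pad = 75, min_reads = 1)$loci), 2)
})

test_that("random read sets reproduce the union-find brute-force loci", {
  set.seed(77)
  for (rep in 1:3) {
    r <- random_reads(200)
    got <- call_loci(r, pad = 75, min_reads = 5)
    want <- bf_call_loci(r, pad = 75, min_reads = 5)
    expect_equal(nrow(got$loci), nrow(want))
    expect_equal(got$loci$start, want$start)
    expect_equal(got$loci$end, want$end)
    expect_equal(got$loci$n_reads, want$weight)
  }
})

test_that("locus calling is invariant to read order and conserves weight", {
  set.seed(88)
  r <- random_reads(300)
  a <- call_loci(r, pad = 50, min_reads = 1)
  b <- call_loci(r[sample.int(nrow(r)), ], pad = 50, min_reads = 1)
  expect_identical(a$loci, b$loci)
  expect_identical(a$counts, b$counts)
  # with min_reads = 1 every read is retained
  expect_equal(sum(a$profiles), sum(r$weight))
  expect_equal(sum(a$counts), sum(r$weight))
  # loci are pairwise separated by more than pad
  gaps <- a$loci$start[-1] - a$loci$end[-nrow(a$loci)]
  expect_true(all(gaps[a$loci$chrom[-1] == a$loci$chrom[-nrow(a$loci)]] > 50))
})

test_that("profiles sum member read weights by length", {
  r <- rbind(read_row("c1", 100, 121), read_row("c1", 110, 131),
             read_row("c1", 120, 141), read_row("c1", 130, 154))
  loc <- call_loci(r, pad = 75, min_reads = 1)
  expect_equal(unname(loc$profiles[1, c("21", "24")]), c(3, 1))
  expect_equal(sum(loc$profiles), 4)

  p <- profile_locus(list(chrom = "c1", start = 100, end = 200),
                     rbind(read_row("c1", 100, 122, w = 0.5),
                           read_row("c1", 120, 142, w = 0.5)))
  expect_equal(unname(p["22"]), 1.0)
  expect_equal(attr(p, "total"), 1.0)
})

test_that("rpm is counts per million mapped reads", {
  expect_equal(rpm(10, 5e6), 2.0)
  expect_equal(rpm(0, 5e6), 0.0)
  m <- matrix(c(10, 0, 20, 5), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(rpm(m, c(5e6, 1e6))["a", ], c(s1 = 2, s2 = 20))
  # hand check of the log10 mean-rpm summary on 3 loci
  cm <- count_matrix(m, library_sizes = c(s1 = 5e6, s2 = 1e6))
  expect_equal(unname(mean_rpm(cm)), c((2 + 20) / 2, (0 + 5) / 2))
})
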