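test_that("region counts weight bins by overlap fraction", {
  bm <- toy_bins(matrix(c(10, 20, 30), ncol = 1), width = 1000)
  one_bin <- intervals("chrT", 1000, 2000)
  expect_equal(unname(region_counts(bm, one_bin)[1, 1]), 20)
  half_bin <- intervals("chrT", 0, 500)
  expect_equal(unname(region_counts(bm, half_bin)[1, 1]), 5)
  spanning <- intervals("chrT", 500, 1500)
  expect_equal(unname(region_counts(bm, spanning)[1, 1]), 5 + 10)
  expect_error(region_counts(bm, intervals("chrX", 0, 10)),
               class = "spikeshift_lookup_error")
})

test_that("a genome tiling conserves total signal", {
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rpois(40, 50), 20, 2, dimnames = list(NULL, c("a", "b")))
    bm <- toy_bins(m, width = 1000)
    cuts <- sort(sample(seq(500, 19500, 500), 6))
    tiling <- intervals("chrT", c(0, cuts), c(cuts, 20000))
    rc <- region_counts(bm, tiling)
    expect_equal(colSums(rc), colSums(m), tolerance = 1e-10)
  }
})

test_that("normalization modes rescale region counts as documented", {
  m <- matrix(c(100, 300, 50, 150), 2, 2, dimnames = list(NULL, c("a", "b")))
  bm <- toy_bins(m, width = 1000)
  whole <- intervals("chrT", 0, 2000)
  nf <- data.frame(sample = c("a", "b"), nf = c(2, 4))
  rc <- region_counts(bm, whole, normalization = "spike_nf", factors = nf)
  expect_equal(unname(rc[1, ]), c(400 * 2, 200 * 4))
  rl <- region_counts(bm, whole, normalization = "library_size")
  expect_equal(unname(rl[1, ]), c(400 / (400 / 1e6), 200 / (200 / 1e6)))
  # input division and replicate averaging
  inp <- toy_bins(matrix(c(10, 10, 30, 10), 2, 2,
                         dimnames = list(NULL, c("a", "b"))), width = 1000)
  ri <- region_counts(bm, whole, input = inp)
  expect_equal(unname(ri[1, ]), c(400, 200) / 30)
  ravg <- region_counts(bm, whole, average_replicates = TRUE,
                        replicate_groups = c(a = "g", b = "g"))
  expect_equal(unname(ravg[1, 1]), 300)
})

test_that("promoter windows follow strand-aware slop with clamping", {
  g <- genome_index(c(chr1 = 1e6))
  plus <- promoter_windows(intervals("chr1", 50000, 50001, strand = "+"),
                           10000, 1000, g)
  expect_equal(c(plus$start, plus$end), c(40000, 51001))
  # exact mirror of the plus-strand window (bedtools slop -s semantics):
  # downstream reaches 1000 bases left of the TSS base, upstream 10000 right
  minus <- promoter_windows(intervals("chr1", 50000, 50001, strand = "-"),
                            10000, 1000, g)
  expect_equal(c(minus$start, minus$end), c(49000, 60001))
  expect_equal(minus$end - minus$start, plus$end - plus$start)
  clamped <- promoter_windows(intervals("chr1", 5000, 5001, strand = "+"),
                              10000, 1000, g)
  expect_equal(clamped$start, 0)
  near_end <- promoter_windows(intervals("chr1", 999900, 999901,
                                         strand = "-"),
                               10000, 1000, g)
  expect_equal(near_end$end, 1e6)
  expect_error(promoter_windows(intervals("chrZ", 0, 1, strand = "+"),
                                10, 10, g),
               class = "spikeshift_lookup_error")
})

test_that("bivalent peak selection deduplicates and matches brute force", {
  g <- genome_index(c(chr1 = 1e6))
  # one peak overlapping two bivalent windows is reported once
  tss <- intervals("chr1", c(10000, 10400), c(10001, 10401),
                   strand = c("+", "+"))
  peaks <- intervals("chr1", c(9500, 500000), c(10500, 500100))
  hit <- bivalent_peak_set(tss, peaks, g)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 9500)
  # no overlaps -> empty
  far <- intervals("chr1", 800000, 800001, strand = "+")
  expect_equal(nrow(bivalent_peak_set(far, peaks, g)), 0)
  # O(n^2) oracle on random fixtures
  set.seed(13)
  for (i in 1:5) {
    pos <- sample(1e5, 30) + 2000
    tss <- intervals("chr1", pos, pos + 1,
                     strand = sample(c("+", "-"), 30, replace = TRUE))
    pk_start <- sort(sample(seq(0, 2e5, 3000), 20))
    peaks <- intervals("chr1", pk_start, pk_start + 2500)
    win <- promoter_windows(tss, 1000, 100, g)
    brute <- vapply(seq_len(nrow(peaks)), function(pk) {
      any(peaks$start[pk] < win$end & win$start < peaks$end[pk])
    }, logical(1))
    got <- bivalent_peak_set(tss, peaks, g)
    expect_equal(nrow(got), sum(brute))
  }
})

test_that("repeat classification applies the stated thresholds", {
  out <- classify_repeat_elements(high = c(6, 2, 6, 10, 4),
                                  ctrl = c(2, 6, 5, 0, 1))
  expect_equal(attr(out, "n_excluded"), 1)        # ctrl = 0 dropped
  expect_equal(out$class, c("hyper", "hypo", "neither", "neither"))
  # partition: every surviving element has exactly one class
  set.seed(41)
  high <- runif(200, 0, 20); ctrl <- runif(200, 0.1, 20)
  calls <- classify_repeat_elements(high, ctrl)
  expect_equal(nrow(calls), 200)
  expect_true(all(calls$class %in% c("hyper", "hypo", "neither")))
  hyper <- calls$log2_ratio > 0.7 & calls$high_signal > 5
  hypo <- calls$log2_ratio < -0.7 & calls$high_signal < 3
  expect_equal(calls$class == "hyper", hyper)
  expect_equal(calls$class == "hypo", hypo)
})

test_that("aggregate_signal_matrix reproduces flat and mirrored profiles", {
  g <- genome_index(c(chrT = 100000))
  bm <- bin_matrix(bin_genome(g, 1000),
                   matrix(7, 100, 1, dimnames = list(NULL, "s1")))
  regions <- intervals("chrT", c(30000, 60000), c(40000, 70000))
  agg <- aggregate_signal_matrix(bm, regions, mode = "reference_point",
                                 flank = 5000)
  expect_equal(unname(agg$profile), rep(7, 10))
  one <- aggregate_signal_matrix(bm, regions[1, ], mode = "scale_regions",
                                 flank = 3000, body_bins = 10)
  expect_equal(unname(one$profile), unname(one$matrix[1, ]))
  # strand symmetry: anchored at the centre, a minus-strand region reads
  # the same positions in reverse
  ramp <- bin_matrix(bin_genome(g, 1000),
                     matrix(seq_len(100), 100, 1,
                            dimnames = list(NULL, "s1")))
  fwd <- intervals("chrT", 50000, 52000, strand = "+")
  rev_ <- intervals("chrT", 50000, 52000, strand = "-")
  a_fwd <- aggregate_signal_matrix(ramp, fwd, flank = 2000,
                                   anchor = "center")
  a_rev <- aggregate_signal_matrix(ramp, rev_, flank = 2000,
                                   anchor = "center")
  expect_equal(unname(a_rev$matrix[1, ]), rev(unname(a_fwd$matrix[1, ])))
  # mirrored signal: a minus-strand region on the mirrored genome gives
  # the plus-strand profile of the original
  mirr <- bin_matrix(bin_genome(g, 1000),
                     matrix(rev(seq_len(100)), 100, 1,
                            dimnames = list(NULL, "s1")))
  m_rev <- intervals("chrT", 1e5 - 52000, 1e5 - 50000, strand = "-")
  b_rev <- aggregate_signal_matrix(mirr, m_rev, flank = 2000,
                                   anchor = "center")
  expect_equal(unname(b_rev$matrix[1, ]), unname(a_fwd$matrix[1, ]))
  # off-chromosome flank positions are missing, or zero on request
  edge <- intervals("chrT", 500, 1500)
  miss <- aggregate_signal_matrix(bm, edge, flank = 3000)
  expect_true(anyNA(miss$matrix))
  zeroed <- aggregate_signal_matrix(bm, edge, flank = 3000,
                                    missing_as_zero = TRUE)
  expect_false(anyNA(zeroed$matrix))
})
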