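test_that("pentamer classification is Hamming distance from TTCCA", {
  expect_equal(classify_pentamer("TTCCA")$distance, 0)
  expect_equal(classify_pentamer("GTCCA")$distance, 1)
  expect_equal(classify_pentamer("AGGTC")$distance, 5)
  expect_equal(classify_pentamer("ttcga")$distance, 1)  # case-folded

  expect_error(classify_pentamer("TTCC"), "exactly 5")
  expect_error(classify_pentamer("TTCCAA"), "exactly 5")
  expect_error(classify_pentamer("TTCCN"), "unambiguous")

  # exactly 15 distinct motifs at distance 1 (3 alternatives x 5 positions)
  all5 <- do.call(paste0, expand.grid(rep(list(c("A","C","G","T")), 5)))
  d <- hamming5(all5)
  expect_equal(sum(d == 1), 15)
  expect_equal(sum(d == 0), 1)
})

test_that("fixed-frame segmentation tiles from position 1 with a residue tail", {
  rec <- seq_record("a", strrep("TTCCA", 10))
  seg <- segment_array(rec, segmentation_params("fixed"))
  expect_equal(sum(seg$type == "pentamer"), 10)
  expect_true(all(seg$distance[seg$type == "pentamer"] == 0))
  expect_equal(sum(seg$type == "residue"), 0)

  rec2 <- seq_record("b", "TTCCATTCCATT")
  seg2 <- segment_array(rec2, segmentation_params("fixed"))
  expect_equal(sum(seg2$type == "pentamer"), 2)
  resid <- seg2[seg2$type == "residue", ]
  expect_equal(resid$end - resid$start + 1, 2L)
})

test_that("dynamic segmentation matches an exhaustive tiling oracle", {
  # spot example first
  rec2 <- seq_record("b", "TTCCATTCCATT")
  seg2 <- segment_array(rec2, segmentation_params("dynamic"))
  expect_equal(sum(seg2$type == "pentamer"), 2)
  expect_equal(attr(seg2, "cost"), 2 * 3)   # two skipped bases

  set.seed(101)
  for (i in 1:40) {
    L <- sample(5:30, 1)
    x <- random_dna(L)
    seg <- segment_array(seq_record("x", x), segmentation_params("dynamic"))
    expect_equal(attr(seg, "cost"), oracle_segmentation_cost(x),
                 info = paste("sequence:", x))
  }
})

test_that("segmentation cost and length bookkeeping are consistent", {
  set.seed(77)
  for (i in 1:20) {
    L <- sample(5:400, 1)
    rec <- seq_record("x", random_dna(L))
    dyn <- segment_array(rec, segmentation_params("dynamic"))
    fix <- segment_array(rec, segmentation_params("fixed"))
    # dynamic never costs more than fixed-frame
    expect_lte(attr(dyn, "cost"), attr(fix, "cost"))
    # segments cover the sequence without overlap
    for (seg in list(dyn, fix)) {
      seg <- seg[order(seg$start), ]
      expect_equal(seg$start[1], 1L)
      expect_equal(seg$end[nrow(seg)], L)
      if (nrow(seg) > 1)
        expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1L))
    }
  }
})

test_that("spectra conserve length and recover generator truth", {
  # 5 * sum(counts) + residue == total length, any input
  set.seed(303)
  for (i in 1:15) {
    rec <- seq_record("x", random_dna(sample(5:300, 1)))
    for (mode in c("dynamic", "fixed")) {
      sp <- pentamer_spectrum(rec, segmentation_params(mode))
      expect_equal(5 * sum(sp$motif_counts) + sp$residue_bases,
                   sp$total_length)
      expect_equal(unname(sp$by_distance),
                   vapply(0:5, function(d) sum(
                     sp$motif_counts[hamming5(names(sp$motif_counts)) == d]),
                     integer(1)))
    }
  }
  # exact spectrum recovery on indel-free synthetic arrays, several seeds
  for (seed in c(1, 17, 2024)) {
    g <- generate_array(array_spec(seed = seed))
    sp <- pentamer_spectrum(g$record)
    expect_identical(sp$motif_counts, g$truth$motif_counts)
    expect_identical(sp$by_distance, g$truth$by_distance)
    expect_equal(sp$residue_bases, 0L)
  }
  # simple exact case
  sp3 <- pentamer_spectrum(seq_record("t", strrep("TTCCA", 3)))
  expect_equal(sp3$motif_counts, c(TTCCA = 3L))
})

test_that("spectrum comparison is antisymmetric over the motif union", {
  a <- pentamer_spectrum(generate_array(array_spec(seed = 4))$record)
  b <- pentamer_spectrum(generate_array(array_spec(seed = 5))$record)
  ab <- compare_spectra(a, b)
  ba <- compare_spectra(b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_setequal(ab$motif, union(names(a$motif_counts),
                                  names(b$motif_counts)))
  self <- compare_spectra(a, a)
  expect_true(all(self$delta == 0))

  mismatched <- pentamer_spectrum(
    generate_array(array_spec(seed = 5))$record,
    segmentation_params(skip_penalty = 4))
  expect_error(compare_spectra(a, mismatched), "different segmentation")
})

test_that("published derivative table is internally consistent", {
  tab <- dyz1_pentamer_counts()
  ones <- tab[tab$kind == "motif" & tab$distance == 1, ]
  expect_equal(nrow(ones), 15)                    # all 1-bp derivatives
  expect_equal(hamming5(ones$row), rep(1, 15))    # each really distance 1
  agg1 <- tab[tab$row == "1_bp_derivatives", ]
  for (col in c("AC068123.5", "DU145", "LNCaP"))
    expect_equal(sum(ones[[col]]), agg1[[col]])
  # reference vs DU145 TTCCA delta as printed: 229 -> 235
  ttcca <- tab[tab$row == "TTCCA", ]
  expect_equal(ttcca$DU145 - ttcca[["AC068123.5"]], 6)
})
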