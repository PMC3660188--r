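test_that("IUPAC patterns compile to exact concrete-sequence matchers", {
  m <- compile_iupac("CCWGG")
  expect_equal(m("ACCAGGT"), 2L)
  expect_equal(m("CCTGG"), 1L)
  expect_length(m("CCGGG"), 0)
  expect_equal(compile_iupac("GATNNNNATC")("GATACGTATC"), 1L)
  expect_equal(compile_iupac("ACGT")("ACGT"), 1L)
  expect_length(compile_iupac("ACGT")("ACGA"), 0)
  expect_error(compile_iupac("ACXGT"), "illegal")
  expect_error(compile_iupac(""), "illegal")
})

test_that("site finding handles palindromes, strands and overlaps", {
  ecorI <- enzyme_spec("EcoRI", "GAATTC", "5p", 1, 5)
  hits <- find_sites(seq_record("s", "AAGAATTCAA"), ecorI)
  expect_equal(nrow(hits), 1)           # palindrome counted once
  expect_equal(hits$position, 3L)
  expect_equal(hits$strand, "forward")

  fokI <- enzyme_spec("FokI", "GGATG", "5p", 14, 18)
  rev <- find_sites(seq_record("s", "TTTCATCCTTT"), fokI)
  expect_equal(nrow(rev), 1)
  expect_equal(rev$strand, "reverse")
  expect_equal(rev$position, 4L)        # CATCC starts at 4

  aa <- enzyme_spec("AAx", "AA", "blunt")
  expect_equal(nrow(find_sites(seq_record("s", "AAAA"), aa)), 3)
})

test_that("site counts equal a naive position-by-position oracle", {
  panel <- list(enzyme_spec("EcoRII", "CCWGG", "5p"),
                enzyme_spec("BsaBI", "GATNNNNATC", "blunt"),
                enzyme_spec("FokI", "GGATG", "5p"),
                enzyme_spec("XhoII", "RGATCY", "5p"),
                enzyme_spec("MaeII", "ACGT", "5p"),
                enzyme_spec("SduI", "GDGCHC", "3p"))
  set.seed(404)
  for (i in 1:12) {
    s <- random_dna(200)
    rec <- seq_record("r", s)
    for (e in panel) {
      expect_equal(nrow(find_sites(rec, e)),
                   naive_site_count(e$recognition, s),
                   info = paste(e$name, "on", substr(s, 1, 20)))
    }
  }
})

test_that("frequency tables keep zeros and reject duplicate enzymes", {
  panel <- list(enzyme_spec("EcoRI", "GAATTC", "5p"),
                enzyme_spec("ClaI", "ATCGAT", "5p"))
  freq <- site_frequency_table(seq_record("s", "TTTTTTTTTT"), panel)
  expect_equal(unname(freq), c(0L, 0L))
  expect_named(freq, c("EcoRI", "ClaI"))
  dup <- c(panel, list(enzyme_spec("EcoRI", "GAATTC", "5p")))
  expect_error(site_frequency_table(seq_record("s", "AC"), dup),
               "duplicate")
  expect_error(site_frequency_table(seq_record("s", "AC"), list()),
               "empty")
})

test_that("lost/gained comparison follows presence transitions only", {
  expect_length(compare_frequencies(c(E = 1L), c(E = 1L))$lost, 0)
  cmp <- compare_frequencies(c(E = 1L, F = 2L), c(E = 0L, F = 5L))
  expect_equal(cmp$lost, "E")
  expect_length(cmp$gained, 0)
  expect_equal(cmp$changed$enzyme, "F")   # count change, not loss
  x <- c(A = 3L, B = 0L)
  self <- compare_frequencies(x, x)
  expect_length(self$lost, 0); expect_length(self$gained, 0)
  expect_equal(nrow(self$changed), 0)
  expect_error(compare_frequencies(c(A = 1L), c(B = 1L)), "same enzyme")
})

test_that("published DYZ1 frequency columns give the reported loss/gain sets", {
  freq <- dyz1_site_frequencies()
  ref <- stats::setNames(freq[["AC068123.5"]], freq$name)
  du <- compare_frequencies(ref, stats::setNames(freq$DU145, freq$name))
  expect_setequal(du$lost, c("BsaBI", "NlaIV", "BamHI", "EcoRII",
                             "XhoII", "CspCI"))
  expect_equal(du$gained, "Eco57I")
  ln <- compare_frequencies(ref, stats::setNames(freq$LNCaP, freq$name))
  expect_setequal(ln$lost, c("BsaBI", "NlaIV", "BamHI", "EcoRII",
                             "XhoII", "CspCI", "MaeII", "MaeIII"))
  expect_equal(ln$gained, "Eco57I")
  # Eco57MI changes count (1 -> 2) but is neither lost nor gained
  expect_true("Eco57MI" %in% du$changed$enzyme)
})

test_that("virtual digestion conserves length and honours cut offsets", {
  fspI <- enzyme_spec("FspI", "TGCGCA", "blunt", 3, 3)
  set.seed(21)
  bg <- random_dna_without(709, "TGCGCA")
  amp <- seq_record("dazI_synthetic", implant(bg, "TGCGCA", 396))
  expect_equal(nrow(find_sites(amp, fspI)), 1)   # construction check
  r <- predict_rflp(amp, fspI)
  expect_equal(r$allele, "cut")
  expect_equal(as.integer(r$fragments), c(398L, 311L))

  # no sites -> one full-length fragment, uncut call
  mboI <- enzyme_spec("MboI", "GATC", "5p", 0, 4)
  set.seed(22)
  uncut <- seq_record("dazII_synthetic", random_dna_without(182, "GATC"))
  r2 <- predict_rflp(uncut, mboI)
  expect_equal(r2$allele, "uncut")
  expect_equal(as.integer(r2$fragments), 182L)

  # three-fragment DraI pattern
  draI <- enzyme_spec("DraI", "TTTAAA", "blunt", 3, 3)
  set.seed(23)
  bg3 <- random_dna_without(244, "TTTAAA")
  amp3 <- seq_record("dazV_synthetic",
                     implant(implant(bg3, "TTTAAA", 120), "TTTAAA", 193))
  expect_equal(nrow(find_sites(amp3, draI)), 2)
  expect_equal(as.integer(predict_rflp(amp3, draI)$fragments),
               c(122L, 73L, 49L))

  # conservation across a panel on random sequences
  panel <- dyz1_enzyme_panel()
  with_cuts <- Filter(function(e) !is.na(e$cut_top), panel)
  set.seed(24)
  for (i in 1:5) {
    rec <- seq_record("r", random_dna(600))
    for (e in with_cuts[seq(1, length(with_cuts), by = 7)])
      expect_equal(sum(digest_fragments(rec, e)), 600)
  }
})

test_that("type IIS cuts beyond the sequence count as sites, not boundaries", {
  eco57I <- enzyme_spec("Eco57I", "CTGAAG", "3p", 22, 20)
  set.seed(31)
  bg <- random_dna_without(60, "CTGAAG")
  rec <- seq_record("r", implant(bg, "CTGAAG", 50))  # cut at 50+21 > 60
  expect_equal(nrow(find_sites(rec, eco57I)), 1)
  expect_equal(as.integer(digest_fragments(rec, eco57I)), 60L)

  nooff <- enzyme_spec("ArsI", "GACNNNNNNTTYG", "3p")
  expect_error(digest_fragments(rec, nooff), "unsupported")
})

test_that("the bundled digest panel loads with Table-consistent metadata", {
  panel <- dyz1_enzyme_panel()
  expect_length(panel, 65)
  expect_equal(panel$BsaBI$site_length, 6)   # N runs are uninformative
  expect_equal(panel$EcoRII$site_length, 5)
  expect_equal(panel$CspCI$site_length, 7)
  expect_equal(panel$Eco57I$recognition, "CTGAAG")
  freq <- dyz1_site_frequencies()
  expect_setequal(freq$name, names(panel))
})
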