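# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (and Biostrings) so they can serve as
# ground truth for the optimized implementations.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# rejection-sample a sequence containing none of `forbidden` (plain
# substring check on both the string and naive reverse complement)
random_dna_without <- function(n, forbidden) {
  naive_rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
  }
  repeat {
    s <- random_dna(n)
    hit <- any(vapply(forbidden, function(p)
      grepl(p, s, fixed = TRUE) || grepl(naive_rc(p), s, fixed = TRUE),
      logical(1)))
    if (!hit) return(s)
  }
}

# implant `site` into `background` so that it occupies positions
# start..start+nchar(site)-1
implant <- function(background, site, start) {
  paste0(substr(background, 1, start - 1), site,
         substr(background, start + nchar(site), nchar(background)))
}

# --- segmentation cost oracle -----------------------------------------
# exhaustively enumerate every pentamer/skip tiling (no memoization)
oracle_segmentation_cost <- function(x, skip_penalty = 3, ref = "TTCCA") {
  L <- nchar(x)
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  dist_at <- function(i) {
    m <- strsplit(substr(x, i, i + 4), "", fixed = TRUE)[[1]]
    sum(m != refc)
  }
  rec <- function(i) {
    if (i > L) return(0)
    best <- skip_penalty + rec(i + 1)
    if (i + 4 <= L) best <- min(best, dist_at(i) + rec(i + 5))
    best
  }
  rec(1)
}

# --- global alignment score oracle ------------------------------------
# enumerate every global alignment path; affine gap run of length k costs
# gap_open + gap_extend * k
oracle_alignment_score <- function(a, b, match = 1, mismatch = -1,
                                   gap_open = 5, gap_extend = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(ca); lb <- length(cb)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > la && j > lb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= la && j <= lb)
      rec(i + 1, j + 1, "m",
          sc + if (ca[i] == cb[j]) match else mismatch)
    if (i <= la)  # gap in b (consume a)
      rec(i + 1, j, "ga",
          sc - gap_extend - if (prev == "ga") 0 else gap_open)
    if (j <= lb)  # gap in a (consume b)
      rec(i, j + 1, "gb",
          sc - gap_extend - if (prev == "gb") 0 else gap_open)
  }
  rec(1, 1, "none", 0)
  best
}

# --- naive IUPAC site scanner oracle ----------------------------------
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

naive_iupac_positions <- function(pattern, subject) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sc <- strsplit(subject, "", fixed = TRUE)[[1]]
  np <- length(pc); ns <- length(sc)
  if (ns < np) return(integer(0))
  hits <- integer(0)
  for (i in 1:(ns - np + 1)) {
    ok <- TRUE
    for (k in seq_len(np)) {
      if (!sc[i + k - 1] %in% IUPAC_SETS[[pc[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

naive_iupac_rc <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(pattern, "", fixed = TRUE)[[1]]]), collapse = "")
}

# site count with the package's strand policy, independently implemented
naive_site_count <- function(pattern, subject) {
  n <- length(naive_iupac_positions(pattern, subject))
  if (naive_iupac_rc(pattern) != pattern)
    n <- n + length(naive_iupac_positions(naive_iupac_rc(pattern), subject))
  n
}
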