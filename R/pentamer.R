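#' Pentamer classification and satellite-array spectra
#'
#' The DYZ1 HaeIII repeat unit (~3.56 kb) is built largely of the
#' pentanucleotide "TTCCA" and mutated derivatives of it. A derivative class
#' is the Hamming distance (0-5) of a 5-base motif from the reference
#' pentamer; there are exactly 15 distinct 1-base derivatives (3 alternative
#' bases at each of 5 positions).
#'
#' @param motif A 5-base unambiguous DNA string.
#' @param ref The reference pentamer (default `"TTCCA"`).
#' @return `classify_pentamer` returns a list of class `pentamer_class` with
#'   fields `motif` and `distance`.
#' @examples
#' classify_pentamer("GTCCA")$distance  # 1
#' @export
classify_pentamer <- function(motif, ref = "TTCCA") {
  motif <- toupper(motif)
  if (nchar(motif) != 5L)
    stop("motif must be exactly 5 bases, got '", motif, "'")
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("A", "C", "G", "T")))
    stop("motif must be unambiguous DNA (A/C/G/T): '", motif, "'")
  structure(list(motif = motif,
                 distance = hamming5(motif, ref)),
            class = "pentamer_class")
}

# Hamming distance between two 5-mers (vectorized over `motif`).
hamming5 <- function(motif, ref = "TTCCA") {
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- matrix(unlist(strsplit(motif, "", fixed = TRUE)),
              nrow = length(motif), byrow = TRUE)
  rowSums(m != matrix(rc, nrow = length(motif), ncol = 5L, byrow = TRUE))
}

#' Segmentation parameters for array decomposition
#'
#' Controls how an array is tiled into pentamers. `"fixed"` tiles in frame
#' from position 1, leaving a trailing residue of `length %% 5` bases.
#' `"dynamic"` minimizes the total cost (sum of pentamer Hamming distances
#' plus `skip_penalty` per unassigned base) over all tilings by dynamic
#' programming, which lets the frame re-anchor after indels.
#'
#' @param mode `"dynamic"` (default) or `"fixed"`.
#' @param skip_penalty Cost per unassigned (skipped) base; must be > 0.
#'   The default 3 means a pentamer of distance <= 2 is always preferred to
#'   skipping.
#' @param max_unit_cost Maximum pentamer distance accepted before skipping
#'   is preferred outright (default 5, i.e. any pentamer is a candidate).
#' @param ref Reference pentamer.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(mode = c("dynamic", "fixed"),
                                skip_penalty = 3,
                                max_unit_cost = 5,
                                ref = "TTCCA") {
  mode <- match.arg(mode)
  if (!is.numeric(skip_penalty) || skip_penalty <= 0)
    stop("'skip_penalty' must be > 0")
  if (!is.numeric(max_unit_cost) || max_unit_cost < 0 || max_unit_cost > 5)
    stop("'max_unit_cost' must be in 0..5")
  if (nchar(ref) != 5L) stop("'ref' must be a pentamer")
  structure(list(mode = mode, skip_penalty = skip_penalty,
                 max_unit_cost = max_unit_cost, ref = toupper(ref)),
            class = "segmentation_params")
}

#' Segment a satellite array into pentamers and residue bases
#'
#' Tiles the sequence with non-overlapping pentamers plus unassigned
#' (residue) bases according to `params`. In dynamic mode ties in cost are
#' broken so that the first differing decision assigns a pentamer rather
#' than a skip (leftmost-pentamer preference).
#'
#' @param record A [seq_record] with unambiguous residues, length >= 5.
#' @param params A [segmentation_params] object.
#' @return A data frame with columns `start`, `end`, `type`
#'   (`"pentamer"`/`"residue"`), `motif` (NA for residue runs) and
#'   `distance`; attribute `cost` holds the total segmentation cost and
#'   attribute `params` the parameters used.
#' @export
segment_array <- function(record, params = segmentation_params()) {
  stopifnot(inherits(record, "seq_record"))
  x <- record$residues
  L <- nchar(x)
  if (L < 5L) stop("sequence shorter than one pentamer")
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("A", "C", "G", "T")))
    stop("ambiguity codes are not allowed inside satellite arrays")
  refc <- strsplit(params$ref, "", fixed = TRUE)[[1]]

  # distance of the pentamer starting at each position
  nk <- L - 4L
  d <- integer(nk)
  for (k in 0:4) d <- d + (ch[(1:nk) + k] != refc[k + 1L])

  if (params$mode == "fixed") {
    n <- L %/% 5L
    starts <- seq.int(1L, by = 5L, length.out = n)
    assign <- rep("pentamer", n)
    resid_len <- L %% 5L
    seg <- data.frame(
      start = starts, end = starts + 4L, type = assign,
      motif = substring(x, starts, starts + 4L),
      distance = d[starts], stringsAsFactors = FALSE)
    if (resid_len > 0L)
      seg <- rbind(seg, data.frame(start = n * 5L + 1L, end = L,
                                   type = "residue", motif = NA_character_,
                                   distance = NA_integer_))
    cost <- sum(d[starts]) + params$skip_penalty * resid_len
  } else {
    # suffix DP: f[i] = min cost of tiling x[i..L]; f[L+1] = 0
    sp <- params$skip_penalty
    f <- numeric(L + 1L); f[L + 1L] <- 0
    # positions L, L-1, ... : pentamer allowed when i + 4 <= L
    for (i in L:1) {
      best <- sp + f[i + 1L]
      if (i <= nk && d[i] <= params$max_unit_cost) {
        pc <- d[i] + f[i + 5L]
        if (pc < best) best <- pc
      }
      f[i] <- best
    }
    # traceback, preferring the pentamer on ties
    starts <- integer(0); i <- 1L
    skip_flag <- logical(L)
    while (i <= L) {
      take <- i <= nk && d[i] <= params$max_unit_cost &&
        (d[i] + f[i + 5L]) <= (sp + f[i + 1L])
      if (take) { starts <- c(starts, i); i <- i + 5L }
      else { skip_flag[i] <- TRUE; i <- i + 1L }
    }
    seg <- data.frame(
      start = starts, end = starts + 4L, type = rep("pentamer", length(starts)),
      motif = substring(x, starts, starts + 4L), distance = d[starts],
      stringsAsFactors = FALSE)
    if (any(skip_flag)) {
      r <- rle(skip_flag)
      ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
      runs <- which(r$values)
      seg <- rbind(seg, data.frame(start = begs[runs], end = ends[runs],
                                   type = "residue", motif = NA_character_,
                                   distance = NA_integer_))
      seg <- seg[order(seg$start), , drop = FALSE]
      rownames(seg) <- NULL
    }
    cost <- f[1L]
  }
  attr(seg, "cost") <- cost
  attr(seg, "params") <- params
  seg
}

#' Pentamer spectrum of a satellite array
#'
#' Counts every assigned pentamer motif, aggregates counts by Hamming
#' distance class 0-5, and records the number of unassigned residue bases.
#' The invariant `5 * sum(counts) + residue_bases == total_length` always
#' holds.
#'
#' @inheritParams segment_array
#' @return An object of class `pentamer_spectrum` with fields
#'   `motif_counts` (named integer vector), `by_distance` (named integer
#'   vector, names `"0"`..`"5"`), `residue_bases`, `total_length` and
#'   `params`.
#' @export
pentamer_spectrum <- function(record, params = segmentation_params()) {
  seg <- segment_array(record, params)
  pent <- seg[seg$type == "pentamer", , drop = FALSE]
  counts <- table(pent$motif)
  motif_counts <- as.integer(counts)
  names(motif_counts) <- names(counts)
  dist <- hamming5(names(motif_counts), params$ref)
  by_distance <- vapply(0:5, function(d)
    sum(motif_counts[dist == d]), integer(1))
  names(by_distance) <- as.character(0:5)
  resid <- sum(seg$end[seg$type == "residue"] -
                 seg$start[seg$type == "residue"] + 1L)
  new_pentamer_spectrum(motif_counts, as.integer(resid), record$length, params)
}

# Internal constructor shared with the synthetic generator's truth records.
new_pentamer_spectrum <- function(motif_counts, residue_bases, total_length,
                                  params) {
  motif_counts <- motif_counts[order(names(motif_counts))]
  dist <- if (length(motif_counts)) hamming5(names(motif_counts), params$ref)
          else integer(0)
  by_distance <- vapply(0:5, function(d)
    as.integer(sum(motif_counts[dist == d])), integer(1))
  names(by_distance) <- as.character(0:5)
  structure(list(motif_counts = motif_counts, by_distance = by_distance,
                 residue_bases = as.integer(residue_bases),
                 total_length = as.integer(total_length), params = params),
            class = "pentamer_spectrum")
}

#' @export
print.pentamer_spectrum <- function(x, ...) {
  cat("<pentamer_spectrum>", x$total_length, "bp;",
      sum(x$motif_counts), "pentamers;", x$residue_bases, "residue bases\n")
  cat("  by distance class:",
      paste(sprintf("%s:%d", names(x$by_distance), x$by_distance),
            collapse = "  "), "\n")
  invisible(x)
}

#' Compare two pentamer spectra
#'
#' Produces a per-motif delta table over the union of motifs seen in either
#' spectrum. `delta = b - a`, so a motif more abundant in the sample than
#' in the reference gets a positive delta; the comparison is antisymmetric.
#'
#' @param a,b [pentamer_spectrum] objects built with identical parameters.
#' @return A data frame with columns `motif`, `distance`, `count_a`,
#'   `count_b`, `delta`, ordered by distance then motif.
#' @export
compare_spectra <- function(a, b) {
  stopifnot(inherits(a, "pentamer_spectrum"), inherits(b, "pentamer_spectrum"))
  if (!identical(a$params, b$params))
    stop("spectra were built with different segmentation parameters")
  motifs <- sort(union(names(a$motif_counts), names(b$motif_counts)))
  ca <- ifelse(motifs %in% names(a$motif_counts),
               a$motif_counts[motifs], 0L)
  cb <- ifelse(motifs %in% names(b$motif_counts),
               b$motif_counts[motifs], 0L)
  out <- data.frame(motif = motifs,
                    distance = hamming5(motifs, a$params$ref),
                    count_a = as.integer(ca), count_b = as.integer(cb),
                    delta = as.integer(cb - ca),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
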