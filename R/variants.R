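#' Gapped sequence pair
#'
#' Holds two rows of a pairwise alignment: equal-length gapped strings over
#' `A/C/G/T/-` with no column gapped in both rows. The first row is treated
#' as the reference throughout the variants module.
#'
#' @param a,b Gapped sequences (reference first).
#' @param source `"computed"` (produced by [align_global()]) or
#'   `"ingested"` (read from a provided alignment file).
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(a, b, source = c("computed", "ingested")) {
  source <- match.arg(source)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("aligned sequences differ in length (", nchar(a), " vs ",
         nchar(b), ")")
  ok <- function(x) grepl("^[ACGT-]+$", x)
  if (!ok(a) || !ok(b))
    stop("aligned sequences may contain only A/C/G/T/-")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (any(ca == "-" & cb == "-"))
    stop("alignment has a column gapped in both rows")
  structure(list(a = a, b = b, source = source), class = "aligned_pair")
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Aligns two unambiguous DNA sequences end to end. The optimization is
#' delegated to [Biostrings::pairwiseAlignment()] (`type = "global"`); a
#' gap run of length L costs `gap_open + gap_extend * L`. The defaults
#' (match +1, mismatch -1, open -5, extend -1) make multi-base indels align
#' as single runs rather than scattered gaps.
#'
#' @param a,b [seq_record] objects (or plain strings); `a` is the
#'   reference.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; penalties
#'   are given as positive magnitudes.
#' @return An [aligned_pair] (source `"computed"`) with the optimal score
#'   in attribute `"score"`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 5, gap_extend = 1) {
  sa <- if (inherits(a, "seq_record")) a$residues else toupper(a)
  sb <- if (inherits(b, "seq_record")) b$residues else toupper(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  if (!grepl("^[ACGT]+$", sa) || !grepl("^[ACGT]+$", sb))
    stop("alignment requires unambiguous A/C/G/T sequences")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  out <- aligned_pair(as.character(Biostrings::alignedPattern(pa)),
                      as.character(Biostrings::alignedSubject(pa)),
                      source = "computed")
  attr(out, "score") <- Biostrings::score(pa)
  out
}

#' Tally substitutions and indel events from an alignment
#'
#' A substitution is an aligned column with two differing non-gap bases; a
#' column pairing a base with a gap is never counted as a substitution.
#' Maximal runs of gap columns are merged into single indel events:
#' a gap run in the reference row is an insertion (the sample carries extra
#' bases), a run in the sample row a deletion. Event positions are reported
#' in reference coordinates: the position of the last reference base before
#' the event (0 for an event at the very start) for insertions, and the
#' first deleted reference base for deletions.
#'
#' @param aln An [aligned_pair] (reference first).
#' @return An object of class `variant_tally` with fields `substitutions`
#'   (count), `substitution_table` (data frame `ref_position`, `ref`,
#'   `alt`), `events` (data frame `kind`, `ref_position`, `length`) and
#'   `net_length_change`.
#' @export
tally_from_alignment <- function(aln) {
  stopifnot(inherits(aln, "aligned_pair"))
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  refpos <- cumsum(ca != "-")          # reference coordinate per column

  sub <- which(ca != "-" & cb != "-" & ca != cb)
  sub_tab <- data.frame(ref_position = refpos[sub], ref = ca[sub],
                        alt = cb[sub], stringsAsFactors = FALSE)

  events <- data.frame(kind = character(0), ref_position = integer(0),
                       length = integer(0), stringsAsFactors = FALSE)
  gap_state <- ifelse(ca == "-", "ins", ifelse(cb == "-", "del", "none"))
  r <- rle(gap_state)
  ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
  for (k in which(r$values != "none")) {
    kind <- if (r$values[k] == "ins") "insertion" else "deletion"
    pos <- if (kind == "insertion") refpos[begs[k]]  # base before the run
           else refpos[begs[k]]                      # first deleted base
    events <- rbind(events, data.frame(
      kind = kind, ref_position = as.integer(pos),
      length = r$lengths[k], stringsAsFactors = FALSE))
  }
  net <- sum(events$length[events$kind == "insertion"]) -
    sum(events$length[events$kind == "deletion"])
  structure(list(substitutions = length(sub),
                 substitution_table = sub_tab,
                 events = events,
                 net_length_change = as.integer(net)),
            class = "variant_tally")
}

#' @export
print.variant_tally <- function(x, ...) {
  cat("<variant_tally>", x$substitutions, "substitution(s),",
      nrow(x$events), "indel event(s), net", x$net_length_change, "bp\n")
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  %s of %d bp at reference position %d\n",
                  x$events$kind[i], x$events$length[i],
                  x$events$ref_position[i]))
  }
  invisible(x)
}

#' Net length change implied by a variant tally
#'
#' Sum of insertion lengths minus sum of deletion lengths; e.g. a 15 bp
#' insertion together with a 114 bp deletion gives -99.
#'
#' @param tally A `variant_tally`, or a data frame of events with columns
#'   `kind` and `length`.
#' @return Signed base count.
#' @export
net_length <- function(tally) {
  ev <- if (inherits(tally, "variant_tally")) tally$events else tally
  if (nrow(ev) == 0L) return(0L)
  as.integer(sum(ev$length[ev$kind == "insertion"]) -
               sum(ev$length[ev$kind == "deletion"]))
}
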