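#' Restriction enzyme specification
#'
#' An enzyme is described by its recognition pattern (IUPAC, possibly with
#' interior N runs such as `"GATNNNNATC"`), its overhang geometry and,
#' where known, the position of the top-strand cut. `site_length` is the
#' number of informative (non-N) letters of the recognition pattern.
#'
#' `cut_top` counts the bases of (or beyond) the recognition sequence, from
#' its start on the strand carrying the pattern, that precede the cut: 1
#' for EcoRI `G/AATTC`, 0 for MboI `/GATC`, 3 for FspI `TGC/GCA`. Type IIS
#' enzymes cutting downstream of the site have `cut_top` larger than the
#' pattern length (Eco57I `CTGAAG(16/14)` has `cut_top = 22`). `cut_bottom`
#' is the analogous offset of the bottom-strand cut; it defaults to
#' `cut_top` (blunt cutters and symmetric palindromes).
#'
#' @param name Enzyme name (unique within a panel).
#' @param recognition IUPAC recognition pattern.
#' @param overhang `"blunt"`, `"5p"` or `"3p"`.
#' @param cut_top,cut_bottom Cut offsets as described; `NA` when unknown
#'   (disables fragmentation but not site counting).
#' @return An object of class `enzyme_spec`.
#' @examples
#' enzyme_spec("EcoRI", "GAATTC", "5p", cut_top = 1)
#' @export
enzyme_spec <- function(name, recognition, overhang = c("blunt", "5p", "3p"),
                        cut_top = NA, cut_bottom = NA) {
  overhang <- match.arg(overhang)
  recognition <- toupper(recognition)
  if (!nzchar(recognition)) stop("empty recognition pattern")
  bad <- .illegal_residues(recognition)
  if (length(bad))
    stop("enzyme '", name, "': illegal letter(s) in recognition pattern: ",
         paste(unique(bad), collapse = ", "))
  ch <- strsplit(recognition, "", fixed = TRUE)[[1]]
  cut_top <- suppressWarnings(as.integer(cut_top))
  cut_bottom <- suppressWarnings(as.integer(cut_bottom))
  if (is.na(cut_bottom)) cut_bottom <- cut_top
  structure(list(name = name, recognition = recognition,
                 site_length = sum(ch != "N"),
                 overhang = overhang,
                 cut_top = cut_top, cut_bottom = cut_bottom),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s  %s  (%d informative bases, %s%s)\n",
              x$name, x$recognition, x$site_length, x$overhang,
              if (!is.na(x$cut_top)) sprintf(", cut %d/%d", x$cut_top,
                                             x$cut_bottom) else ""))
  invisible(x)
}

#' Read an enzyme panel from TSV
#'
#' Expected columns: `name`, `recognition`, `overhang`, and optionally
#' `cut_top` / `cut_bottom`. Extra columns are ignored.
#'
#' @param path TSV file with a header row.
#' @return A named list of [enzyme_spec] objects, in file order.
#' @export
read_enzyme_panel <- function(path) {
  tab <- read_tsv_table(path)
  need <- c("name", "recognition", "overhang")
  if (!all(need %in% names(tab)))
    stop("enzyme panel must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate enzyme names in panel: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    enzyme_spec(tab$name[i], tab$recognition[i], tab$overhang[i],
                if ("cut_top" %in% names(tab)) tab$cut_top[i] else NA,
                if ("cut_bottom" %in% names(tab)) tab$cut_bottom[i] else NA)
  })
  names(specs) <- tab$name
  specs
}

#' Compile an IUPAC pattern into a position matcher
#'
#' Returns a function that maps a DNA string to the 1-based start positions
#' of every (overlapping) occurrence of the pattern, with ambiguity codes
#' in the pattern expanded (W = A/T, R = A/G, N = any, ...). Matching is
#' done with [Biostrings::matchPattern()] treating the subject as fixed.
#'
#' @param pattern IUPAC DNA pattern.
#' @return A function `(subject) -> integer vector of start positions`,
#'   with the pattern retained in attribute `"pattern"`.
#' @examples
#' m <- compile_iupac("CCWGG")
#' m("ACCAGGT")  # 2
#' @export
compile_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  bad <- .illegal_residues(pattern)
  if (!nzchar(pattern) || length(bad))
    stop("illegal IUPAC pattern: '", pattern, "'")
  pat <- Biostrings::DNAString(pattern)
  f <- function(subject) {
    subj <- if (methods::is(subject, "DNAString")) subject
            else Biostrings::DNAString(toupper(subject))
    Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = "subject"))
  }
  attr(f, "pattern") <- pattern
  f
}

# Is an IUPAC pattern its own reverse complement (as a pattern)?
is_palindromic_pattern <- function(pattern) {
  identical(toupper(pattern), reverse_complement(pattern))
}

#' Find recognition sites of an enzyme in a sequence
#'
#' All overlapping occurrences are reported. A palindromic recognition
#' pattern describes one double-stranded site, so it is searched on the
#' forward strand only; a non-palindromic pattern is additionally sought on
#' the reverse strand (via its reverse complement) and reported at its
#' forward-strand start coordinate with `strand = "reverse"`.
#'
#' @param record A [seq_record] with unambiguous residues.
#' @param enzyme An [enzyme_spec].
#' @param both_strands Search the reverse strand for non-palindromic
#'   patterns (default `TRUE`).
#' @return A data frame with columns `enzyme`, `position`, `strand`.
#' @export
find_sites <- function(record, enzyme, both_strands = TRUE) {
  stopifnot(inherits(record, "seq_record"), inherits(enzyme, "enzyme_spec"))
  subj <- Biostrings::DNAString(record$residues)
  fwd <- compile_iupac(enzyme$recognition)(subj)
  pos <- fwd; strand <- rep("forward", length(fwd))
  if (both_strands && !is_palindromic_pattern(enzyme$recognition)) {
    rev <- compile_iupac(reverse_complement(enzyme$recognition))(subj)
    pos <- c(pos, rev)
    strand <- c(strand, rep("reverse", length(rev)))
  }
  o <- order(pos)
  data.frame(enzyme = rep(enzyme$name, length(pos)),
             position = as.integer(pos[o]), strand = strand[o],
             stringsAsFactors = FALSE)
}

#' Per-enzyme site frequency table
#'
#' @param record A [seq_record].
#' @param panel A named list of [enzyme_spec] objects (duplicate names are
#'   rejected).
#' @param both_strands Passed to [find_sites()].
#' @return A named integer vector of site counts (zeros retained).
#' @export
site_frequency_table <- function(record, panel, both_strands = TRUE) {
  if (length(panel) == 0L) stop("empty enzyme panel")
  nm <- vapply(panel, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate enzyme names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  counts <- vapply(panel, function(e)
    nrow(find_sites(record, e, both_strands)), integer(1))
  names(counts) <- nm
  counts
}

#' Compare site frequencies between a reference and a sample
#'
#' An enzyme is *lost* when it has at least one site in the reference and
#' none in the sample, *gained* in the opposite case; enzymes present in
#' both but at different counts are reported as *changed*, not lost or
#' gained.
#'
#' @param ref,sample Named integer vectors over the same enzyme panel
#'   (e.g. from [site_frequency_table()]).
#' @return An object of class `digest_summary` with fields `lost`, `gained`
#'   (character vectors) and `changed` (data frame `enzyme`, `ref`,
#'   `sample`).
#' @export
compare_frequencies <- function(ref, sample) {
  if (is.null(names(ref)) || is.null(names(sample)) ||
      !setequal(names(ref), names(sample)) ||
      length(ref) != length(sample))
    stop("reference and sample must cover the same enzyme panel")
  sample <- sample[names(ref)]
  lost <- names(ref)[ref > 0L & sample == 0L]
  gained <- names(ref)[ref == 0L & sample > 0L]
  ch <- names(ref)[ref > 0L & sample > 0L & ref != sample]
  structure(list(
    lost = lost, gained = gained,
    changed = data.frame(enzyme = ch, ref = as.integer(ref[ch]),
                         sample = as.integer(sample[ch]),
                         stringsAsFactors = FALSE, row.names = NULL)),
    class = "digest_summary")
}

#' @export
print.digest_summary <- function(x, ...) {
  cat("<digest_summary>\n")
  cat("  lost   (", length(x$lost), "):",
      paste(x$lost, collapse = ", "), "\n")
  cat("  gained (", length(x$gained), "):",
      paste(x$gained, collapse = ", "), "\n")
  cat("  changed count:", nrow(x$changed), "\n")
  invisible(x)
}

# Top-strand cut boundaries (cut falls after the returned position) for all
# sites of `enzyme`; off-sequence cuts are dropped.
cut_boundaries <- function(record, enzyme, both_strands = TRUE) {
  hits <- find_sites(record, enzyme, both_strands)
  plen <- nchar(enzyme$recognition)
  cuts <- integer(0)
  if (nrow(hits)) {
    fwd <- hits$position[hits$strand == "forward"]
    cuts <- c(cuts, fwd - 1L + enzyme$cut_top)
    rev <- hits$position[hits$strand == "reverse"]
    if (length(rev))
      cuts <- c(cuts, (rev + plen - 1L) - enzyme$cut_bottom)
  }
  sort(unique(cuts[cuts >= 1L & cuts < record$length]))
}

#' Virtual digestion of a linear molecule
#'
#' Fragments are delimited by the sorted top-strand cut positions. A
#' recognition hit whose cut offset falls outside the sequence (type IIS
#' enzymes near an end) still counts as a site but produces no fragment
#' boundary. Fragment lengths always sum to the sequence length.
#'
#' @param record A [seq_record] (linear molecule).
#' @param enzyme An [enzyme_spec] with a defined `cut_top`.
#' @param both_strands Passed to [find_sites()].
#' @return An integer vector of fragment lengths in molecule order, class
#'   `fragment_set`.
#' @export
digest_fragments <- function(record, enzyme, both_strands = TRUE) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (is.na(enzyme$cut_top))
    stop("enzyme '", enzyme$name,
         "' has no cut offset: fragmentation unsupported")
  cuts <- cut_boundaries(record, enzyme, both_strands)
  frag <- diff(c(0L, cuts, record$length))
  structure(as.integer(frag), class = "fragment_set")
}

#' PCR-RFLP allele call for an amplicon
#'
#' Digests the amplicon and calls `"uncut"` (single full-length fragment,
#' the undigested allele pattern) when the enzyme finds no site, `"cut"`
#' otherwise.
#'
#' @inheritParams digest_fragments
#' @param amplicon A [seq_record] for the PCR product.
#' @return A list with `allele` (`"cut"`/`"uncut"`) and `fragments`
#'   (a `fragment_set`).
#' @export
predict_rflp <- function(amplicon, enzyme, both_strands = TRUE) {
  frags <- digest_fragments(amplicon, enzyme, both_strands)
  list(allele = if (length(frags) > 1L) "cut" else "uncut",
       fragments = frags)
}
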