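#' Primer pair for end-point PCR
#'
#' @param id Pair identifier.
#' @param forward,reverse Primer sequences written 5'->3' (the reverse
#'   primer anneals to the forward strand via its reverse complement).
#'   Lengths must be >= 15 bases when sequences are given.
#' @param forward_region,reverse_region Optional [region]s giving primer
#'   locations on a template (for coordinate-based amplicon arithmetic).
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(id, forward = NULL, reverse = NULL,
                        forward_region = NULL, reverse_region = NULL) {
  chk <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- toupper(x)
    if (nchar(x) < 15L)
      stop(what, " primer of pair '", id, "' is shorter than 15 bases")
    bad <- .illegal_residues(x)
    if (length(bad)) stop(what, " primer of pair '", id,
                          "' has illegal residues")
    x
  }
  structure(list(id = id,
                 forward = chk(forward, "forward"),
                 reverse = chk(reverse, "reverse"),
                 forward_region = forward_region,
                 reverse_region = reverse_region),
            class = "primer_pair")
}

#' Amplicon length from primer coordinates
#'
#' For a forward primer at `fwd` and a reverse primer at `rev` on the same
#' template (both as 1-based inclusive intervals on the forward strand),
#' the end-point PCR product spans `fwd$start .. rev$end`, so its length is
#' `rev$end - fwd$start + 1`. A degenerate self-pair (identical intervals)
#' is allowed and returns the interval width.
#'
#' @param fwd,rev [region] objects (or length-2 numeric `c(start, end)`).
#' @return Product length in bases.
#' @examples
#' amplicon_length_from_coords(region(61, 85), region(860, 884))  # 824
#' amplicon_length_from_coords(region(763, 782), region(861, 880)) # 118
#' @export
amplicon_length_from_coords <- function(fwd, rev) {
  as_reg <- function(x) if (inherits(x, "region")) x else region(x[1], x[2])
  fwd <- as_reg(fwd); rev <- as_reg(rev)
  if (rev$end < fwd$start)
    stop("inverted primer coordinates: reverse primer ends before the ",
         "forward primer starts")
  as.integer(rev$end - fwd$start + 1L)
}

#' Predict the PCR product of a primer pair on a template
#'
#' The forward primer is matched on the forward strand and the reverse
#' primer's reverse complement downstream of it, both with at most
#' `max_mismatch` mismatches (exact by default, the end-point PCR
#' analogue). When several products are possible the smallest is reported.
#' Primers in the wrong orientation yield no product.
#'
#' @param template A [seq_record].
#' @param pair A [primer_pair] with both primer sequences set.
#' @param max_mismatch Allowed mismatches per primer (default 0).
#' @return `NULL` when no product forms, otherwise a list with `length`
#'   and `region` (the product's span on the template).
#' @export
predict_amplicon <- function(template, pair, max_mismatch = 0L) {
  stopifnot(inherits(template, "seq_record"), inherits(pair, "primer_pair"))
  if (is.null(pair$forward) || is.null(pair$reverse))
    stop("primer pair '", pair$id, "' lacks primer sequences")
  subj <- Biostrings::DNAString(template$residues)
  fhit <- Biostrings::matchPattern(pair$forward, subj,
                                   max.mismatch = max_mismatch)
  rhit <- Biostrings::matchPattern(reverse_complement(pair$reverse), subj,
                                   max.mismatch = max_mismatch)
  if (length(fhit) == 0L || length(rhit) == 0L) return(NULL)
  fs <- Biostrings::start(fhit)
  re <- Biostrings::end(rhit)
  rs <- Biostrings::start(rhit)
  best <- NULL
  for (f in fs) {
    ok <- rs >= f + nchar(pair$forward)  # reverse site fully downstream
    if (!any(ok)) next
    e <- min(re[ok])
    len <- e - f + 1L
    if (is.null(best) || len < best$length)
      best <- list(length = as.integer(len), region = region(f, e))
  }
  best
}

#' Read an STS marker panel from TSV
#'
#' Expected columns: `sY_id`, `locus`, `multicopy` (logical or 0/1/`*`);
#' optional primer columns `fwd_seq`, `rev_seq` and status columns are
#' carried through untouched.
#'
#' @param path TSV file with a header row.
#' @return A data frame, one row per marker, with unique `sY_id`.
#' @export
read_sts_panel <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("sY_id", "locus") %in% names(tab)))
    stop("STS panel must have columns sY_id and locus")
  if (anyDuplicated(tab$sY_id))
    stop("duplicate STS identifiers in panel")
  if ("multicopy" %in% names(tab))
    tab$multicopy <- tab$multicopy %in% c("*", "1", "TRUE", "yes")
  tab
}

#' Build a validated STS presence/absence profile
#'
#' Input is either a named status vector (values `"present"`/`"absent"`,
#' or `"+"`/`"-"` as in lab score sheets) covering the panel exactly, or a
#' template sequence plus a primer table, in which case each marker is
#' scored by [predict_amplicon()].
#'
#' @param x A named character vector of marker statuses, or a [seq_record]
#'   template.
#' @param panel A data frame from [read_sts_panel()]. For template-based
#'   profiling it must carry `fwd_seq` and `rev_seq` columns.
#' @param max_mismatch Passed to [predict_amplicon()] for template-based
#'   profiling.
#' @return A named character vector over the panel's markers with values
#'   `"present"`/`"absent"`, class `sts_profile`.
#' @export
profile_sts <- function(x, panel, max_mismatch = 0L) {
  ids <- panel$sY_id
  if (inherits(x, "seq_record")) {
    if (!all(c("fwd_seq", "rev_seq") %in% names(panel)))
      stop("template-based profiling needs fwd_seq/rev_seq in the panel")
    status <- vapply(seq_len(nrow(panel)), function(i) {
      pp <- primer_pair(ids[i], panel$fwd_seq[i], panel$rev_seq[i])
      if (is.null(predict_amplicon(x, pp, max_mismatch))) "absent"
      else "present"
    }, "")
    names(status) <- ids
  } else {
    status <- x
    status[status == "+"] <- "present"
    status[status == "-"] <- "absent"
    if (is.null(names(status)) || !setequal(names(status), ids) ||
        length(status) != length(ids))
      stop("status vector must cover every panel marker exactly once")
    if (!all(status %in% c("present", "absent")))
      stop("statuses must be 'present'/'absent' (or '+'/'-')")
    status <- status[ids]
  }
  structure(status, class = "sts_profile")
}

#' @export
print.sts_profile <- function(x, ...) {
  cat("<sts_profile>", sum(x == "present"), "present /",
      sum(x == "absent"), "absent of", length(x), "markers\n")
  if (any(x == "absent"))
    cat("  absent:", paste(names(x)[x == "absent"], collapse = ", "), "\n")
  invisible(x)
}

#' Read deletion signatures from JSON
#'
#' Each signature is an object with fields `class` (name), `absent`
#' (marker ids that must be absent) and `flanks` (marker ids that must be
#' present). Signatures are configuration, not hard-coded truth: the
#' shipped file is a curated approximation of recurrent Y-microdeletion
#' patterns and is meant to be edited.
#'
#' @param path JSON file.
#' @return A list of signature lists, each of class `deletion_signature`.
#' @export
read_signatures <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    sig <- list(class = s$class,
                absent = as.character(unlist(s$absent)),
                flanks = as.character(unlist(s$flanks)))
    if (length(intersect(sig$absent, sig$flanks)))
      stop("signature '", sig$class,
           "' lists a marker as both absent and flank")
    structure(sig, class = "deletion_signature")
  })
}

#' Call deletion classes from an STS profile
#'
#' A class is called if and only if all of its `absent` markers are absent
#' from the profile and all of its `flanks` markers are present.
#' Overlapping and nested matches are all reported; flank requirements are
#' the mechanism for disambiguating nested patterns (e.g. a gr/gr
#' signature requiring a marker that the full AZFc deletion removes).
#'
#' @param profile An `sts_profile`.
#' @param signatures A list of signatures from [read_signatures()] (or
#'   built in code with the same fields).
#' @return A character vector of matched class names, sorted; empty when
#'   nothing matches (an intact profile never matches).
#' @export
classify_deletions <- function(profile, signatures) {
  stopifnot(inherits(profile, "sts_profile"))
  markers <- names(profile)
  hits <- character(0)
  for (s in signatures) {
    unknown <- setdiff(c(s$absent, s$flanks), markers)
    if (length(unknown))
      stop("signature '", s$class, "' references marker(s) not in the ",
           "profile's panel: ", paste(unknown, collapse = ", "))
    if (all(profile[s$absent] == "absent") &&
        all(profile[s$flanks] == "present"))
      hits <- c(hits, s$class)
  }
  sort(hits)
}
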