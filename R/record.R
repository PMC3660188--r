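#' Sequence records with 1-based coordinate addressing
#'
#' A `seq_record` is an identified DNA sequence: an id, an optional free-text
#' description, and uppercase residues over the IUPAC DNA alphabet. All
#' coordinates in this package are 1-based and inclusive on the forward
#' strand, matching the convention of primer location tables (e.g. a primer
#' at 61-85 covers 25 bases).
#'
#' @param id Record identifier (first whitespace-delimited token of a FASTA
#'   header).
#' @param residues DNA residues; lowercase is accepted and folded to
#'   uppercase. Only IUPAC DNA letters are allowed (`U` is rejected).
#' @param description Optional free text (remainder of a FASTA header).
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `residues` and `length`.
#' @examples
#' rec <- seq_record("unit1", "ttccattcca")
#' rec$length
#' @export
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L)
    stop("'residues' must be a single string")
  residues <- toupper(residues)
  if (!nzchar(residues))
    stop("empty sequence for record '", id, "'")
  bad <- .illegal_residues(residues)
  if (length(bad))
    stop("record '", id, "' contains non-IUPAC DNA residue(s): ",
         paste(unique(bad), collapse = ", "))
  structure(
    list(id = id, description = description, residues = residues,
         length = nchar(residues)),
    class = "seq_record"
  )
}

# IUPAC DNA alphabet (no U: DNA only)
.IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")

.illegal_residues <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  ch[!ch %in% .IUPAC_DNA]
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  (%d bp)\n", x$id, x$length))
  show <- if (x$length > 60) paste0(substr(x$residues, 1, 57), "...")
          else x$residues
  cat(" ", show, "\n")
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' Records are returned in file order with residues uppercased. The FASTA
#' syntax is parsed by [Biostrings::readBStringSet()]; residues are then
#' validated against the IUPAC DNA alphabet so that an illegal letter is
#' reported with the record that contains it.
#'
#' @param path Path to a FASTA file.
#' @return A list of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no records in '", path, "'")
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[i]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    seq_record(id, as.character(set[[i]]), desc)
  })
}

#' Write sequence records as FASTA
#'
#' Output lines are wrapped at 60 columns so files are deterministic.
#'
#' @param records A `seq_record` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "residues"))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Define a 1-based inclusive region
#'
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand `"forward"` or `"reverse"`.
#' @return An object of class `region`.
#' @examples
#' region(89, 703)           # the SRY coding region within its amplicon
#' @export
region <- function(start, end, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid region: need 1 <= start <= end")
  structure(list(start = start, end = end, strand = strand),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %d-%d (%s)\n", x$start, x$end, x$strand))
  invisible(x)
}

#' Extract a region from a record
#'
#' Returns the sub-sequence covered by `region`; a reverse-strand region
#' returns the reverse complement. The returned length is always
#' `end - start + 1`.
#'
#' @param record A [seq_record].
#' @param reg A [region] lying within the record.
#' @return A [seq_record] for the extracted (sub-)sequence.
#' @export
extract_region <- function(record, reg) {
  stopifnot(inherits(record, "seq_record"), inherits(reg, "region"))
  if (reg$end > record$length)
    stop("region ", reg$start, "-", reg$end, " out of bounds for '",
         record$id, "' (", record$length, " bp)")
  sub <- substr(record$residues, reg$start, reg$end)
  if (reg$strand == "reverse") sub <- reverse_complement(sub)
  seq_record(
    sprintf("%s:%d-%d%s", record$id, reg$start, reg$end,
            if (reg$strand == "reverse") "(-)" else ""),
    sub,
    record$description
  )
}

#' Reverse complement of a DNA string
#'
#' Honours IUPAC ambiguity codes (W<->W, R<->Y, N<->N, ...).
#'
#' @param residues A DNA string.
#' @return The reverse complement, as a plain string.
#' @export
reverse_complement <- function(residues) {
  residues <- toupper(residues)
  bad <- .illegal_residues(residues)
  if (length(bad))
    stop("non-IUPAC DNA residue(s): ", paste(unique(bad), collapse = ", "))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(residues)))
}

# Plain TSV-with-header reader used for every tabular asset.
read_tsv_table <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", ...)
}

#' Read an aligned-sequence file
#'
#' Reads a pairwise or multiple alignment either as gapped FASTA or as a
#' CLUSTAL-format file (the format emitted by ClustalW). Gapped FASTA is
#' parsed with [Biostrings::readBStringSet()]; CLUSTAL with
#' [seqinr::read.alignment()].
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return A named character vector of gapped sequences (uppercase, gaps as
#'   `-`), one element per aligned sequence.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    out <- toupper(as.character(set))
    names(out) <- sub("\\s.*$", "", names(set))
  } else {
    aln <- seqinr::read.alignment(path, format = "clustal")
    out <- toupper(unlist(aln$seq))
    names(out) <- aln$nam
  }
  if (length(unique(nchar(out))) != 1L)
    stop("aligned sequences have unequal lengths in '", path, "'")
  out
}
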