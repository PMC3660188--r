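# Accessors for the tabular assets shipped with the package. These are
# published tables re-typed as editable plain-text inputs: the 65-enzyme
# virtual-digest panel with its printed site frequencies for the DYZ1
# reference unit (GenBank AC068123.5) and the DU145/LNCaP cell-line units,
# the printed pentamer/derivative counts per 3564 bp HaeIII unit, the DYZ1
# and SRY primer tables with their amplicon combinations, the 51-marker
# MSY STS panel, the PCR-RFLP assay definitions, and a curated (editable,
# approximate) AZF deletion-signature configuration.

dyz1_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dyz1kit")
  if (!nzchar(path)) stop("missing package asset: ", file)
  path
}

#' Bundled DYZ1 virtual-digest enzyme panel
#'
#' The 65-enzyme panel used for virtual restriction mapping of the 3.56 kb
#' DYZ1 unit, as [enzyme_spec] objects. Cut offsets are provided for
#' common within-site cutters; enzymes without a curated offset can be
#' counted but not fragmented.
#'
#' @return A named list of [enzyme_spec] objects.
#' @export
dyz1_enzyme_panel <- function() {
  read_enzyme_panel(dyz1_extdata("enzyme_panel_dyz1.tsv"))
}

#' Published per-enzyme site frequencies for DYZ1 units
#'
#' Site counts of the digest panel on the reference DYZ1 unit
#' (AC068123.5) and on the DU145 and LNCaP cell-line units, as printed.
#'
#' @return A data frame with columns `name`, `AC068123.5`, `DU145`,
#'   `LNCaP`.
#' @export
dyz1_site_frequencies <- function() {
  read_tsv_table(dyz1_extdata("dyz1_site_frequencies.tsv"))
}

#' Published pentamer/derivative counts per DYZ1 HaeIII unit
#'
#' Counts of the TTCCA pentamer, each of its fifteen 1-base derivatives,
#' and the 2-5-base derivative aggregates per HaeIII unit for the
#' reference (AC068123.5), DU145 and LNCaP sequences, plus the unit
#' lengths.
#'
#' @return A data frame with columns `row`, `kind` (`size`, `motif`,
#'   `aggregate`), `distance`, `AC068123.5`, `DU145`, `LNCaP`.
#' @export
dyz1_pentamer_counts <- function() {
  read_tsv_table(dyz1_extdata("dyz1_pentamer_counts.tsv"))
}

#' Bundled DYZ1 and SRY primer tables
#'
#' `dyz1_primers()` returns the six forward (SAS 1-6) and six reverse
#' (SAS 7-12) primers tiling the 3.56 kb DYZ1 array with their 1-based
#' locations on the array (the upstream SAS 1 primer has no in-array
#' coordinates). `sry_primers()` returns the primer pair flanking the SRY
#' coding exon.
#'
#' @return A data frame with columns `id`, `seq`, `length`, `start`,
#'   `end`, `orientation`.
#' @export
dyz1_primers <- function() {
  read_tsv_table(dyz1_extdata("dyz1_primers.tsv"))
}

#' @rdname dyz1_primers
#' @export
sry_primers <- function() {
  read_tsv_table(dyz1_extdata("sry_primers.tsv"))
}

#' Bundled DYZ1 primer-combination table
#'
#' The 19 forward/reverse primer combinations used to verify DYZ1 array
#' intactness by end-point PCR, with their published amplicon sizes.
#' Annealing/extension conditions are retained as inert metadata.
#'
#' @return A data frame with columns `combination`, `fwd_id`, `rev_id`,
#'   `amplicon_bp`, `conditions`.
#' @export
dyz1_amplicon_combinations <- function() {
  read_tsv_table(dyz1_extdata("dyz1_amplicon_combinations.tsv"))
}

#' Bundled 51-marker MSY STS panel
#'
#' The sequence-tagged-site markers spanning the male-specific region of
#' the Y chromosome used for deletion screening, with locus labels,
#' multicopy flags and the published presence status in DU145 and LNCaP.
#'
#' @return A data frame from [read_sts_panel()] with extra columns
#'   `status_DU145`, `status_LNCaP`.
#' @export
msy_sts_panel <- function() {
  read_sts_panel(dyz1_extdata("msy_sts_panel.tsv"))
}

#' Bundled PCR-RFLP assay definitions
#'
#' Sequence-family-variant assays for the multicopy DAZ, GOLY, BPY2 and
#' TTTY4 genes: amplicon size, digestion enzyme and the published
#' fragment patterns of the two alleles.
#'
#' @return A data frame with columns `target`, `snv`, `amplicon_bp`,
#'   `enzyme`, `recognition`, `cut_top`, `fragments_A`, `fragments_B`.
#' @export
rflp_assays <- function() {
  read_tsv_table(dyz1_extdata("rflp_assays.tsv"))
}

#' Curated AZF deletion-signature configuration
#'
#' A curated, editable approximation of the STS absence patterns of
#' recurrent Y-chromosome microdeletions (AZFa, P5/proximal-P1,
#' P5/distal-P1, AZFc, gr/gr, b1/b2, b2/b3, TSPY-TSPY), expressed over the
#' bundled 51-marker panel. The signature engine is agnostic to this
#' content; treat the file as configuration to adapt to your marker set.
#'
#' @return A list of signatures from [read_signatures()].
#' @export
azf_signatures <- function() {
  read_signatures(dyz1_extdata("azf_signatures_curated.json"))
}
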