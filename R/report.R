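#' Render a combined analysis report
#'
#' Collects the outputs of any subset of the analysis stages into a single
#' JSON-serializable structure plus a human-readable table set. Sections
#' appear in a fixed order (spectrum, digest, variants, sts, qpcr)
#' regardless of input order, and the JSON form re-parses to identical
#' values.
#'
#' @param stages A named list; recognized names are `spectrum` (a
#'   [pentamer_spectrum]), `digest` (a `digest_summary`), `variants` (a
#'   `variant_tally`), `sts` (an `sts_profile`), `qpcr` (a
#'   `standard_curve`). At least one stage is required.
#' @return A list with `json` (a JSON string) and `text` (a character
#'   vector of report lines).
#' @export
render_report <- function(stages) {
  order_names <- c("spectrum", "digest", "variants", "sts", "qpcr")
  if (!is.list(stages) || is.null(names(stages)) || length(stages) == 0L)
    stop("'stages' must be a non-empty named list")
  unknown <- setdiff(names(stages), order_names)
  if (length(unknown))
    stop("unrecognized stage(s): ", paste(unknown, collapse = ", "))
  stages <- stages[intersect(order_names, names(stages))]

  payload <- list()
  lines <- character(0)
  hdr <- function(x) c(paste0("== ", x, " =="))

  if (!is.null(stages$spectrum)) {
    s <- stages$spectrum
    stopifnot(inherits(s, "pentamer_spectrum"))
    payload$spectrum <- list(
      total_length = s$total_length,
      residue_bases = s$residue_bases,
      by_distance = as.list(s$by_distance),
      motif_counts = as.list(s$motif_counts))
    lines <- c(lines, hdr("pentamer spectrum"),
               sprintf("total length: %d bp; residue bases: %d",
                       s$total_length, s$residue_bases),
               sprintf("distance %s: %d units", names(s$by_distance),
                       s$by_distance))
  }
  if (!is.null(stages$digest)) {
    d <- stages$digest
    stopifnot(inherits(d, "digest_summary"))
    payload$digest <- list(lost = as.list(d$lost),
                           gained = as.list(d$gained),
                           changed = d$changed)
    lines <- c(lines, hdr("virtual digest comparison"),
               sprintf("lost (%d): %s", length(d$lost),
                       paste(d$lost, collapse = ", ")),
               sprintf("gained (%d): %s", length(d$gained),
                       paste(d$gained, collapse = ", ")),
               sprintf("changed counts: %d enzymes", nrow(d$changed)))
  }
  if (!is.null(stages$variants)) {
    v <- stages$variants
    stopifnot(inherits(v, "variant_tally"))
    payload$variants <- list(substitutions = v$substitutions,
                             events = v$events,
                             net_length_change = v$net_length_change)
    lines <- c(lines, hdr("variant tally"),
               sprintf("substitutions: %d", v$substitutions),
               sprintf("indel events: %d (net %+d bp)", nrow(v$events),
                       v$net_length_change))
  }
  if (!is.null(stages$sts)) {
    p <- stages$sts
    stopifnot(inherits(p, "sts_profile"))
    payload$sts <- list(present = as.list(names(p)[p == "present"]),
                        absent = as.list(names(p)[p == "absent"]))
    lines <- c(lines, hdr("STS profile"),
               sprintf("%d present / %d absent of %d markers",
                       sum(p == "present"), sum(p == "absent"), length(p)))
  }
  if (!is.null(stages$qpcr)) {
    q <- stages$qpcr
    stopifnot(inherits(q, "standard_curve"))
    payload$qpcr <- list(slope = q$slope, intercept = q$intercept,
                         r_squared = q$r_squared,
                         efficiency = q$efficiency,
                         flags = as.list(q$flags))
    lines <- c(lines, hdr("qPCR standard curve"),
               sprintf("slope %.4f cycles/log10; R^2 %.6f; efficiency %.1f%%",
                       q$slope, q$r_squared, 100 * q$efficiency))
  }
  list(json = as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                            digits = NA)),
       text = lines)
}

# --- command-line entry point -----------------------------------------

cli_usage <- function() {
  c("usage: dyz1kit <subcommand> [arguments]",
    "",
    "subcommands:",
    "  spectrum <fasta> [--mode dynamic|fixed] [--skip-penalty N]",
    "           [--format tsv|json] [--out FILE] [--force]",
    "  digest <fasta> --panel panel.tsv [--out FILE]",
    "  compare-digest <ref.fasta> <sample.fasta> --panel panel.tsv",
    "  rflp <amplicon.fasta> --panel panel.tsv --enzyme NAME",
    "  variants <ref.fasta> <sample.fasta> [--aligned FILE]",
    "  sts-classify --profile profile.tsv --signatures sigs.json",
    "  qpcr-fit <standards.tsv>",
    "  qpcr-quant <standards.tsv> <unknowns.tsv> [--genome-mass-pg 3.3]",
    "  simulate-array --seed N --out PREFIX",
    "  simulate-series --seed N --out PREFIX")
}

cli_opt <- function(args, name, default = NULL) {
  i <- which(args == name)
  if (length(i) == 0L) return(default)
  if (i[1] == length(args)) stop("missing value for ", name)
  args[i[1] + 1L]
}

cli_flag <- function(args, name) any(args == name)

cli_positional <- function(args) {
  keep <- logical(length(args))
  i <- 1L
  valued <- c("--mode", "--skip-penalty", "--format", "--out", "--panel",
              "--enzyme", "--aligned", "--profile", "--signatures",
              "--genome-mass-pg", "--seed")
  while (i <= length(args)) {
    if (args[i] %in% valued) i <- i + 2L
    else if (startsWith(args[i], "--")) i <- i + 1L
    else { keep[i] <- TRUE; i <- i + 1L }
  }
  args[keep]
}

cli_emit <- function(lines, out, force) {
  if (is.null(out)) { writeLines(lines); return(invisible(NULL)) }
  if (file.exists(out) && !force)
    stop("output file '", out, "' exists; use --force to overwrite")
  writeLines(lines, out)
  invisible(out)
}

#' Run the dyz1kit command line
#'
#' Thin dispatcher over the package's functions; the installed script
#' `system.file("scripts", "dyz1kit.R", package = "dyz1kit")` forwards
#' `commandArgs(trailingOnly = TRUE)` here. Outputs are deterministic for
#' a given seed and inputs; existing output files are never overwritten
#' without `--force`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
    writeLines(cli_usage())
    return(invisible(0L))
  }
  sub <- args[1]
  rest <- args[-1]
  out <- cli_opt(rest, "--out")
  force <- cli_flag(rest, "--force")
  fmt <- cli_opt(rest, "--format", "tsv")
  pos <- cli_positional(rest)

  status <- tryCatch({
    switch(sub,
      "spectrum" = {
        rec <- read_fasta(pos[1])[[1]]
        params <- segmentation_params(
          mode = cli_opt(rest, "--mode", "dynamic"),
          skip_penalty = as.numeric(cli_opt(rest, "--skip-penalty", "3")))
        sp <- pentamer_spectrum(rec, params)
        if (fmt == "json") {
          cli_emit(render_report(list(spectrum = sp))$json, out, force)
        } else {
          tab <- c("row\tcount",
                   sprintf("actual_size_bp\t%d", sp$total_length),
                   sprintf("%s\t%d", sp$params$ref,
                           sp$by_distance[["0"]]),
                   sprintf("%d_bp_derivatives\t%d", 1:5,
                           sp$by_distance[as.character(1:5)]),
                   sprintf("%s\t%d",
                           names(sp$motif_counts)[
                             hamming5(names(sp$motif_counts),
                                      sp$params$ref) == 1L],
                           sp$motif_counts[
                             hamming5(names(sp$motif_counts),
                                      sp$params$ref) == 1L]),
                   sprintf("residue_bases\t%d", sp$residue_bases))
          cli_emit(tab, out, force)
        }
        0L
      },
      "digest" = {
        rec <- read_fasta(pos[1])[[1]]
        panel <- read_enzyme_panel(cli_opt(rest, "--panel"))
        freq <- site_frequency_table(rec, panel)
        cli_emit(c("enzyme\tsites",
                   sprintf("%s\t%d", names(freq), freq)), out, force)
        0L
      },
      "compare-digest" = {
        panel <- read_enzyme_panel(cli_opt(rest, "--panel"))
        ref <- site_frequency_table(read_fasta(pos[1])[[1]], panel)
        sam <- site_frequency_table(read_fasta(pos[2])[[1]], panel)
        cmp <- compare_frequencies(ref, sam)
        cli_emit(render_report(list(digest = cmp))$text, out, force)
        0L
      },
      "rflp" = {
        rec <- read_fasta(pos[1])[[1]]
        panel <- read_enzyme_panel(cli_opt(rest, "--panel"))
        enz <- panel[[cli_opt(rest, "--enzyme")]]
        if (is.null(enz)) stop("enzyme not found in panel")
        r <- predict_rflp(rec, enz)
        cli_emit(sprintf("%s\t%s\t%s", rec$id, r$allele,
                         paste(r$fragments, collapse = "+")), out, force)
        0L
      },
      "variants" = {
        aligned <- cli_opt(rest, "--aligned")
        aln <- if (!is.null(aligned)) {
          g <- read_alignment(aligned)
          aligned_pair(g[[1]], g[[2]], source = "ingested")
        } else {
          align_global(read_fasta(pos[1])[[1]], read_fasta(pos[2])[[1]])
        }
        cli_emit(render_report(list(variants =
                                      tally_from_alignment(aln)))$text,
                 out, force)
        0L
      },
      "sts-classify" = {
        prof_tab <- read_tsv_table(cli_opt(rest, "--profile"))
        status <- prof_tab$status
        names(status) <- prof_tab$sY_id
        panel <- data.frame(sY_id = prof_tab$sY_id,
                            locus = prof_tab$sY_id,
                            stringsAsFactors = FALSE)
        prof <- profile_sts(status, panel)
        sigs <- read_signatures(cli_opt(rest, "--signatures"))
        calls <- classify_deletions(prof, sigs)
        cli_emit(if (length(calls)) calls else "no_deletion_detected",
                 out, force)
        0L
      },
      "qpcr-fit" = {
        curve <- fit_standard_curve(read_dilution_series(pos[1]))
        cli_emit(render_report(list(qpcr = curve))$text, out, force)
        0L
      },
      "qpcr-quant" = {
        curve <- fit_standard_curve(read_dilution_series(pos[1]))
        unk <- read_unknowns(pos[2])
        gm <- as.numeric(cli_opt(rest, "--genome-mass-pg", "3.3"))
        cpr <- quantify(unk$ct, curve)
        cpg <- copies_per_genome(cpr, unk$input_mass_pg, gm)
        cli_emit(c("sample\tcopies_per_reaction\tcopies_per_genome_equivalent",
                   sprintf("%s\t%.1f\t%.1f", unk$sample, cpr, cpg)),
                 out, force)
        0L
      },
      "simulate-array" = {
        seed <- as.integer(cli_opt(rest, "--seed", "1"))
        g <- generate_array(array_spec(seed = seed))
        prefix <- if (is.null(out)) "synthetic_array" else out
        fa <- paste0(prefix, ".fasta")
        if (file.exists(fa) && !force) stop("'", fa, "' exists")
        write_fasta(g$record, fa)
        truth <- paste0(prefix, "_truth.json")
        writeLines(as.character(jsonlite::toJSON(list(
          seed = seed, motif_counts = as.list(g$truth$motif_counts),
          by_distance = as.list(g$truth$by_distance)),
          auto_unbox = TRUE)), truth)
        0L
      },
      "simulate-series" = {
        seed <- as.integer(cli_opt(rest, "--seed", "1"))
        ser <- simulate_dilution_series(series_spec(seed = seed))
        prefix <- if (is.null(out)) "synthetic_series" else out
        tsv <- paste0(prefix, ".tsv")
        if (file.exists(tsv) && !force) stop("'", tsv, "' exists")
        writeLines(c("known_copies\tct\treplicate",
                     sprintf("%.10g\t%.6f\t%s", ser$known_copies, ser$ct,
                             ser$replicate)), tsv)
        writeLines(as.character(jsonlite::toJSON(list(seed = seed),
                                                 auto_unbox = TRUE)),
                   paste0(prefix, "_truth.json"))
        0L
      },
      { message("unknown subcommand: ", sub)
        writeLines(cli_usage(), con = stderr()); 2L }
    )
  }, error = function(e) {
    message("dyz1kit error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
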