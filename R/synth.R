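# Seeded generators for every input class the pipeline consumes. Each
# generator records the ground truth it planted, so recovery tests never
# need external data. RNG use is localized: the caller's .Random.seed is
# saved and restored.

with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a synthetic satellite array
#'
#' Defaults mirror the composition of a real DYZ1 HaeIII unit: 712
#' pentamer units (3560 bases, the scale of the 3564 bp repeat) with
#' derivative rates chosen so that roughly 32% of units are the intact
#' reference pentamer, 41% are 1-base derivatives, 20% 2-base, and the
#' remainder 3-5-base derivatives - the proportions observed in reference
#' DYZ1 sequence.
#'
#' @param n_units Number of pentamer units.
#' @param derivative_rates Named numeric vector, names `"1"`..`"5"`,
#'   per-unit probability of drawing a derivative of that Hamming class;
#'   must sum to <= 1 (the remainder is the intact pentamer rate).
#' @param seed Integer seed.
#' @param ref Reference pentamer.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(n_units = 712L,
                       derivative_rates = c("1" = 0.410, "2" = 0.199,
                                            "3" = 0.052, "4" = 0.0126,
                                            "5" = 0.0014),
                       seed = 1L, ref = "TTCCA") {
  if (n_units < 1L) stop("need at least one unit")
  if (is.null(names(derivative_rates)) ||
      !setequal(names(derivative_rates), as.character(1:5)))
    stop("derivative_rates must be named '1'..'5'")
  derivative_rates <- derivative_rates[as.character(1:5)]
  if (any(derivative_rates < 0) || sum(derivative_rates) > 1)
    stop("derivative rates must be non-negative and sum to <= 1")
  structure(list(n_units = as.integer(n_units),
                 derivative_rates = derivative_rates,
                 seed = as.integer(seed), ref = toupper(ref)),
            class = "array_spec")
}

#' Generate a synthetic satellite array with known pentamer spectrum
#'
#' Builds a tandem array of `n_units` pentamers. Each unit is the
#' reference pentamer or, with the specified per-class probabilities, a
#' derivative at Hamming distance d obtained by substituting d distinct
#' uniformly chosen positions with uniformly chosen alternative bases - so
#' a class-d draw always yields a motif at distance exactly d, and the
#' recorded truth spectrum is exact. The same seed always reproduces the
#' same array.
#'
#' @param spec An [array_spec].
#' @return A list with `record` (a [seq_record]) and `truth` (a
#'   [pentamer_spectrum] reflecting the planted composition).
#' @export
generate_array <- function(spec) {
  stopifnot(inherits(spec, "array_spec"))
  with_local_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    refc <- strsplit(spec$ref, "", fixed = TRUE)[[1]]
    p <- c(1 - sum(spec$derivative_rates), spec$derivative_rates)
    cls <- sample(0:5, spec$n_units, replace = TRUE, prob = p)
    motifs <- vapply(cls, function(d) {
      if (d == 0L) return(spec$ref)
      pos <- sample.int(5L, d)
      ch <- refc
      for (j in pos) ch[j] <- sample(setdiff(bases, refc[j]), 1L)
      paste(ch, collapse = "")
    }, "")
    rec <- seq_record(sprintf("synthetic_array_seed%d", spec$seed),
                      paste(motifs, collapse = ""),
                      "synthetic DYZ1-like tandem pentamer array")
    counts <- table(motifs)
    mc <- as.integer(counts); names(mc) <- names(counts)
    truth <- new_pentamer_spectrum(mc, 0L, rec$length,
                                   segmentation_params(ref = spec$ref))
    list(record = rec, truth = truth)
  })
}

#' Plan of variants to inject into a sequence
#'
#' @param n_substitutions Number of point substitutions to plant at
#'   seeded random positions.
#' @param indels A data frame with columns `kind`
#'   (`"insertion"`/`"deletion"`), `position` (1-based; an insertion goes
#'   between `position` and `position + 1`, a deletion removes
#'   `position .. position + length - 1`) and `length`.
#' @param min_event_spacing Minimum separation in bases between any two
#'   planted events (default 20), so that alignment can recover each event
#'   as a distinct run.
#' @param seed Integer seed.
#' @return An object of class `variant_plan`.
#' @export
variant_plan <- function(n_substitutions = 0L, indels = NULL,
                         min_event_spacing = 20L, seed = 1L) {
  if (is.null(indels))
    indels <- data.frame(kind = character(0), position = integer(0),
                         length = integer(0), stringsAsFactors = FALSE)
  if (!all(c("kind", "position", "length") %in% names(indels)))
    stop("indels need columns kind, position, length")
  if (!all(indels$kind %in% c("insertion", "deletion")))
    stop("indel kind must be 'insertion' or 'deletion'")
  if (any(indels$length < 1L)) stop("indel lengths must be >= 1")
  if (nrow(indels) > 1L) {
    o <- order(indels$position)
    s <- indels[o, ]
    span_end <- ifelse(s$kind == "deletion", s$position + s$length - 1L,
                       s$position)
    gaps <- s$position[-1L] - span_end[-nrow(s)]
    if (any(gaps < min_event_spacing))
      stop("indel events overlap or are closer than min_event_spacing")
  }
  structure(list(n_substitutions = as.integer(n_substitutions),
                 indels = indels,
                 min_event_spacing = as.integer(min_event_spacing),
                 seed = as.integer(seed)),
            class = "variant_plan")
}

#' Inject substitutions and indels with retained ground truth
#'
#' Substitution positions are drawn at seeded random positions at least
#' `min_event_spacing` bases from every other event; each substituted base
#' is replaced by a different base. Indels are applied at the planned
#' reference positions (right to left, so coordinates stay in the original
#' frame). The returned truth tally is expressed in the same form that
#' [tally_from_alignment()] reports.
#'
#' @param record A [seq_record] (unambiguous).
#' @param plan A [variant_plan]; all events must fit in the sequence.
#' @return A list with `record` (mutated [seq_record]) and `truth` (a
#'   `variant_tally`).
#' @export
inject_variants <- function(record, plan) {
  stopifnot(inherits(record, "seq_record"), inherits(plan, "variant_plan"))
  L <- record$length
  ind <- plan$indels
  if (nrow(ind)) {
    ends <- ifelse(ind$kind == "deletion", ind$position + ind$length - 1L,
                   ind$position)
    if (any(ind$position < 1L) || any(ends > L))
      stop("indel events do not fit within the sequence")
  }
  with_local_seed(plan$seed, {
    bases <- c("A", "C", "G", "T")
    ch <- strsplit(record$residues, "", fixed = TRUE)[[1]]

    # positions blocked by indels (with spacing margin)
    blocked <- logical(L)
    sp <- plan$min_event_spacing
    if (nrow(ind)) {
      for (i in seq_len(nrow(ind))) {
        e <- if (ind$kind[i] == "deletion")
          ind$position[i] + ind$length[i] - 1L else ind$position[i]
        lo <- max(1L, ind$position[i] - sp)
        hi <- min(L, e + sp)
        blocked[lo:hi] <- TRUE
      }
    }
    sub_pos <- integer(0)
    if (plan$n_substitutions > 0L) {
      cand <- which(!blocked)
      for (k in seq_len(plan$n_substitutions)) {
        if (!length(cand))
          stop("cannot place ", plan$n_substitutions,
               " substitutions at the requested spacing")
        p <- cand[sample.int(length(cand), 1L)]
        sub_pos <- c(sub_pos, p)
        cand <- cand[abs(cand - p) >= sp]
      }
      sub_pos <- sort(sub_pos)
    }
    sub_ref <- ch[sub_pos]
    sub_alt <- vapply(sub_ref, function(b)
      sample(setdiff(bases, b), 1L), "")
    ch[sub_pos] <- sub_alt

    # apply indels right to left so earlier coordinates are unaffected
    if (nrow(ind)) {
      o <- order(ind$position, decreasing = TRUE)
      for (i in o) {
        p <- ind$position[i]; len <- ind$length[i]
        if (ind$kind[i] == "deletion") {
          ch <- ch[-(p:(p + len - 1L))]
        } else {
          ins <- sample(bases, len, replace = TRUE)
          ch <- append(ch, ins, after = p)
        }
      }
    }
    mutated <- seq_record(paste0(record$id, "_mut"),
                          paste(ch, collapse = ""),
                          "synthetic mutated copy with known variants")
    events <- ind[order(ind$position), , drop = FALSE]
    names(events)[names(events) == "position"] <- "ref_position"
    rownames(events) <- NULL
    truth <- structure(list(
      substitutions = length(sub_pos),
      substitution_table = data.frame(ref_position = sub_pos, ref = sub_ref,
                                      alt = unname(sub_alt),
                                      stringsAsFactors = FALSE),
      events = events,
      net_length_change = net_length(events)),
      class = "variant_tally")
    list(record = mutated, truth = truth)
  })
}

#' Specification of a simulated qPCR dilution series
#'
#' Defaults mirror a standard absolute-quantification setup: ten-fold
#' dilutions of a cloned template starting at 2e8 copies, six levels,
#' triplicate reactions, 100% efficiency and no Ct noise.
#'
#' @param start_copies Copies at the first (most concentrated) level.
#' @param dilution_factor Fold dilution between levels (> 1).
#' @param n_levels Number of dilution levels (>= 3 for fitting).
#' @param replicates Reactions per level.
#' @param efficiency Amplification efficiency as a fraction (> 0); 1.0
#'   doubles the template every cycle.
#' @param ct_at_1_copy Cycles needed to detect a single copy (the curve's
#'   intercept; default 40, a typical single-copy detection limit).
#' @param noise_sd Gaussian noise on the cycle scale added per reaction.
#' @param seed Integer seed.
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(start_copies = 2e8, dilution_factor = 10,
                        n_levels = 6L, replicates = 3L, efficiency = 1.0,
                        ct_at_1_copy = 40, noise_sd = 0, seed = 1L) {
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  if (efficiency <= 0) stop("efficiency must be > 0")
  if (start_copies <= 0) stop("start_copies must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(start_copies = start_copies,
                 dilution_factor = dilution_factor,
                 n_levels = as.integer(n_levels),
                 replicates = as.integer(replicates),
                 efficiency = efficiency, ct_at_1_copy = ct_at_1_copy,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "series_spec")
}

#' Simulate a qPCR dilution series
#'
#' Under constant-efficiency exponential amplification a template of
#' `copies` crosses threshold at
#' `ct = ct_at_1_copy - log(copies) / log(1 + efficiency)`, plus Gaussian
#' noise; at 100% efficiency successive ten-fold dilutions are spaced by
#' `log(10)/log(2) = 3.3219` cycles.
#'
#' @param spec A [series_spec].
#' @return A data frame with columns `known_copies`, `ct`, `replicate`.
#' @export
simulate_dilution_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  with_local_seed(spec$seed, {
    copies <- spec$start_copies / spec$dilution_factor^(0:(spec$n_levels - 1L))
    grid <- expand.grid(replicate = seq_len(spec$replicates),
                        known_copies = copies)
    ct0 <- spec$ct_at_1_copy -
      log(grid$known_copies) / log(1 + spec$efficiency)
    noise <- if (spec$noise_sd > 0)
      stats::rnorm(nrow(grid), 0, spec$noise_sd) else 0
    data.frame(known_copies = grid$known_copies, ct = ct0 + noise,
               replicate = paste0("r", grid$replicate),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic STS dataset with a planted deletion class
#'
#' Builds a presence/absence profile that is absent exactly at the markers
#' of the named signature class (the reserved name `"none"` gives an
#' all-present profile), and optionally a synthetic mock template plus
#' per-marker primer pairs: each present marker contributes a cassette of
#' forward primer, random spacer and reverse-complemented reverse primer,
#' so template-based profiling recovers the same profile.
#'
#' @param class_name A signature class name, or `"none"`.
#' @param signatures Signature list as from [read_signatures()].
#' @param panel STS panel data frame from [read_sts_panel()].
#' @param seed Integer seed.
#' @param with_template Also build the mock template and primer columns.
#' @return A list with `profile` (an `sts_profile`), `truth`
#'   (the class name), and when `with_template` is set, `panel` (with
#'   synthetic `fwd_seq`/`rev_seq` columns) and `template` (a
#'   [seq_record]).
#' @export
generate_sts_dataset <- function(class_name, signatures, panel,
                                 seed = 1L, with_template = FALSE) {
  ids <- panel$sY_id
  absent <- character(0)
  if (!identical(class_name, "none")) {
    cls <- vapply(signatures, `[[`, "", "class")
    k <- match(class_name, cls)
    if (is.na(k)) stop("unknown deletion class: '", class_name, "'")
    absent <- signatures[[k]]$absent
  }
  status <- ifelse(ids %in% absent, "absent", "present")
  names(status) <- ids
  profile <- profile_sts(status, panel)
  out <- list(profile = profile, truth = class_name)
  if (with_template) {
    with_local_seed(seed, {
      bases <- c("A", "C", "G", "T")
      rnd <- function(n) paste(sample(bases, n, replace = TRUE),
                               collapse = "")
      panel$fwd_seq <- vapply(ids, function(i) rnd(20L), "")
      panel$rev_seq <- vapply(ids, function(i) rnd(20L), "")
      cassettes <- vapply(seq_along(ids), function(i) {
        if (status[i] == "absent") return("")
        paste0(panel$fwd_seq[i], rnd(60L),
               reverse_complement(panel$rev_seq[i]))
      }, "")
      template <- seq_record(
        sprintf("synthetic_msy_mock_%s_seed%d", class_name, seed),
        paste0(paste(cassettes, collapse = ""), rnd(40L)),
        "synthetic MSY mock template (not genomic sequence)")
      out$panel <- panel
      out$template <- template
    })
  }
  out
}
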