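# Orchestration: run every analysis stage over a set of inputs, collect the
# tables into one report, and write the report as TSVs plus JSON. A failure
# in one stage is recorded and does not abort independent stages.

stage_log <- function(...) message("[hoxspec] ", sprintf(...))

run_stage <- function(report, name, expr) {
  stage_log("stage %s", name)
  result <- tryCatch(expr, error = function(e) {
    stage_log("stage %s FAILED: %s", name, conditionMessage(e))
    structure(conditionMessage(e), class = "stage_error")
  })
  if (inherits(result, "stage_error")) {
    report$errors[[name]] <- as.character(result)
  } else {
    report[[name]] <- result
  }
  report
}

#' Run the full comparative binding-specificity pipeline
#'
#' Executes, in dependency order: pairwise reciprocal-overlap analysis of
#' all peak sets; common/specific partitions against a reference
#' (accessibility) set; binned-track Pearson correlations; differential
#' ranking of each factor's peaks against the reference track; k-mer
#' fingerprints against the TSS-upstream background; motif-set enrichment
#' and per-peak match density; chromatin-state prevalence; and
#' summit-centred minor-groove-width and GC profiles. Stages whose inputs
#' are absent are skipped with a logged reason; a failing stage is recorded
#' in `$errors` without aborting the rest.
#'
#' @param inputs A [generate_scenario()] bundle, or any list with elements
#'   `genome`, `peaks` (named list of [peak_set()]), `tracks` (named list of
#'   [signal_track()]), and optionally `states`, `tss`.
#' @param config An [analysis_config()].
#' @param pwms Named list of `pwm` objects (default: the bundled synthetic
#'   Hox-like PWM).
#' @param panels Named list of [kmer_panel()]s (default: the bundled
#'   5-mer and 8-mer fingerprint panels).
#' @param shape_table A `shape_table` for minor-groove-width profiles;
#'   `NULL` skips the MGW profile stage.
#' @param reference Name of the accessibility-like peak set/track used for
#'   partitions and differential ranking (default `"DNase"` when present).
#' @return A list of class `pipeline_report`; see [write_report()].
#' @export
run_pipeline <- function(inputs, config = analysis_config(),
                         pwms = list(hox_like = hox_like_pwm()),
                         panels = list(hox_5mers = hox_monomer_panel(),
                                       exdhox_8mers = exd_hox_dimer_panel()),
                         shape_table = NULL,
                         reference = if ("DNase" %in% names(inputs$peaks))
                           "DNase" else NULL) {
  if (is.null(inputs$peaks) || !length(inputs$peaks)) {
    abort("`inputs$peaks` must hold at least one peak set")
  }
  if (is.null(inputs$genome)) abort("`inputs$genome` is required")
  set.seed(config$random_seed)
  f <- config$reciprocal_overlap_fraction
  peaks <- inputs$peaks
  tracks <- inputs$tracks %||% list()
  report <- list(errors = list())

  report <- run_stage(report, "overlaps", {
    pairs <- utils::combn(names(peaks), 2, simplify = FALSE)
    dplyr::bind_rows(lapply(pairs, function(p) {
      tidy(reciprocal_overlap(peaks[[p[1]]], peaks[[p[2]]], f))
    }))
  })

  partitions <- NULL
  if (!is.null(reference)) {
    report <- run_stage(report, "partitions", {
      others <- setdiff(names(peaks), reference)
      parts <- lapply(others, function(nm) {
        partition_by_reference(peaks[[nm]], peaks[[reference]], f)
      })
      names(parts) <- others
      parts
    })
    partitions <- report$partitions
    report <- run_stage(report, "partition_summary", {
      dplyr::bind_rows(purrr::imap(partitions, function(p, nm) {
        tibble(set = nm, reference = reference,
               n_common = nrow(p$common), n_specific = nrow(p$specific),
               pct_common = 100 * nrow(p$common) /
                 (nrow(p$common) + nrow(p$specific)))
      }))
    })
  } else {
    stage_log("no reference set; skipping partitions")
  }

  if (length(tracks) >= 2) {
    report <- run_stage(report, "correlations", {
      binned <- lapply(tracks, bin_track, genome = inputs$genome,
                       w = config$window_size_bp)
      pairs <- utils::combn(names(tracks), 2, simplify = FALSE)
      dplyr::bind_rows(lapply(pairs, function(p) {
        profile_correlation(binned[[p[1]]], binned[[p[2]]])
      }))
    })
  } else {
    stage_log("fewer than two tracks; skipping correlations")
  }

  if (!is.null(reference) && reference %in% names(tracks)) {
    report <- run_stage(report, "rankings", {
      factors <- intersect(setdiff(names(peaks), reference), names(tracks))
      rks <- lapply(factors, function(nm) {
        differential_rank(peaks[[nm]], tracks[[nm]], tracks[[reference]],
                          c = config$pseudocount,
                          n_top = min(1000L, nrow(peaks[[nm]])))
      })
      names(rks) <- factors
      rks
    })
    report <- run_stage(report, "medians", {
      dplyr::bind_rows(lapply(names(peaks), function(nm) {
        glance(peak_median_signal(peaks[[nm]], tracks[[reference]]))
      }))
    })
  }

  bg <- NULL
  if (!is.null(inputs$tss)) {
    report <- run_stage(report, "background", {
      build_tss_background(inputs$tss, inputs$genome,
                           span = config$profile_span_bp)
    })
    bg <- report$background
  } else {
    stage_log("no TSS set; skipping background-dependent stages")
  }

  if (!is.null(bg) && length(panels)) {
    report <- run_stage(report, "fingerprints", {
      dplyr::bind_rows(purrr::imap(panels, function(panel, pnm) {
        dplyr::bind_rows(lapply(names(peaks), function(nm) {
          fp <- fingerprint(extract_peak_sequences(peaks[[nm]],
                                                   inputs$genome),
                            bg, panel)
          dplyr::mutate(as_tibble(fp), set = nm, panel = pnm,
                        .before = 1)
        }))
      }))
    })
  }

  if (!is.null(bg) && length(pwms)) {
    report <- run_stage(report, "motif_enrichment", {
      dplyr::bind_rows(lapply(names(peaks), function(nm) {
        enr <- motif_set_enrichment(
          extract_peak_sequences(peaks[[nm]], inputs$genome), bg, pwms,
          p_match = config$pwm_match_pvalue)
        dplyr::mutate(as_tibble(enr), set = nm, .before = 1)
      }))
    })
    report <- run_stage(report, "densities", {
      pwm <- pwms[[1]]
      cutoff <- score_threshold(pwm, config$pwm_match_pvalue)
      dens <- lapply(names(peaks), function(nm) {
        seqs <- extract_peak_sequences(peaks[[nm]], inputs$genome)
        match_density(peaks[[nm]], scan_pwm(seqs, pwm, cutoff))
      })
      names(dens) <- names(peaks)
      dplyr::bind_rows(lapply(dens, glance))
    })
  }

  if (!is.null(inputs$states)) {
    report <- run_stage(report, "state_prevalence", {
      tabs <- lapply(names(peaks), function(nm) {
        dplyr::mutate(as_tibble(state_prevalence(peaks[[nm]],
                                                 inputs$states)),
                      set = nm, .before = 1)
      })
      genome_tab <- dplyr::mutate(
        as_tibble(genome_state_composition(inputs$states,
                                           genome_lengths(inputs$genome))),
        set = "genome", .before = 1)
      dplyr::bind_rows(c(tabs, list(genome_tab)))
    })
  } else {
    stage_log("no state annotation; skipping state prevalence")
  }

  report <- run_stage(report, "gc_profiles", {
    dplyr::bind_rows(lapply(names(peaks), function(nm) {
      pr <- summit_profile(peaks[[nm]], inputs$genome, mode = "gc",
                           span = config$profile_span_bp,
                           window = config$smooth_window_bp,
                           step = config$smooth_step_bp)
      dplyr::mutate(as_tibble(pr), set = nm, mode = "gc", .before = 1)
    }))
  })
  if (!is.null(shape_table)) {
    report <- run_stage(report, "mgw_profiles", {
      dplyr::bind_rows(lapply(names(peaks), function(nm) {
        pr <- summit_profile(peaks[[nm]], inputs$genome, mode = "mgw",
                             table = shape_table,
                             span = config$profile_span_bp,
                             window = config$smooth_window_bp,
                             step = config$smooth_step_bp)
        dplyr::mutate(as_tibble(pr), set = nm, mode = "mgw", .before = 1)
      }))
    })
  } else {
    stage_log("no shape table supplied; skipping minor-groove-width profiles")
  }

  report$provenance <- list(
    peak_sets = names(peaks),
    tracks = names(tracks),
    reference = reference,
    config = unclass(config),
    version = as.character(packageVersion("hoxspec")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  tabs <- names(x)[vapply(x, is.data.frame, logical(1))]
  cat("# pipeline_report with tables:", paste(tabs, collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("# failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' One TSV per result table plus `report.json` holding every table and the
#' provenance block. Reports are deterministic for fixed inputs and seed up
#' to the provenance timestamp.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- names(report)[vapply(report, is.data.frame, logical(1))]
  for (nm in tabs) {
    utils::write.table(as_tibble(report[[nm]]),
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- c(lapply(setNames(tabs, tabs), function(nm)
    as.data.frame(report[[nm]])),
    list(errors = report$errors, provenance = report$provenance))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE,
                       auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}
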