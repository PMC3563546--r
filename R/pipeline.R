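#' Run the full processing pipeline
#'
#' Reads the measurement table, runs the configured pre-correction data
#' checks, assembles fragments, applies the corrections in the configured
#' order, computes the post-correction average-labeling summary and replicate
#' statistics, and writes the configured outputs.  If any data check raises a
#' flag the pipeline terminates before correction and writes the feedback
#' mask so the flagged cells can be reviewed against the data — unless
#' `force = TRUE`, which continues regardless (mirroring a command-line
#' override of regular operation).
#'
#' @param config A [run_config()] or the path to a configuration file.
#' @param data A measurement table (`mdv_raw`), a path to one, or `NULL` to
#'   use the configuration's `data_file`.
#' @param out_dir Output directory; `NULL` suppresses all file output.
#' @param force Continue past data-check flags.
#' @param fragments Fragment library; defaults to the configuration's
#'   `fragment_file` or the built-in [fragment_library()].
#' @param rt Retention-time table (or path), if the retention-time check is
#'   configured.
#' @param obm OBM tibble (or path), if the `obm` correction is configured.
#' @param table Isotope table; defaults to the configuration's
#'   `isotope_file` or [default_isotope_table()].
#' @return A list of class `mdvflux_run` with components `status`
#'   (`"clean"`, `"flags"` or `"flags-forced"`), `mask`, `assembly_feedback`,
#'   `correction` (see [apply_corrections()]), `dataset` (corrected),
#'   `labeling`, `stats`, `groups` and `files` (paths written).
#' @export
run_pipeline <- function(config, data = NULL, out_dir = NULL, force = FALSE,
                         fragments = NULL, rt = NULL, obm = NULL,
                         table = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg_file <- function(key) config$files[[key]]

  if (is.null(data)) data <- cfg_file("data")
  if (is.null(data)) stop("no measurement data supplied", call. = FALSE)
  raw <- if (is.character(data)) read_measurement_table(data) else data

  if (is.null(fragments)) {
    fragments <- if (!is.null(cfg_file("fragments"))) {
      read_fragment_library(cfg_file("fragments"))
    } else {
      fragment_library()
    }
  }
  if (is.null(table)) {
    table <- if (!is.null(cfg_file("isotopes"))) {
      read_isotope_table(cfg_file("isotopes"))
    } else {
      default_isotope_table()
    }
  }
  if ("obm" %in% config$corrections && is.null(obm)) {
    if (is.null(cfg_file("obm"))) {
      stop("'obm' correction configured but no OBM table supplied",
           call. = FALSE)
    }
    obm <- read_obm_table(cfg_file("obm"))
  }
  if (is.character(obm)) obm <- read_obm_table(obm)
  if ("retention-time" %in% config$checks && is.null(rt)) {
    if (!is.null(cfg_file("rt"))) rt <- cfg_file("rt")
  }
  if (is.character(rt)) rt <- read_measurement_table(rt)

  rep_names <- config$replicate_names
  if (is.null(rep_names) && !is.null(cfg_file("replicate_names"))) {
    rep_names <- read_replicate_names(cfg_file("replicate_names"))
  }
  groups <- replicate_grouping(chromatograms(raw), config$replicate_groups,
                               rep_names)

  files <- character()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  # ---- pre-correction data checks -------------------------------------
  masks <- list()
  if ("missing" %in% config$checks) masks <- c(masks, list(check_missing(raw)))
  if ("intensity" %in% config$checks) {
    masks <- c(masks, list(check_intensity_bounds(raw, config$intensity_min,
                                                  config$intensity_max)))
  }
  if ("retention-time" %in% config$checks && !is.null(rt)) {
    masks <- c(masks, list(check_retention_times(rt, config$rt_sd_multiplier,
                                                 config$rt_pooled)))
  }
  mask <- if (length(masks)) combine_masks(masks) else NULL
  flagged <- !is.null(mask) && any_flags(mask)
  if (flagged && !is.null(out_dir)) {
    p <- file.path(out_dir, "feedback_mask.tsv")
    write_feedback_mask(mask, p)
    files <- c(files, p)
  }
  if (flagged && !force) {
    return(structure(list(status = "flags", mask = mask,
                          assembly_feedback = NULL, correction = NULL,
                          dataset = NULL, labeling = NULL, stats = NULL,
                          groups = groups, files = files),
                     class = "mdvflux_run"))
  }

  # ---- assembly and correction ----------------------------------------
  asm <- assemble_fragments(raw, fragments,
                            leading_boundary = config$leading_boundary,
                            trailing_boundary = config$trailing_boundary)
  corr <- apply_corrections(asm$dataset, config, obm = obm, table = table)
  labeling <- summarize_labeling(corr$dataset, groups)
  stats <- replicate_stats(corr$dataset, groups)

  # ---- outputs --------------------------------------------------------
  if (!is.null(out_dir)) {
    if ("tsv" %in% config$output_formats) {
      p <- file.path(out_dir, "corrected.tsv")
      write_measurement_table(dataset_as_table(corr$dataset), p)
      files <- c(files, p)
      p <- file.path(out_dir, "replicate_stats.tsv")
      utils::write.table(stats, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, p)
      files <- c(files, write_labeling_summary(labeling, out_dir))
    }
    if ("ftbl-ms" %in% config$output_formats) {
      files <- c(files, write_ftbl_ms(stats, out_dir, "mass-spectrometry",
                                      model_file = cfg_file("ftbl_model")))
    }
    if ("ftbl-label" %in% config$output_formats) {
      files <- c(files, write_ftbl_ms(stats, out_dir, "label-measurements"))
    }
    if ("openflux" %in% config$output_formats) {
      files <- c(files, write_openflux_csv(stats, out_dir))
    }
  }
  structure(list(status = if (flagged) "flags-forced" else "clean",
                 mask = mask, assembly_feedback = asm$feedback,
                 correction = corr, dataset = corr$dataset,
                 labeling = labeling, stats = stats, groups = groups,
                 files = unname(files)),
            class = "mdvflux_run")
}

#' One-line summary of a pipeline run
#'
#' @param x An `mdvflux_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble: `status`, number of fragments, chromatograms
#'   and flagged cells, mean average labeling and files written.
#' @export
glance.mdvflux_run <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    n_fragments = if (is.null(x$dataset)) 0L else
      length(unique(x$dataset$fragment)),
    n_chromatograms = if (is.null(x$dataset)) 0L else
      length(unique(x$dataset$chromatogram)),
    n_flagged = if (is.null(x$mask)) 0L else nrow(qc_flags(x$mask)),
    mean_labeling = if (is.null(x$labeling)) NA_real_ else
      x$labeling$overall$labeling,
    n_files = length(x$files)
  )
}

#' @export
print.mdvflux_run <- function(x, ...) {
  cat("mdvflux pipeline run: status =", x$status, "\n")
  print(glance(x))
  invisible(x)
}
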