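#' Replicate statistics of a corrected dataset
#'
#' Aggregates corrected MDV fractions over each replicate group: per mass
#' weight the arithmetic mean and the sample (n - 1) standard deviation over
#' the group's chromatograms.  For a group with a single chromatogram a
#' default deviation of five percent (0.05) is returned at every mass, so
#' that downstream flux software requiring an error value always receives
#' one.
#'
#' @param dataset A corrected `mdv_dataset` (fractions).
#' @param groups Tibble `chromatogram` / `group` (see
#'   [replicate_grouping()]); replicates must occupy consecutive columns of
#'   the original table in the order the group sizes were configured.
#' @return A tibble with one row per group, fragment and mass weight:
#'   columns `group`, `analyte`, `fragment`, `num_c`, `weight`, `mean`, `sd`,
#'   `n`.  Mean vectors sum to 1 within each group and fragment.
#' @export
replicate_stats <- function(dataset, groups = NULL) {
  if (is.null(groups)) {
    groups <- replicate_grouping(unique(dataset$chromatogram))
  }
  long <- tibble::as_tibble(dataset) |>
    dplyr::transmute(.data$analyte, .data$fragment, .data$num_c,
                     .data$chromatogram,
                     weight = purrr::map(.data$values, ~ seq_along(.x) - 1L),
                     value = .data$values) |>
    tidyr::unnest(c("weight", "value")) |>
    dplyr::left_join(groups, by = "chromatogram")
  long |>
    dplyr::group_by(.data$group, .data$analyte, .data$fragment, .data$num_c,
                    .data$weight) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() == 1L) 0.05 else stats::sd(.data$value),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$group, .data$analyte, .data$fragment, .data$weight)
}

ftbl_section_name <- function(section) {
  switch(section,
         "mass-spectrometry" = "MASS_SPECTROMETRY",
         "label-measurements" = "LABEL_MEASUREMENTS",
         stop("unknown FTBL section '", section, "'", call. = FALSE))
}

# FTBL table rows (tab-indented) for one replicate group.
ftbl_rows <- function(stats_group, section) {
  fmt <- function(x) sprintf("%.6g", x)
  rows <- character()
  frs <- dplyr::distinct(stats_group, .data$analyte, .data$fragment,
                         .data$num_c)
  for (i in seq_len(nrow(frs))) {
    sub <- stats_group[stats_group$fragment == frs$fragment[i], ]
    sub <- sub[order(sub$weight), ]
    if (section == "mass-spectrometry") {
      positions <- paste(seq_len(frs$num_c[i]), collapse = ",")
      for (k in seq_len(nrow(sub))) {
        lead <- if (k == 1L) c(frs$analyte[i], positions) else c("", "")
        rows <- c(rows, paste(c("", lead, sub$weight[k], fmt(sub$mean[k]),
                                fmt(sub$sd[k])), collapse = "\t"))
      }
    } else {
      for (k in seq_len(nrow(sub))) {
        lead <- if (k == 1L) frs$analyte[i] else ""
        rows <- c(rows, paste(c("", lead, i, fmt(sub$mean[k]),
                                fmt(sub$sd[k]),
                                paste0("#M", sub$weight[k])),
                              collapse = "\t"))
      }
    }
  }
  rows
}

#' Write FTBL measurement sections for 13CFLUX
#'
#' Writes the replicate means and deviations as the `MASS_SPECTROMETRY` or
#' `LABEL_MEASUREMENTS` section of an FTBL file, one file per replicate
#' group, named after the group (generic `group_XX` names are used when no
#' identifier file was supplied).  Alternatively the rows can be injected
#' into an existing FTBL model file: the new rows are appended to the end of
#' the existing target section and every other line is preserved
#' byte-identically.
#'
#' The FTBL dialect is tab-indented: a section header at column 0, a
#' tab-indented column-header row, and tab-indented data rows in which
#' continuation rows of a fragment leave the name columns empty.  Column
#' layout: `META_NAME  FRAGMENT  WEIGHT  VALUE  DEVIATION` for mass
#' spectrometry; `META_NAME  CUM_GROUP  VALUE  DEVIATION  CUM_CONSTRAINTS`
#' for label measurements.  Values are written as fractions (downstream
#' tools expect fractions, not percent).
#'
#' @param stats Replicate statistics from [replicate_stats()].
#' @param dir Output directory (created if needed).
#' @param section `"mass-spectrometry"` or `"label-measurements"`.
#' @param model_file Optional path to an existing FTBL model containing the
#'   target section; rows are injected instead of writing standalone files.
#' @return Paths of the written files, invisibly.
#' @export
write_ftbl_ms <- function(stats, dir,
                          section = c("mass-spectrometry",
                                      "label-measurements"),
                          model_file = NULL) {
  section <- match.arg(section)
  sec_name <- ftbl_section_name(section)
  col_header <- if (section == "mass-spectrometry") {
    "\tMETA_NAME\tFRAGMENT\tWEIGHT\tVALUE\tDEVIATION"
  } else {
    "\tMETA_NAME\tCUM_GROUP\tVALUE\tDEVIATION\tCUM_CONSTRAINTS"
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(stats) == 0L) {
    warning("no replicate statistics to write", call. = FALSE)
    return(invisible(character()))
  }
  model_lines <- NULL
  if (!is.null(model_file)) {
    model_lines <- readLines(model_file)
    if (!any(trimws(model_lines) == sec_name)) {
      stop("model file '", model_file, "' has no ", sec_name, " section",
           call. = FALSE)
    }
  }
  paths <- character()
  for (g in unique(stats$group)) {
    rows <- ftbl_rows(stats[stats$group == g, ], section)
    if (is.null(model_lines)) {
      path <- file.path(dir, paste0(g, ".ftbl"))
      writeLines(c(sec_name, col_header, rows), path)
    } else {
      path <- file.path(dir, paste0(g, "_model.ftbl"))
      start <- which(trimws(model_lines) == sec_name)[1]
      after <- start
      n <- length(model_lines)
      # the section runs until the next column-0 section header (or EOF)
      while (after < n && (startsWith(model_lines[after + 1L], "\t") ||
                           !nzchar(trimws(model_lines[after + 1L])))) {
        after <- after + 1L
      }
      # append after the last non-blank line of the section
      while (after > start && !nzchar(trimws(model_lines[after]))) {
        after <- after - 1L
      }
      writeLines(c(model_lines[seq_len(after)], rows,
                   if (after < n) model_lines[(after + 1L):n]), path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write OpenFLUX measurement CSV files
#'
#' One comma-separated file per replicate group with one row per fragment
#' and mass weight: columns `fragment`, `weight`, `mean`, `sd` (fractions).
#' This flat dialect is documented here because OpenFLUX accepts
#' spreadsheet-shaped measurement listings; adjust downstream if a different
#' column order is required.
#'
#' @param stats Replicate statistics from [replicate_stats()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_openflux_csv <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(stats) == 0L) {
    warning("no replicate statistics to write", call. = FALSE)
    return(invisible(character()))
  }
  paths <- character()
  for (g in unique(stats$group)) {
    sub <- stats[stats$group == g, c("fragment", "weight", "mean", "sd")]
    path <- file.path(dir, paste0(g, "_openflux.csv"))
    utils::write.table(sub, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Corrected dataset back in matrix layout
#'
#' Rebuilds the analyte/mass matrix layout from a corrected dataset so it can
#' be written with [write_measurement_table()].  Fractions are scaled to
#' percent for human-readable output (`percent = TRUE`, the default).
#'
#' @param dataset A corrected `mdv_dataset` (boundaries already stripped).
#' @param percent Scale fractions to percentages of 100%.
#' @return An `mdv_raw` tibble.
#' @export
dataset_as_table <- function(dataset, percent = TRUE) {
  chrom <- unique(dataset$chromatogram)
  frs <- dplyr::distinct(tibble::as_tibble(dataset), .data$analyte,
                         .data$fragment, .data$num_c, .data$base_mass)
  rows <- purrr::map_dfr(seq_len(nrow(frs)), function(i) {
    fr <- frs[i, ]
    out <- tibble::tibble(analyte = fr$analyte,
                          mass = fr$base_mass + 0:fr$num_c)
    for (cc in chrom) {
      v <- dataset$values[dataset$fragment == fr$fragment &
                            dataset$chromatogram == cc]
      out[[cc]] <- if (length(v) == 1L) {
        if (percent) 100 * v[[1]] else v[[1]]
      } else {
        NA_real_
      }
    }
    out
  })
  new_mdv_raw(rows, title = "corrected data")
}
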