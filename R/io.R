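#' Read a measurement matrix from TSV
#'
#' Reads the standard tab-separated matrix dialect used throughout the
#' pipeline: the first column holds analyte identifiers, the second the
#' nominal mass of each mass isotopomer, and the remaining columns one
#' measurement per chromatogram.  The first row may hold an optional title
#' (detected when all its cells beyond the second are empty); the following
#' row holds the chromatogram identifiers.  Each file carries a single type
#' of data (intensities, retention times, ...).
#'
#' Blank cells are preserved as missing values (`NA`); non-numeric cells also
#' become `NA` and are caught by [check_missing()].
#'
#' @param path Path to a TSV file.
#' @return A tibble of class `mdv_raw` with columns `analyte`, `mass` and one
#'   numeric column per chromatogram; the optional title is kept in the
#'   `"title"` attribute.
#' @export
read_measurement_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) < 2L) {
    stop("measurement file '", path, "' needs at least a header and one row",
         call. = FALSE)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  first <- cells[[1]]
  has_title <- length(first) <= 2L || all(first[-(1:2)] == "")
  title <- if (has_title) first[1] else ""
  id_row <- cells[[if (has_title) 2L else 1L]]
  chrom <- id_row[-(1:2)]
  chrom <- chrom[nzchar(chrom)]
  if (length(chrom) == 0L) {
    stop("no chromatogram identifiers found in '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop("duplicated chromatogram identifiers in '", path, "'", call. = FALSE)
  }
  body <- cells[-seq_len(if (has_title) 2L else 1L)]
  ncol_expect <- length(chrom) + 2L
  rows <- purrr::imap(body, function(cl, i) {
    # trailing empty cells may be dropped by strsplit; pad them back
    if (length(cl) < ncol_expect) cl <- c(cl, rep("", ncol_expect - length(cl)))
    if (length(cl) > ncol_expect) {
      stop("row ", i, " of '", path, "' has ", length(cl) - 2L,
           " values but ", length(chrom), " chromatograms", call. = FALSE)
    }
    cl
  })
  mat <- do.call(rbind, rows)
  vals <- suppressWarnings(
    matrix(as.numeric(mat[, -(1:2), drop = FALSE]), nrow = nrow(mat))
  )
  colnames(vals) <- chrom
  mass <- suppressWarnings(as.numeric(mat[, 2]))
  if (anyNA(mass)) {
    stop("non-numeric mass in row ", which(is.na(mass))[1], " of '", path, "'",
         call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  out <- dplyr::bind_cols(
    tibble::tibble(analyte = mat[, 1], mass = as.integer(mass)), out
  )
  new_mdv_raw(out, title = title)
}

new_mdv_raw <- function(tbl, title = "") {
  attr(tbl, "title") <- title
  class(tbl) <- unique(c("mdv_raw", class(tbl)))
  tbl
}

#' @rdname read_measurement_table
#' @param x An `mdv_raw` table (or a feedback mask of the same shape).
#' @export
chromatograms <- function(x) setdiff(names(x), c("analyte", "mass"))

#' Write a measurement matrix (or feedback mask) to TSV
#'
#' Writes the same matrix dialect read by [read_measurement_table()]; a
#' read-after-write round trip reproduces the table (numeric formatting at
#' 15 significant digits).  Missing values become empty cells.  Feedback
#' masks from the data checks use the identical layout so the flags can be
#' overlaid cell-by-cell on the measurements in any spreadsheet.
#'
#' @param x An `mdv_raw` tibble or `qc_mask`.
#' @param path Output path.
#' @param title Optional title row; defaults to the table's own title.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(x, path, title = attr(x, "title")) {
  chrom <- chromatograms(x)
  fmt_cell <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", sprintf("%.15g", v))
    else ifelse(is.na(v), "", as.character(v))
  }
  body <- vapply(seq_len(nrow(x)), function(i) {
    cells <- c(x$analyte[i], fmt_cell(x$mass[i]),
               vapply(chrom, function(cc) fmt_cell(x[[cc]][i]), ""))
    paste(cells, collapse = "\t")
  }, "")
  header <- paste(c("", "", chrom), collapse = "\t")
  lines <- c(if (!is.null(title) && nzchar(title)) title, header, body)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_measurement_table
#' @param mask A `qc_mask` produced by the data checks.
#' @export
write_feedback_mask <- function(mask, path) {
  write_measurement_table(mask, path)
}

#' Build a run configuration
#'
#' Collects every processing option in one object: which corrections to apply
#' and in which order, which pre-correction data checks to run, detector
#' thresholds, boundary-mass counts, replicate grouping and output formats.
#' Corrections are applied exactly in the order given — the order matters for
#' the original-biomass correction (see the package vignette).
#'
#' @param corrections Character vector, subset of
#'   `c("proton-loss", "proton-gain", "na", "obm")`, applied in order.  Empty
#'   means: normalize only.
#' @param checks Subset of `c("missing", "intensity", "retention-time")`.
#' @param intensity_min,intensity_max Linear detector range (ion counts); any
#'   measurement outside is flagged.
#' @param rt_sd_multiplier Retention-time window half-width in standard
#'   deviations.
#' @param rt_pooled If `TRUE`, retention-time statistics are pooled over all
#'   fragments and chromatograms; default computes them per fragment across
#'   chromatograms.
#' @param leading_boundary,trailing_boundary Number of boundary masses below
#'   M+0 / above M+numC present for every fragment.
#' @param replicate_groups Integer vector of consecutive replicate-group
#'   sizes (columns of the measurement table, in order); `NULL` treats every
#'   chromatogram as its own group.
#' @param replicate_names Optional character vector of group identifiers.
#' @param tracer_element Tracer element symbol (default `"C"`).
#' @param output_formats Subset of
#'   `c("tsv", "ftbl-ms", "ftbl-label", "openflux")`.
#' @param files Named list of companion file paths (`data`, `rt`, `obm`,
#'   `replicate_names`, `fragments`, `isotopes`, `ftbl_model`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(corrections = character(),
                       checks = "missing",
                       intensity_min = 0, intensity_max = Inf,
                       rt_sd_multiplier = 3, rt_pooled = FALSE,
                       leading_boundary = 0L, trailing_boundary = 0L,
                       replicate_groups = NULL, replicate_names = NULL,
                       tracer_element = "C",
                       output_formats = "tsv",
                       files = list()) {
  known_corr <- c("proton-loss", "proton-gain", "na", "obm")
  known_checks <- c("missing", "intensity", "retention-time")
  known_out <- c("tsv", "ftbl-ms", "ftbl-label", "openflux")
  if (length(corrections) && !all(corrections %in% known_corr)) {
    stop("unknown correction(s): ",
         paste(setdiff(corrections, known_corr), collapse = ", "),
         call. = FALSE)
  }
  if (length(checks) && !all(checks %in% known_checks)) {
    stop("unknown check(s): ",
         paste(setdiff(checks, known_checks), collapse = ", "), call. = FALSE)
  }
  if (length(output_formats) && !all(output_formats %in% known_out)) {
    stop("unknown output format(s): ",
         paste(setdiff(output_formats, known_out), collapse = ", "),
         call. = FALSE)
  }
  if (leading_boundary < 0L || trailing_boundary < 0L) {
    stop("boundary counts must be non-negative", call. = FALSE)
  }
  structure(
    list(corrections = corrections, checks = checks,
         intensity_min = intensity_min, intensity_max = intensity_max,
         rt_sd_multiplier = rt_sd_multiplier, rt_pooled = rt_pooled,
         leading_boundary = as.integer(leading_boundary),
         trailing_boundary = as.integer(trailing_boundary),
         replicate_groups = replicate_groups,
         replicate_names = replicate_names,
         tracer_element = tracer_element,
         output_formats = output_formats, files = files),
    class = "run_config"
  )
}

#' Read a run configuration from a key = value file
#'
#' Parses a flat configuration file of `key = value` lines (`#` starts a
#' comment).  List-valued keys take comma-separated values.  Recognised keys:
#' `corrections` (mandatory; may be empty), `checks`, `intensity_min`,
#' `intensity_max`, `rt_sd_multiplier`, `rt_pooled`, `leading_boundary`,
#' `trailing_boundary`, `replicate_groups`, `tracer_element`,
#' `output_formats`, and the companion-file keys `data_file`, `rt_file`,
#' `obm_file`, `replicate_names_file`, `fragment_file`, `isotope_file`,
#' `ftbl_model_file`.  Unknown keys produce a warning, not an error, to
#' tolerate configuration dialect drift.
#'
#' @param path Path to the configuration file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_.-]+)[[:space:]]*=(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) {
    stop("cannot parse configuration line: '", lines[bad][1], "'",
         call. = FALSE)
  }
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  conf <- stats::setNames(as.list(vals), keys)

  split_list <- function(v) {
    if (is.null(v) || !nzchar(v)) character() else trimws(strsplit(v, ",")[[1]])
  }
  file_keys <- c(data_file = "data", rt_file = "rt", obm_file = "obm",
                 replicate_names_file = "replicate_names",
                 fragment_file = "fragments", isotope_file = "isotopes",
                 ftbl_model_file = "ftbl_model")
  known <- c("corrections", "checks", "intensity_min", "intensity_max",
             "rt_sd_multiplier", "rt_pooled", "leading_boundary",
             "trailing_boundary", "replicate_groups", "tracer_element",
             "output_formats", names(file_keys))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!"corrections" %in% keys) {
    stop("configuration is missing the mandatory key 'corrections' ",
         "(an empty value means: normalize only)", call. = FALSE)
  }
  files <- list()
  for (k in names(file_keys)) {
    if (!is.null(conf[[k]]) && nzchar(conf[[k]])) {
      files[[file_keys[[k]]]] <- conf[[k]]
    }
  }
  num_or <- function(key, default) {
    if (is.null(conf[[key]])) default else as.numeric(conf[[key]])
  }
  run_config(
    corrections = split_list(conf$corrections),
    checks = if (is.null(conf$checks)) "missing" else split_list(conf$checks),
    intensity_min = num_or("intensity_min", 0),
    intensity_max = num_or("intensity_max", Inf),
    rt_sd_multiplier = num_or("rt_sd_multiplier", 3),
    rt_pooled = isTRUE(tolower(conf$rt_pooled %||% "false") %in%
                         c("true", "yes", "1")),
    leading_boundary = num_or("leading_boundary", 0),
    trailing_boundary = num_or("trailing_boundary", 0),
    replicate_groups = {
      g <- split_list(conf$replicate_groups)
      if (length(g)) as.integer(g) else NULL
    },
    tracer_element = conf$tracer_element %||% "C",
    output_formats = if (is.null(conf$output_formats)) "tsv"
                     else split_list(conf$output_formats),
    files = files
  )
}

#' Read an original-biomass (OBM) table
#'
#' Reads the per-chromatogram fraction of unlabeled original biomass — the
#' biomass present before the tracer was fed — from a two-column TSV file
#' with header `chromatogram  obm`.  Fractions must lie in \[0, 1\].
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chromatogram` and `obm`.
#' @export
read_obm_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("chromatogram", "obm") %in% names(raw))) {
    stop("OBM file needs columns 'chromatogram' and 'obm'", call. = FALSE)
  }
  obm <- as.numeric(raw$obm)
  if (anyNA(obm) || any(obm < 0 | obm > 1)) {
    stop("OBM fractions must be numbers in [0, 1]", call. = FALSE)
  }
  tibble::tibble(chromatogram = as.character(raw$chromatogram), obm = obm)
}

#' Read replicate-group names
#'
#' One group identifier per line, in the order of the replicate groups.
#'
#' @param path Path to the text file.
#' @return Character vector of group names.
#' @export
read_replicate_names <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Map chromatograms to replicate groups
#'
#' Replicates occupy consecutive columns of the measurement table, in the
#' same order as the group sizes in the configuration.  With no group sizes
#' every chromatogram forms its own group.
#'
#' @param chrom Character vector of chromatogram identifiers, in table order.
#' @param group_sizes Integer vector of consecutive group sizes (must sum to
#'   `length(chrom)`), or `NULL`.
#' @param names Optional group identifiers (one per group); generic
#'   `group_XX` names are used otherwise.
#' @return A tibble with columns `chromatogram` and `group`.
#' @export
replicate_grouping <- function(chrom, group_sizes = NULL, names = NULL) {
  n <- length(chrom)
  if (is.null(group_sizes)) {
    sizes <- rep(1L, n)
  } else {
    sizes <- as.integer(group_sizes)
    if (sum(sizes) != n) {
      stop("replicate group sizes sum to ", sum(sizes), " but there are ", n,
           " chromatograms", call. = FALSE)
    }
  }
  ids <- if (!is.null(names)) {
    if (length(names) != length(sizes)) {
      stop("got ", length(names), " replicate names for ", length(sizes),
           " groups", call. = FALSE)
    }
    names
  } else {
    sprintf("group_%02d", seq_along(sizes))
  }
  tibble::tibble(chromatogram = chrom,
                 group = rep(ids, times = sizes))
}
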