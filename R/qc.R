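#' Pre-correction data checks
#'
#' Each check inspects a measurement (or retention-time) matrix and returns a
#' feedback mask of identical shape: a cell is empty (`""`) when the value is
#' fine and carries a flag code otherwise.  Written back as TSV (see
#' [write_feedback_mask()]) the mask overlays the measurement file
#' cell-by-cell, so flagged values can be reviewed directly against the data.
#' Any flagged cell aborts the pipeline before correction unless the run is
#' forced (see [run_pipeline()]).
#'
#' Flag codes: `missing`, `below-min`, `above-max`, `rt-outlier`.
#'
#' @param raw An `mdv_raw` table.
#' @return A `qc_mask` tibble of the same shape as `raw`.
#' @name data-checks
NULL

new_qc_mask <- function(raw, flags) {
  chrom <- chromatograms(raw)
  out <- tibble::tibble(analyte = raw$analyte, mass = raw$mass)
  for (k in seq_along(chrom)) out[[chrom[k]]] <- flags[, k]
  attr(out, "title") <- attr(raw, "title")
  class(out) <- unique(c("qc_mask", class(out)))
  out
}

qc_values_matrix <- function(raw) {
  chrom <- chromatograms(raw)
  m <- as.matrix(tibble::as_tibble(raw)[chrom])
  storage.mode(m) <- "double"
  m
}

#' @rdname data-checks
#' @details `check_missing()` flags empty and non-numeric cells; a cell
#'   holding text such as `"n.d."` counts as missing, never as zero.
#' @export
check_missing <- function(raw) {
  m <- qc_values_matrix(raw)
  flags <- matrix("", nrow(m), ncol(m))
  flags[is.na(m)] <- "missing"
  new_qc_mask(raw, flags)
}

#' @rdname data-checks
#' @param lo,hi Linear detector range: measurements below `lo` are flagged
#'   `below-min`, above `hi` `above-max`.  Boundary-mass rows are ordinary
#'   rows of the table and are checked too.
#' @export
check_intensity_bounds <- function(raw, lo = 0, hi = Inf) {
  m <- qc_values_matrix(raw)
  flags <- matrix("", nrow(m), ncol(m))
  flags[!is.na(m) & m < lo] <- "below-min"
  flags[!is.na(m) & m > hi] <- "above-max"
  new_qc_mask(raw, flags)
}

#' @rdname data-checks
#' @param rt An `mdv_raw` table of retention times (same layout as the
#'   measurements, one row per fragment).
#' @param k Window half-width in standard deviations; a retention time
#'   farther than `k` SD from the mean is flagged `rt-outlier`.
#' @param pooled If `FALSE` (default) the mean and SD are computed per
#'   fragment across chromatograms; if `TRUE` they are pooled over all
#'   fragments and chromatograms of the table.
#' @export
check_retention_times <- function(rt, k = 3, pooled = FALSE) {
  m <- qc_values_matrix(rt)
  flags <- matrix("", nrow(m), ncol(m))
  if (ncol(m) < 2L) {
    warning("retention-time check needs at least two chromatograms; skipped",
            call. = FALSE)
    return(new_qc_mask(rt, flags))
  }
  if (is.finite(k)) {
    if (pooled) {
      mu <- mean(m, na.rm = TRUE)
      sd_ <- stats::sd(as.vector(m), na.rm = TRUE)
      out <- !is.na(m) & abs(m - mu) > k * sd_
      flags[out] <- "rt-outlier"
    } else {
      for (i in seq_len(nrow(m))) {
        mu <- mean(m[i, ], na.rm = TRUE)
        sd_ <- stats::sd(m[i, ], na.rm = TRUE)
        if (!is.finite(sd_)) next
        out <- !is.na(m[i, ]) & abs(m[i, ] - mu) > k * sd_
        flags[i, out] <- "rt-outlier"
      }
    }
  }
  new_qc_mask(rt, flags)
}

#' Combine feedback masks
#'
#' Overlays several masks of identical shape; a cell carries all flags raised
#' for it, separated by `";"`.
#'
#' @param masks List of `qc_mask` objects of identical shape.
#' @return A single `qc_mask`.
#' @export
combine_masks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  out <- masks[[1]]
  chrom <- chromatograms(out)
  for (mk in masks[-1]) {
    stopifnot(identical(dim(mk), dim(out)))
    for (cc in chrom) {
      both <- nzchar(out[[cc]]) & nzchar(mk[[cc]])
      out[[cc]] <- ifelse(both, paste(out[[cc]], mk[[cc]], sep = ";"),
                          paste0(out[[cc]], mk[[cc]]))
    }
  }
  out
}

#' Do any cells carry a flag?
#'
#' @param mask A `qc_mask`.
#' @return `TRUE` when at least one cell is flagged.
#' @export
any_flags <- function(mask) {
  chrom <- chromatograms(mask)
  any(vapply(chrom, function(cc) any(nzchar(mask[[cc]])), TRUE))
}

#' Flagged cells in long form
#'
#' @param mask A `qc_mask`.
#' @return A tibble with one row per flagged cell: `analyte`, `mass`,
#'   `chromatogram`, `flag`.
#' @export
qc_flags <- function(mask) {
  chrom <- chromatograms(mask)
  tibble::as_tibble(mask) |>
    tidyr::pivot_longer(dplyr::all_of(chrom), names_to = "chromatogram",
                        values_to = "flag") |>
    dplyr::filter(nzchar(.data$flag))
}

#' Average labeling (fractional enrichment) of an MDV
#'
#' The mean fraction of tracer-element positions carrying label,
#' \deqn{\sum_{i=0}^{numC} i\, m_i / (numC \sum_i m_i),}
#' a number between 0 (completely unlabeled) and 1 (fully labeled).  It is
#' invariant under scaling of the MDV, and meaningful as a labeling measure
#' only after correction.  Run on corrected data from *unlabeled* control
#' samples it should be ~0; larger values reveal contamination or residual
#' correction bias.
#'
#' @param values Numeric MDV, M+0 .. M+numC.
#' @param num_c Number of tracer atoms; defaults to `length(values) - 1`.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' average_labeling(c(0.25, 0.25, 0.25, 0.25))  # 0.5
average_labeling <- function(values, num_c = length(values) - 1L) {
  stopifnot(length(values) == num_c + 1L)
  s <- sum(values)
  if (s == 0) stop("cannot compute average labeling of an all-zero MDV",
                   call. = FALSE)
  sum((seq_along(values) - 1L) * values) / (num_c * s)
}

#' Average-labeling summary of a corrected dataset
#'
#' Computes the average labeling per MDV, then aggregates it per
#' chromatogram, per replicate group and over the whole dataset (unweighted
#' means over MDVs).  Intended to be run on both labeled and unlabeled
#' samples: entries far from expectation point at contaminated MDVs,
#' analytes or chromatograms.
#'
#' @param dataset A corrected `mdv_dataset`.
#' @param groups Optional tibble `chromatogram` / `group` (see
#'   [replicate_grouping()]); defaults to one group per chromatogram.
#' @return A list of class `labeling_summary` with tibbles `per_mdv`,
#'   `per_chromatogram`, `per_group` and `overall`.
#' @export
summarize_labeling <- function(dataset, groups = NULL) {
  if (is.null(groups)) {
    groups <- replicate_grouping(unique(dataset$chromatogram))
  }
  per_mdv <- tibble::as_tibble(dataset) |>
    dplyr::mutate(labeling = purrr::map2_dbl(.data$values, .data$num_c,
                                             average_labeling)) |>
    dplyr::left_join(groups, by = "chromatogram") |>
    dplyr::select("analyte", "fragment", "chromatogram", "group", "labeling")
  per_chrom <- per_mdv |>
    dplyr::group_by(.data$chromatogram) |>
    dplyr::summarise(labeling = mean(.data$labeling), .groups = "drop")
  per_group <- per_mdv |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(labeling = mean(.data$labeling), .groups = "drop")
  overall <- tibble::tibble(labeling = mean(per_mdv$labeling))
  structure(list(per_mdv = per_mdv, per_chromatogram = per_chrom,
                 per_group = per_group, overall = overall),
            class = "labeling_summary")
}

#' @export
print.labeling_summary <- function(x, ...) {
  cat("Average-labeling summary\n")
  cat("  overall:", format(x$overall$labeling, digits = 4), "\n")
  cat("  per chromatogram:\n")
  print(x$per_chromatogram, n = 10)
  invisible(x)
}

#' Write a labeling summary to TSV files
#'
#' @param x A `labeling_summary`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_labeling_summary <- function(x, dir, prefix = "labeling") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    per_mdv = file.path(dir, paste0(prefix, "_per_mdv.tsv")),
    per_chromatogram = file.path(dir, paste0(prefix, "_per_chromatogram.tsv")),
    per_group = file.path(dir, paste0(prefix, "_per_group.tsv")),
    overall = file.path(dir, paste0(prefix, "_overall.tsv"))
  )
  for (nm in names(paths)) {
    utils::write.table(x[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
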