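#' Assemble MDVs from measurement rows
#'
#' Walks the rows of a measurement table and groups consecutive masses into
#' mass isotopomer distribution vectors.  A row whose (analyte, mass) matches
#' a library fragment's M+0 minus the leading boundary count starts a
#' fragment; the following `num_c + 1` masses (plus boundary masses) must be
#' present in consecutive order.  A mass missing in the middle of an MDV is
#' *not* assumed to be zero: the fragment is treated as incomplete, excluded
#' from correction and reported, and the out-of-order masses that follow are
#' taken as the start of a possible new fragment.  Rows that match no library
#' fragment are skipped with feedback identifying where the problem was
#' encountered.  Every input row ends up either in an MDV, in a boundary
#' vector, or in a feedback message — nothing is dropped silently.
#'
#' @param raw An `mdv_raw` measurement table from [read_measurement_table()].
#' @param library A fragment library tibble (see [fragment_library()]).
#' @param leading_boundary,trailing_boundary Number of boundary masses below
#'   M+0 / above M+numC expected for *every* fragment (all fragments must
#'   carry the same boundary counts).
#' @return A list with components
#'   \describe{
#'     \item{dataset}{a tibble of class `mdv_dataset`, one row per fragment
#'       and chromatogram, with list-columns `values` (M+0 .. M+numC),
#'       `leading` and `trailing` (boundary intensities, increasing mass);}
#'     \item{feedback}{a tibble of skipped rows with columns `row`, `analyte`,
#'       `mass`, `flag` (`"incomplete"` or `"unknown"`) and `message`.}
#'   }
#' @export
assemble_fragments <- function(raw, library = fragment_library(),
                               leading_boundary = 0L, trailing_boundary = 0L) {
  stopifnot(inherits(raw, "mdv_raw"))
  leading_boundary <- as.integer(leading_boundary)
  trailing_boundary <- as.integer(trailing_boundary)
  chrom <- chromatograms(raw)
  n <- nrow(raw)
  fb <- list()
  pieces <- list()
  i <- 1L
  while (i <= n) {
    # maximal run of consecutive masses for one analyte
    j <- i
    while (j < n && raw$analyte[j + 1L] == raw$analyte[i] &&
           raw$mass[j + 1L] == raw$mass[j] + 1L) {
      j <- j + 1L
    }
    run_len <- j - i + 1L
    hit <- library[library$analyte == raw$analyte[i] &
                     library$base_mass - leading_boundary == raw$mass[i], ,
                   drop = FALSE]
    if (nrow(hit) == 0L) {
      fb[[length(fb) + 1L]] <- tibble::tibble(
        row = i, analyte = raw$analyte[i], mass = raw$mass[i],
        flag = "unknown",
        message = paste0("no library fragment starts at analyte '",
                         raw$analyte[i], "', mass ", raw$mass[i],
                         if (leading_boundary > 0L)
                           paste0(" (leading boundary ", leading_boundary, ")")
                         else "")
      )
      i <- i + 1L
      next
    }
    frag <- hit[1L, ]
    expect_len <- frag$num_c + 1L + leading_boundary + trailing_boundary
    if (run_len < expect_len) {
      rows <- i:j
      fb[[length(fb) + 1L]] <- tibble::tibble(
        row = rows, analyte = raw$analyte[rows], mass = raw$mass[rows],
        flag = "incomplete",
        message = paste0("fragment '", frag$fragment, "' is incomplete: mass ",
                         raw$mass[i] + run_len,
                         " is missing (expected ", expect_len,
                         " consecutive masses)")
      )
      i <- j + 1L
      next
    }
    rows <- i:(i + expect_len - 1L)
    lead_idx <- seq_len(leading_boundary)
    core_idx <- leading_boundary + seq_len(frag$num_c + 1L)
    trail_idx <- leading_boundary + frag$num_c + 1L + seq_len(trailing_boundary)
    pieces[[length(pieces) + 1L]] <- purrr::map_dfr(chrom, function(cc) {
      v <- raw[[cc]][rows]
      dplyr::bind_cols(
        frag[, c("analyte", "fragment", "formula", "tracer", "num_c",
                 "base_mass")],
        tibble::tibble(chromatogram = cc,
                       values = list(v[core_idx]),
                       leading = list(v[lead_idx]),
                       trailing = list(v[trail_idx]),
                       is_fraction = FALSE)
      )
    })
    i <- i + expect_len
  }
  dataset <- if (length(pieces)) dplyr::bind_rows(pieces) else
    tibble::tibble(analyte = character(), fragment = character(),
                   formula = character(), tracer = character(),
                   num_c = integer(), base_mass = integer(),
                   chromatogram = character(), values = list(),
                   leading = list(), trailing = list(),
                   is_fraction = logical())
  class(dataset) <- unique(c("mdv_dataset", class(dataset)))
  attr(dataset, "leading_boundary") <- leading_boundary
  attr(dataset, "trailing_boundary") <- trailing_boundary
  feedback <- if (length(fb)) dplyr::bind_rows(fb) else
    tibble::tibble(row = integer(), analyte = character(), mass = integer(),
                   flag = character(), message = character())
  list(dataset = dataset, feedback = feedback)
}

#' Long (tidy) view of an MDV dataset
#'
#' @param x An `mdv_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per fragment, chromatogram and mass shift:
#'   columns `analyte`, `fragment`, `chromatogram`, `weight` (0 .. numC) and
#'   `value`.
#' @export
tidy.mdv_dataset <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::transmute(.data$analyte, .data$fragment, .data$chromatogram,
                     weight = purrr::map(.data$values, ~ seq_along(.x) - 1L),
                     value = .data$values) |>
    tidyr::unnest(c("weight", "value"))
}
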