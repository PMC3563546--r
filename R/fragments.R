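#' Define an analyte fragment
#'
#' A fragment is the measured ion of a (possibly derivatized) analyte.  Its
#' full elemental formula — metabolite backbone plus derivatization additions
#' — drives the natural-abundance correction; `num_c` backbone tracer atoms
#' fix the MDV length at `num_c + 1`; the nominal `base_mass` of M+0
#' identifies the fragment in the measurement table.
#'
#' @param analyte Analyte identifier as it appears in the measurement table.
#' @param fragment Fragment identifier (unique within the analyte).
#' @param formula Full elemental formula string, e.g. `"C11H26NO2Si2"`.
#' @param num_c Number of tracer-element atoms in the metabolite backbone.
#' @param base_mass Integer nominal m/z of the M+0 mass isotopomer.
#' @param tracer Tracer element symbol; default `"C"` for 13C experiments.
#' @return A one-row tibble with columns `analyte`, `fragment`, `formula`,
#'   `tracer`, `num_c`, `base_mass`.
#' @export
#' @examples
#' fragment_definition("Ala", "Ala_260", "C11H26NO2Si2", num_c = 3,
#'                     base_mass = 260)
fragment_definition <- function(analyte, fragment, formula, num_c, base_mass,
                                tracer = "C") {
  counts <- parse_formula(formula)
  if (!tracer %in% names(counts)) {
    stop("tracer element '", tracer, "' absent from formula '", formula, "'",
         call. = FALSE)
  }
  if (num_c < 1L) stop("num_c must be at least 1", call. = FALSE)
  if (num_c > counts[[tracer]]) {
    stop("num_c (", num_c, ") exceeds the ", tracer, " count of '", formula,
         "'", call. = FALSE)
  }
  tibble::tibble(analyte = analyte, fragment = fragment, formula = formula,
                 tracer = tracer, num_c = as.integer(num_c),
                 base_mass = as.integer(base_mass))
}

#' Built-in fragment library
#'
#' A small library of proteinogenic amino-acid fragments as measured by GC-MS
#' after trimethylsilyl (TMS) derivatization, covering the common M-57
#' fragments plus a second, shorter alanine fragment.  The formulas include
#' the derivatization atoms (Si enters the
#' correction).  Extend or replace it with [read_fragment_library()] for
#' other analytes or derivatization chemistries.
#'
#' @return A tibble of fragment definitions (see [fragment_definition()]).
#' @export
#' @examples
#' fragment_library()
fragment_library <- function() {
  dplyr::bind_rows(
    fragment_definition("Gly", "Gly_246", "C10H24NO2Si2", 2L, 246L),
    fragment_definition("Ala", "Ala_260", "C11H26NO2Si2", 3L, 260L),
    fragment_definition("Ala", "Ala_232", "C9H24NOSi2", 2L, 232L),
    fragment_definition("Ser", "Ser_390", "C14H34NO3Si3", 3L, 390L),
    fragment_definition("Val", "Val_288", "C13H30NO2Si2", 5L, 288L),
    fragment_definition("Thr", "Thr_404", "C15H36NO3Si3", 4L, 404L),
    fragment_definition("Asp", "Asp_418", "C16H36NO4Si3", 4L, 418L)
  )
}

#' Read a fragment library from TSV
#'
#' @param path TSV file with header columns `analyte`, `fragment`, `formula`,
#'   `num_c`, `base_mass` and optionally `tracer` (defaults to `"C"`).
#' @return A tibble of fragment definitions.
#' @export
read_fragment_library <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("analyte", "fragment", "formula", "num_c", "base_mass")
  if (!all(need %in% names(raw))) {
    stop("fragment library needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$tracer)) raw$tracer <- "C"
  purrr::pmap_dfr(raw[c(need, "tracer")], function(analyte, fragment, formula,
                                                   num_c, base_mass, tracer) {
    fragment_definition(analyte, fragment, formula, num_c, base_mass, tracer)
  })
}
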