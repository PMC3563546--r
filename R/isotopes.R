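#' Natural-abundance isotope table
#'
#' The default table of naturally occurring stable-isotope abundances used by
#' all corrections.  Each element carries an abundance vector over the mass
#' shifts +0, +1 and +2; isotopes heavier than +2 are ignored because their
#' natural probabilities are negligible for the fragment sizes encountered in
#' GC-MS/LC-MS labeling data.  The light-isotope fraction is the complement of
#' the listed heavy fractions.
#'
#' Shipped elements and heavy-isotope fractions:
#' \itemize{
#'   \item C: 13C 1.1\%
#'   \item H: 2H 0.0115\%
#'   \item N: 15N 0.366\%
#'   \item O: 17O 0.038\%, 18O 0.2\%
#'   \item S: 33S 0.75\%, 34S 4.2\%
#'   \item Si: 29Si 4.7\%, 30Si 3.1\%
#' }
#'
#' @return A tibble with columns `element`, `shift` (0, 1 or 2) and
#'   `abundance` (fraction in \[0, 1\]).
#' @seealso [read_isotope_table()] to override abundances from a TSV file,
#'   [isotope_vector()], [na_distribution()].
#' @export
#' @examples
#' default_isotope_table()
#' isotope_vector(default_isotope_table(), "C")
default_isotope_table <- function() {
  tab <- tibble::tribble(
    ~element, ~shift, ~abundance,
    "C",  1L, 0.011,
    "H",  1L, 0.000115,
    "N",  1L, 0.00366,
    "O",  1L, 0.00038,
    "O",  2L, 0.002,
    "S",  1L, 0.0075,
    "S",  2L, 0.042,
    "Si", 1L, 0.047,
    "Si", 2L, 0.031
  )
  complete_isotope_table(tab)
}

# Add the shift-0 (light isotope) row for each element as the complement of
# the heavy fractions, and validate ranges.
complete_isotope_table <- function(tab) {
  stopifnot(all(c("element", "shift", "abundance") %in% names(tab)))
  if (any(tab$abundance < 0 | tab$abundance > 1)) {
    stop("isotope abundances must lie in [0, 1]", call. = FALSE)
  }
  if (any(tab$shift < 0 | tab$shift > 2)) {
    stop("isotope mass shifts are restricted to +0, +1, +2", call. = FALSE)
  }
  heavy <- dplyr::filter(tab, .data$shift > 0L)
  light <- heavy |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(heavy = sum(.data$abundance), .groups = "drop") |>
    dplyr::mutate(shift = 0L, abundance = 1 - .data$heavy) |>
    dplyr::select("element", "shift", "abundance")
  given0 <- dplyr::filter(tab, .data$shift == 0L)
  light <- dplyr::filter(light, !(.data$element %in% given0$element))
  out <- dplyr::bind_rows(given0, light, heavy) |>
    dplyr::arrange(.data$element, .data$shift)
  if (any(out$abundance < 0)) {
    stop("heavy-isotope abundances exceed 1 for some element", call. = FALSE)
  }
  sums <- out |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(s = sum(.data$abundance), .groups = "drop")
  if (any(sums$s > 1 + 1e-9)) {
    stop("isotope abundance vectors must sum to at most 1", call. = FALSE)
  }
  class(out) <- c("isotope_table", class(out))
  out
}

#' Read an isotope-table override from TSV
#'
#' Reads a tab-separated file with columns `element`, `shift`, `abundance`
#' listing the heavy-isotope fractions (shifts +1 and +2; an explicit shift-0
#' row is also accepted).  The shift-0 fraction defaults to the complement.
#' This is the escape hatch for laboratories that work with more precise or
#' locally calibrated natural-abundance values.
#'
#' @param path Path to a TSV file with a header row `element  shift  abundance`.
#' @return An isotope table as from [default_isotope_table()].
#' @export
read_isotope_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("element", "shift", "abundance")
  if (!all(need %in% names(raw))) {
    stop("isotope table file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  complete_isotope_table(tibble::as_tibble(raw[need]))
}

#' Abundance vector of one element
#'
#' @param table An isotope table (see [default_isotope_table()]).
#' @param element Element symbol, e.g. `"C"` or `"Si"`.
#' @return Numeric vector of natural abundances for mass shifts +0, +1, ...
#'   (trailing zero shifts are dropped, so carbon returns length 2 and
#'   silicon length 3).
#' @export
#' @examples
#' isotope_vector(default_isotope_table(), "Si")
isotope_vector <- function(table, element) {
  rows <- table[table$element == element, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("element '", element, "' is not in the isotope table; ",
         "add it via an isotope-table override file", call. = FALSE)
  }
  v <- numeric(max(rows$shift) + 1L)
  v[rows$shift + 1L] <- rows$abundance
  # trim trailing zero shifts: an element with no heavy isotope is (1)
  v[seq_len(max(which(v > 0), 1L))]
}

# Internal: isotope table as a named list of abundance vectors.
iso_vectors <- function(table) {
  els <- unique(table$element)
  stats::setNames(lapply(els, function(e) isotope_vector(table, e)), els)
}

#' Parse a molecular formula string
#'
#' Turns a formula such as `"C11H26NO2Si2"` into a named count vector.  The
#' formula is the *full* elemental composition of the measured fragment,
#' including any derivatization additions (e.g. trimethylsilyl groups), since
#' every atom contributes natural-abundance signal.
#'
#' @param formula Formula string, element symbols with optional counts.
#' @return Named integer vector of atom counts.
#' @export
#' @examples
#' parse_formula("C11H26NO2Si2")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (length(parts) == 0L || paste(parts, collapse = "") != s) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  els <- sub("[0-9]*$", "", parts)
  cnt <- sub("^[A-Za-z]+", "", parts)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  out <- tapply(cnt, els, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Probability of one isotope-count assignment (multinomial abundance)
#'
#' Probability that, among `N` atoms of a single element, the isotopes with
#' the given natural abundances occur exactly `counts` times each:
#' \deqn{N! \prod_i p(I_i)^{f(I_i)} / f(I_i)!}
#'
#' @param counts Integer vector of occurrences per isotope (must sum to `N`,
#'   the number of atoms); aligned with `abundances`.
#' @param abundances Natural-abundance probabilities of the isotopes, same
#'   length as `counts`.
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' # one 13C among two carbons
#' multinomial_abundance(c(1, 1), c(0.989, 0.011))
multinomial_abundance <- function(counts, abundances) {
  stopifnot(length(counts) == length(abundances))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("isotope counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  exp(lfactorial(n) - sum(lfactorial(counts))) * prod(abundances^counts)
}

#' Natural-abundance mass-shift distribution of a formula
#'
#' Probability distribution of the total mass shift contributed by naturally
#' occurring heavy isotopes across all atoms of a fragment, obtained by
#' convolving each atom's truncated (+0/+1/+2) isotope vector.  Entry `k + 1`
#' is the probability that natural isotopes shift the fragment mass by `+k`.
#'
#' @param formula Named count vector (as from [parse_formula()]) or a formula
#'   string.
#' @param table Isotope table; defaults to [default_isotope_table()].
#' @param max_len Optional truncation length of the returned vector.  The
#'   leading entries are unaffected by truncation, so extending `max_len`
#'   never changes values already computed.
#' @return Numeric probability vector; sums to at most 1 (exactly 1 when the
#'   per-element vectors are complete and no truncation occurs).
#' @export
#' @examples
#' na_distribution("C3")        # a three-carbon skeleton
#' na_distribution("C2", max_len = 3)
na_distribution <- function(formula, table = default_isotope_table(),
                            max_len = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  vecs <- iso_vectors(table)
  unknown <- setdiff(names(formula), names(vecs))
  if (length(unknown) > 0L) {
    stop("element(s) not in the isotope table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- 1
  for (el in names(formula)) {
    v <- vecs[[el]]
    for (i in seq_len(formula[[el]])) {
      out <- convolve_trunc(out, v, max_len)
    }
  }
  if (!is.null(max_len) && length(out) < max_len) {
    out <- c(out, numeric(max_len - length(out)))
  }
  out
}

# Discrete convolution of two probability vectors, truncated to max_len.
convolve_trunc <- function(a, b, max_len = NULL) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (j in seq_along(b)) {
    idx <- seq_along(a) + j - 1L
    out[idx] <- out[idx] + a * b[j]
  }
  if (!is.null(max_len) && length(out) > max_len) out <- out[seq_len(max_len)]
  out
}
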