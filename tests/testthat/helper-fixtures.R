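# Shared fixtures: tiny tables and fragments built in code.

# a raw table for the built-in alanine fragment (numC = 3, M+0 = 260)
make_ala_raw <- function(chrom = c("c1", "c2", "c3"),
                         masses = 260:263,
                         values = NULL, title = "fixture") {
  n <- length(masses)
  tbl <- tibble::tibble(analyte = rep("Ala", n), mass = as.integer(masses))
  if (is.null(values)) values <- matrix(seq_len(n * length(chrom)) * 1000,
                                        nrow = n)
  for (k in seq_along(chrom)) tbl[[chrom[k]]] <- values[, k]
  mdvflux:::new_mdv_raw(tbl, title = title)
}

# one-fragment dataset row for direct correction calls
make_mdv_dataset <- function(values, formula = "C2", num_c = 2,
                             leading = numeric(), trailing = numeric(),
                             fragment = "frag", analyte = "X",
                             chromatogram = "c1", base_mass = 100L) {
  ds <- tibble::tibble(
    analyte = analyte, fragment = fragment, formula = formula,
    tracer = "C", num_c = as.integer(num_c), base_mass = as.integer(base_mass),
    chromatogram = chromatogram, values = list(values),
    leading = list(leading), trailing = list(trailing), is_fraction = FALSE
  )
  class(ds) <- unique(c("mdv_dataset", class(ds)))
  attr(ds, "leading_boundary") <- length(leading)
  attr(ds, "trailing_boundary") <- length(trailing)
  ds
}

# random formula over the shipped elements, at most `max_atoms` atoms
random_formula <- function(max_atoms = 10L) {
  els <- c("C", "H", "N", "O", "S", "Si")
  n_el <- sample(1:3, 1)
  chosen <- sample(els, n_el)
  counts <- stats::rmultinom(1, sample(seq_len(max_atoms), 1),
                             rep(1, n_el))[, 1]
  counts[counts == 0] <- 1L
  stats::setNames(as.integer(counts), chosen)
}

# random MDV summing to 1
random_mdv <- function(n) {
  x <- stats::rgamma(n, shape = 1) + 1e-3
  x / sum(x)
}
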