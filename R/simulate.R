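#' Specify a synthetic labeling experiment
#'
#' Collects everything the forward-model simulator needs: the fragments, the
#' true labeling distributions, the distortion parameters (proton-shift
#' factor, original-biomass fractions), the experiment shape (chromatograms,
#' replicate groups) and the detector model (intensity scale, multiplicative
#' noise).  The defaults describe a small two-analyte, three-fragment GC-MS
#' experiment with six chromatograms in two replicate groups, a 10%
#' proton-loss factor, 20% original biomass and a noise-free detector — the
#' regime in which the correction pipeline must reproduce the ground truth
#' exactly.
#'
#' @param fragments Tibble of fragment definitions.
#' @param true_mdvs Named list (by fragment id) of true labeling fractions,
#'   each of length `num_c + 1` summing to 1; `NULL` draws random
#'   compositions.
#' @param corrections Correction order the dataset is built for; the forward
#'   model applies the corresponding distortions in reverse order, so running
#'   [apply_corrections()] with the same order undoes them exactly.
#' @param alpha_loss,alpha_gain Proton-shift scaling factors in \[0, 1).
#' @param obm Original-biomass fraction, one value recycled over
#'   chromatograms or a vector of one fraction per chromatogram.
#' @param n_chromatograms Number of chromatograms.
#' @param group_sizes Consecutive replicate-group sizes (must sum to
#'   `n_chromatograms`).
#' @param intensity_scale Total ion count an MDV is scaled to.
#' @param noise Relative standard deviation of multiplicative Gaussian
#'   detector noise (0 = noise-free).
#' @param rt_noise Standard deviation (minutes) of retention-time jitter.
#' @param leading_boundary,trailing_boundary Boundary-mass counts to emit;
#'   `NULL` derives them from the corrections (1 leading mass when proton
#'   loss is simulated, 1 trailing when proton gain is).  Boundary masses not
#'   populated by a proton shift are emitted with zero true intensity, as
#'   monitored-only masses.
#' @param seed Integer seed; identical specs simulate identical datasets.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(fragments = default_sim_fragments(),
                            true_mdvs = NULL,
                            corrections = c("proton-loss", "na", "obm"),
                            alpha_loss = 0.1, alpha_gain = 0,
                            obm = 0.2,
                            n_chromatograms = 6L,
                            group_sizes = c(3L, 3L),
                            intensity_scale = 1e6,
                            noise = 0,
                            rt_noise = 0,
                            leading_boundary = NULL,
                            trailing_boundary = NULL,
                            seed = 1L) {
  if (!is.null(group_sizes) && sum(group_sizes) != n_chromatograms) {
    stop("group sizes must sum to the number of chromatograms", call. = FALSE)
  }
  if (alpha_loss < 0 || alpha_loss >= 1 || alpha_gain < 0 || alpha_gain >= 1) {
    stop("proton-shift factors must lie in [0, 1)", call. = FALSE)
  }
  if (noise < 0) stop("noise must be non-negative", call. = FALSE)
  obm <- rep_len(obm, n_chromatograms)
  if (any(obm < 0 | obm >= 1)) {
    stop("original-biomass fractions must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(fragments = fragments, true_mdvs = true_mdvs,
         corrections = corrections,
         alpha_loss = alpha_loss, alpha_gain = alpha_gain, obm = obm,
         n_chromatograms = as.integer(n_chromatograms),
         group_sizes = group_sizes,
         intensity_scale = intensity_scale, noise = noise,
         rt_noise = rt_noise,
         leading_boundary = leading_boundary,
         trailing_boundary = trailing_boundary,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @rdname simulation_spec
#' @export
default_sim_fragments <- function() {
  dplyr::bind_rows(
    fragment_definition("Gly", "Gly_246", "C10H24NO2Si2", 2L, 246L),
    fragment_definition("Ala", "Ala_260", "C11H26NO2Si2", 3L, 260L),
    fragment_definition("Ala", "Ala_232", "C9H24NOSi2", 2L, 232L)
  )
}

#' Fragment set with the shape of a large GC-MS amino-acid run
#'
#' Generates a library of `n_fragments` synthetic TMS-derivatized fragments
#' whose mass rows (MDV plus one trailing boundary mass each) total
#' `total_masses`, for scale testing at the size of a realistic multi-plate
#' experiment (65 fragments / 412 masses by default).
#'
#' @param n_fragments Number of fragments (each its own analyte).
#' @param total_masses Total number of mass rows including one trailing
#'   boundary row per fragment.
#' @return A tibble of fragment definitions.
#' @export
benchmark_fragments <- function(n_fragments = 65L, total_masses = 412L) {
  # each fragment contributes num_c + 2 rows (MDV + 1 trailing boundary)
  base_numc <- (total_masses %/% n_fragments) - 2L
  n_big <- total_masses - n_fragments * (base_numc + 2L)
  if (base_numc < 1L || n_big < 0L || n_big > n_fragments) {
    stop("cannot realise ", total_masses, " masses with ", n_fragments,
         " fragments", call. = FALSE)
  }
  num_c <- rep(base_numc, n_fragments)
  if (n_big > 0L) num_c[seq_len(n_big)] <- base_numc + 1L
  purrr::map_dfr(seq_len(n_fragments), function(i) {
    nc <- num_c[i]
    fragment_definition(
      analyte = sprintf("A%02d", i),
      fragment = sprintf("A%02d_f", i),
      formula = sprintf("C%dH%dNO2Si2", nc + 6L, 2L * nc + 16L),
      num_c = nc,
      base_mass = as.integer(150L + i * 20L)
    )
  })
}

#' Forward-simulate a labeling dataset with known ground truth
#'
#' Builds a raw measurement table by pushing each fragment's true labeling
#' distribution through the distortions the corrections are meant to undo:
#' natural-abundance convolution with the fragment's correction matrix,
#' the proton-shift forward equations (populating the boundary masses), and
#' mixing with the unlabeled original-biomass distribution.  The distortions
#' are applied in the reverse of `spec$corrections`, so the pipeline run with
#' that same order recovers the truth exactly in the noise-free case.
#' Intensities are scaled to ion counts and optionally perturbed by
#' multiplicative Gaussian noise; everything is driven by `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param table Isotope table used for the natural-abundance forward model.
#' @return A list with components `raw` (an `mdv_raw` measurement table
#'   including boundary rows), `rt` (a retention-time table of the same
#'   layout, one row per fragment), `truth` (an `mdv_dataset` of the true
#'   fractions), `obm` (tibble usable by [apply_corrections()]), `groups`
#'   (replicate grouping) and the boundary counts used.
#' @export
simulate_dataset <- function(spec, table = default_isotope_table()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  frags <- spec$fragments
  chrom <- sprintf("chrom_%03d", seq_len(spec$n_chromatograms))
  lead_n <- spec$leading_boundary %||%
    (if ("proton-loss" %in% spec$corrections) 1L else 0L)
  trail_n <- spec$trailing_boundary %||%
    (if ("proton-gain" %in% spec$corrections) 1L else 0L)
  if ("proton-loss" %in% spec$corrections && lead_n < 1L) {
    stop("simulating proton loss needs at least one leading boundary mass",
         call. = FALSE)
  }
  if ("proton-gain" %in% spec$corrections && trail_n < 1L) {
    stop("simulating proton gain needs at least one trailing boundary mass",
         call. = FALSE)
  }

  truths <- spec$true_mdvs
  if (is.null(truths)) {
    truths <- stats::setNames(purrr::map(frags$num_c, function(nc) {
      x <- stats::rgamma(nc + 1L, shape = 1)
      x / sum(x)
    }), frags$fragment)
  }
  cms <- stats::setNames(
    purrr::pmap(frags, function(analyte, fragment, formula, tracer, num_c,
                                base_mass) {
      build_correction_matrix(formula, num_c, tracer, table)
    }), frags$fragment)
  na_dists <- stats::setNames(
    purrr::pmap(frags, function(analyte, fragment, formula, tracer, num_c,
                                base_mass) {
      normalize_fractions(na_distribution(formula, table,
                                          max_len = num_c + 1L))
    }), frags$fragment)
  na_before_obm <- {
    corr <- spec$corrections
    ("na" %in% corr) && ("obm" %in% corr) &&
      which(corr == "na")[1] < which(corr == "obm")[1]
  }

  rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(frags))) {
    fr <- frags[i, ]
    truth <- truths[[fr$fragment]]
    stopifnot(length(truth) == fr$num_c + 1L,
              abs(sum(truth) - 1) < 1e-9)
    vals <- matrix(0, fr$num_c + 1L + lead_n + trail_n,
                   spec$n_chromatograms)
    for (ci in seq_len(spec$n_chromatograms)) {
      x <- truth
      lead_b <- numeric(lead_n)
      trail_b <- numeric(trail_n)
      # boundary intensities are co-scaled with the MDV at every
      # renormalization so that each distortion is the exact inverse of its
      # correction regardless of the configured order
      rescale <- function(s) {
        x <<- x / s
        lead_b <<- lead_b / s
        trail_b <<- trail_b / s
      }
      for (corr in rev(spec$corrections)) {
        if (corr == "obm") {
          rescale(sum(x))
          d <- if (na_before_obm) c(1, numeric(fr$num_c))
               else na_dists[[fr$fragment]]
          x <- (1 - spec$obm[ci]) * x + spec$obm[ci] * d
        } else if (corr == "na") {
          # natural isotopes shift signal beyond the measured M+numC
          # window; intensities are meaningful relative to the window total
          x <- as.numeric(cms[[fr$fragment]] %*% x)
          rescale(sum(x))
        } else if (corr == "proton-loss") {
          a <- spec$alpha_loss
          rescale(sum(x))
          lead_b[lead_n] <- a * x[1]
          x <- (1 - a) * x + a * c(x[-1], 0)
        } else if (corr == "proton-gain") {
          a <- spec$alpha_gain
          rescale(sum(x))
          trail_b[1L] <- a * x[length(x)]
          x <- (1 - a) * x + a * c(0, x[-length(x)])
        }
      }
      v <- c(lead_b, x, trail_b) * spec$intensity_scale
      if (spec$noise > 0) {
        v <- pmax(v * (1 + stats::rnorm(length(v), 0, spec$noise)), 0)
      }
      vals[, ci] <- v
    }
    masses <- (fr$base_mass - lead_n):(fr$base_mass + fr$num_c + trail_n)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(analyte = fr$analyte, mass = as.integer(masses)),
      tibble::as_tibble(as.data.frame(vals) |>
                          stats::setNames(chrom))
    )
    truth_rows[[i]] <- purrr::map_dfr(chrom, function(cc) {
      dplyr::bind_cols(fr, tibble::tibble(chromatogram = cc,
                                          values = list(truth),
                                          is_fraction = TRUE))
    })
  }
  raw <- new_mdv_raw(dplyr::bind_rows(rows), title = "simulated dataset")
  truth_ds <- dplyr::bind_rows(truth_rows)
  class(truth_ds) <- unique(c("mdv_dataset", class(truth_ds)))

  rt_base <- stats::runif(nrow(frags), 5, 25)
  rt_vals <- matrix(rep(rt_base, spec$n_chromatograms), ncol =
                      spec$n_chromatograms)
  if (spec$rt_noise > 0) {
    rt_vals <- rt_vals + stats::rnorm(length(rt_vals), 0, spec$rt_noise)
  }
  rt <- new_mdv_raw(dplyr::bind_cols(
    tibble::tibble(analyte = frags$analyte, mass = frags$base_mass),
    tibble::as_tibble(as.data.frame(rt_vals) |> stats::setNames(chrom))
  ), title = "retention times")

  list(raw = raw, rt = rt, truth = truth_ds,
       obm = tibble::tibble(chromatogram = chrom, obm = spec$obm),
       groups = replicate_grouping(chrom, spec$group_sizes),
       leading_boundary = lead_n, trailing_boundary = trail_n)
}

#' Exhaustive-enumeration oracle for natural-abundance distributions
#'
#' Computes the mass-shift distribution of a formula by enumerating every
#' per-atom isotope assignment and accumulating probability per total shift —
#' no convolution, no factorials.  Exponential in the atom count (feasible up
#' to ~10 atoms); serves as the independent reference for
#' [na_distribution()] and [multinomial_abundance()].
#'
#' @inheritParams na_distribution
#' @return Probability vector over total mass shift.
#' @export
brute_force_na <- function(formula, table = default_isotope_table(),
                           max_len = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  vecs <- iso_vectors(table)
  atoms <- unlist(purrr::map(names(formula), function(el) {
    rep(list(vecs[[el]]), formula[[el]])
  }), recursive = FALSE)
  if (length(atoms) == 0L) {
    out <- 1
  } else {
    if (prod(lengths(atoms)) > 2^20) {
      stop("brute-force enumeration over ", length(atoms),
           " atoms is too large; use na_distribution()", call. = FALSE)
    }
    grid <- expand.grid(purrr::map(atoms, seq_along))
    shift <- rowSums(grid) - ncol(grid)
    prob <- rep(1, nrow(grid))
    for (k in seq_along(atoms)) {
      prob <- prob * atoms[[k]][grid[[k]]]
    }
    out <- as.numeric(tapply(prob, factor(shift, levels = 0:max(shift)), sum))
    out[is.na(out)] <- 0
  }
  if (!is.null(max_len)) {
    out <- out[seq_len(min(max_len, length(out)))]
    if (length(out) < max_len) out <- c(out, numeric(max_len - length(out)))
  }
  out
}
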