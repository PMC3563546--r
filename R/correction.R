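#' Natural-abundance correction matrix of a fragment
#'
#' Builds the square lower-triangular matrix that maps the true labeling
#' distribution of a fragment to the distribution actually measured once
#' naturally occurring heavy isotopes are taken into account.  Column `j`
#' (0-based) is the natural-abundance mass-shift distribution of the fragment
#' with `j` tracer atoms removed from the natural-isotope pool (those
#' positions carry the experimental label and cannot also acquire a natural
#' heavy isotope), shifted down by `j` rows: entry `(i, j)` is the
#' probability that a `j`-labeled molecule is measured at mass M+`i`.  The
#' matrix is truncated to `(num_c + 1) x (num_c + 1)`; per-element isotope
#' vectors are truncated at shift +2.
#'
#' @param formula Full elemental formula (string or named count vector)
#'   including derivatization atoms.
#' @param num_c Number of tracer atoms in the backbone (MDV length - 1).
#' @param tracer Tracer element symbol.
#' @param table Isotope table.
#' @return A `(num_c + 1) x (num_c + 1)` matrix; columns sum to at most 1,
#'   diagonal entries are positive.
#' @export
#' @examples
#' build_correction_matrix("C2", num_c = 2)
build_correction_matrix <- function(formula, num_c, tracer = "C",
                                    table = default_isotope_table()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!tracer %in% names(formula) || formula[[tracer]] < num_c) {
    stop("formula must contain at least num_c atoms of the tracer element '",
         tracer, "'", call. = FALSE)
  }
  n <- num_c + 1L
  cm <- matrix(0, n, n)
  for (j in 0:num_c) {
    f <- formula
    f[[tracer]] <- f[[tracer]] - j
    f <- f[f > 0L]
    d <- na_distribution(f, table, max_len = n - j)
    cm[(j + 1L):n, j + 1L] <- d
  }
  cm
}

#' Correct an MDV for naturally occurring isotopes
#'
#' Solves `measured = CM %*% true` for the true labeling distribution under a
#' non-negativity constraint (non-negative least squares), then normalizes.
#' With noise-free data the solution coincides with plain triangular
#' inversion; with noisy data plain inversion can produce negative fractions,
#' which NNLS avoids.
#'
#' @param values Measured MDV (ion counts or fractions), length `num_c + 1`.
#' @param cm Correction matrix from [build_correction_matrix()].
#' @param fragment Fragment identifier used in error messages.
#' @return Corrected MDV as fractions summing to 1.
#' @export
correct_na <- function(values, cm, fragment = "<fragment>") {
  normalize_fractions(na_solve(values, cm, fragment))
}

# Unnormalized NNLS solution of measured = cm %*% x.
na_solve <- function(values, cm, fragment = "<fragment>") {
  stopifnot(length(values) == nrow(cm), nrow(cm) == ncol(cm))
  if (anyNA(values)) {
    stop("MDV of fragment '", fragment, "' contains missing values",
         call. = FALSE)
  }
  if (any(diag(cm) <= 0) || rcond(cm) < 1e-12) {
    stop("correction matrix of fragment '", fragment,
         "' is singular or ill-conditioned", call. = FALSE)
  }
  x <- pracma::lsqnonneg(cm, as.numeric(values))$x
  if (sum(x) <= 0) {
    stop("natural-abundance correction of fragment '", fragment,
         "' yielded an all-zero MDV", call. = FALSE)
  }
  x
}

#' Estimate the proton-shift scaling factor
#'
#' During ionisation a fixed fraction \eqn{\alpha} of all molecules of a
#' fragment can lose (or, e.g. for the McLafferty ion of fatty acid methyl
#' esters, gain) one hydrogen atom, independent of labeling.  For proton
#' loss the measured intensities obey
#' \deqn{M_k^{meas} = (1-\alpha) M_k' + \alpha M_{k+1}'}
#' with the boundary mass \eqn{M_{-1}^{meas} = (1-\alpha) M_{-1}' + \alpha
#' M_0'}.  Assuming the true boundary intensity is negligible
#' (\eqn{M_{-1}' = 0}), \eqn{\alpha} is obtained by fixed-point iteration:
#' starting from \eqn{\alpha_0 = } boundary / adjacent measured value, the
#' primed (true) intensities are recovered by inverting the equation set at
#' the current \eqn{\alpha}, and \eqn{\alpha} is updated to boundary /
#' adjacent primed value, until the change falls below `tol`.  Proton gain is
#' the mirror image and requires the trailing boundary mass M+numC+1.
#'
#' When the true boundary measurement is not negligible the factor can be
#' artificially inflated or no stable value found; estimation then fails and
#' the caller should leave the data uncorrected.
#'
#' @param values Measured MDV, M+0 .. M+numC.
#' @param boundary Measured boundary intensity: M-1 for `"loss"`, M+numC+1
#'   for `"gain"`; same scale as `values`.
#' @param direction `"loss"` or `"gain"`.
#' @param tol Convergence tolerance on successive alpha values.
#' @param max_iter Iteration cap.
#' @return An object of class `proton_shift_model`: list with `direction`,
#'   `alpha`, `iterations`, `converged`.  `converged = FALSE` (with `alpha =
#'   NA`) signals failure.
#' @export
#' @examples
#' # forward-simulate loss with alpha = 0.1, then recover it
#' true <- c(0.8, 0.15, 0.05)
#' meas <- c(0.9 * true[1] + 0.1 * true[2],
#'           0.9 * true[2] + 0.1 * true[3],
#'           0.9 * true[3])
#' estimate_alpha(meas, boundary = 0.1 * true[1], direction = "loss")
estimate_alpha <- function(values, boundary, direction = c("loss", "gain"),
                           tol = 1e-9, max_iter = 100L) {
  direction <- match.arg(direction)
  fail <- function() structure(list(direction = direction, alpha = NA_real_,
                                    iterations = NA_integer_,
                                    converged = FALSE),
                               class = "proton_shift_model")
  adj_meas <- if (direction == "loss") values[1] else values[length(values)]
  if (is.na(boundary) || anyNA(values) || adj_meas <= 0) return(fail())
  if (boundary == 0) {
    return(structure(list(direction = direction, alpha = 0,
                          iterations = 0L, converged = TRUE),
                     class = "proton_shift_model"))
  }
  alpha <- boundary / adj_meas
  if (alpha < 0 || alpha >= 1) return(fail())
  for (it in seq_len(max_iter)) {
    primed <- invert_proton_shift(values, alpha, direction)
    adj <- if (direction == "loss") primed[1] else primed[length(primed)]
    if (!is.finite(adj) || adj <= 0) return(fail())
    alpha_new <- boundary / adj
    if (alpha_new < 0 || alpha_new >= 1) return(fail())
    if (abs(alpha_new - alpha) < tol) {
      return(structure(list(direction = direction, alpha = alpha_new,
                            iterations = it, converged = TRUE),
                       class = "proton_shift_model"))
    }
    alpha <- alpha_new
  }
  fail()
}

# Invert the proton-shift equation set at a known alpha (no normalization).
invert_proton_shift <- function(values, alpha, direction) {
  n <- length(values)
  primed <- numeric(n)
  if (direction == "loss") {
    primed[n] <- values[n] / (1 - alpha)
    if (n > 1L) for (k in (n - 1L):1L) {
      primed[k] <- (values[k] - alpha * primed[k + 1L]) / (1 - alpha)
    }
  } else {
    primed[1] <- values[1] / (1 - alpha)
    if (n > 1L) for (k in 2:n) {
      primed[k] <- (values[k] - alpha * primed[k - 1L]) / (1 - alpha)
    }
  }
  primed
}

#' Correct an MDV for proton loss or gain
#'
#' Inverts the proton-shift equation set (see [estimate_alpha()]) at the
#' model's scaling factor and normalizes the result.  For loss the recursion
#' runs from the heaviest mass down; for gain from the lightest mass up.
#'
#' @param values Measured MDV.
#' @param model A `proton_shift_model` (or a number, taken as the loss
#'   factor).
#' @return Corrected MDV as fractions summing to 1.
#' @export
correct_proton_shift <- function(values, model) {
  if (is.numeric(model)) {
    model <- structure(list(direction = "loss", alpha = model,
                            iterations = 0L, converged = TRUE),
                       class = "proton_shift_model")
  }
  stopifnot(inherits(model, "proton_shift_model"))
  if (!isTRUE(model$converged)) {
    stop("cannot correct with a failed proton-shift model", call. = FALSE)
  }
  if (model$alpha == 0) return(normalize_fractions(values))
  normalize_fractions(invert_proton_shift(values, model$alpha,
                                          model$direction))
}

#' Correct an MDV for unlabeled original biomass
#'
#' Biomass present before the tracer was fed is unlabeled and dilutes the
#' measured labeling.  Given its fraction `f` of the sample, the unlabeled
#' contribution — distributed over the mass isotopomers according to the
#' natural-abundance distribution `na_dist` — is subtracted and the remainder
#' rescaled:
#' \deqn{m_{corr} = (m - f \cdot na) / (1 - f).}
#' Small negative entries arising from noise are clamped to zero before
#' renormalization.  When the correction runs *after* natural-abundance
#' correction, the unlabeled biomass is simply the M+0 species, so `na_dist`
#' degenerates to `(1, 0, ..., 0)`.
#'
#' @param values MDV as fractions (normalized).
#' @param f Original-biomass fraction in \[0, 1).
#' @param na_dist Natural-abundance distribution of the fully unlabeled
#'   fragment, same length as `values`, summing to 1.
#' @return Corrected MDV as fractions.
#' @export
correct_obm <- function(values, f, na_dist) {
  stopifnot(length(values) == length(na_dist))
  if (f < 0 || f >= 1) {
    stop("original-biomass fraction must lie in [0, 1); got ", f,
         call. = FALSE)
  }
  if (f == 0) return(normalize_fractions(values))
  out <- (values - f * na_dist) / (1 - f)
  out[out < 0] <- 0
  if (sum(out) <= 0) {
    stop("original-biomass correction removed the entire signal ",
         "(measured MDV indistinguishable from unlabeled biomass)",
         call. = FALSE)
  }
  normalize_fractions(out)
}

#' Normalize an intensity vector to fractions
#'
#' Scales the vector to unit sum (displayed as percentages of 100% only at
#' output time; internally fractions are used throughout).
#'
#' @param values Non-negative intensities.
#' @return `values / sum(values)`.
#' @export
normalize_fractions <- function(values) {
  s <- sum(values)
  if (!is.finite(s) || s <= 0) {
    stop("cannot normalize a vector with non-positive sum", call. = FALSE)
  }
  values / s
}

#' Apply the configured corrections to a dataset
#'
#' Runs the corrections listed in the configuration, in exactly that order,
#' on every MDV of every chromatogram; each correction normalizes its result,
#' and the final MDVs are fractions with all boundary data removed.  An empty
#' correction list scales (normalizes) the uncorrected data.  MDVs containing
#' missing values, and fragments for which proton-shift estimation fails, are
#' reported in the feedback and (for failed proton shifts) passed on
#' uncorrected for that step.
#'
#' The unlabeled-biomass distribution used by the `obm` step depends on its
#' position in the order: before natural-abundance correction it is the
#' fragment's (truncated, renormalized) natural-abundance distribution;
#' after, it is the pure M+0 vector.
#'
#' @param dataset An `mdv_dataset` from [assemble_fragments()] or
#'   [simulate_dataset()].
#' @param config A [run_config()]; only `corrections`, boundary counts and
#'   `tracer_element` are used here.
#' @param obm Tibble `chromatogram` / `obm` (required when `"obm"` is among
#'   the corrections; every chromatogram must be present).
#' @param table Isotope table.
#' @return A list of class `mdv_correction_result` with components
#'   `dataset` (corrected, `is_fraction = TRUE`, boundaries stripped),
#'   `alphas` (tibble of proton-shift estimates per fragment and
#'   chromatogram) and `feedback` (tibble of messages).
#' @export
apply_corrections <- function(dataset, config, obm = NULL,
                              table = default_isotope_table()) {
  corrections <- config$corrections
  lead_n <- attr(dataset, "leading_boundary") %||% 0L
  trail_n <- attr(dataset, "trailing_boundary") %||% 0L
  if ("proton-loss" %in% corrections && lead_n < 1L) {
    stop("proton-loss correction requires a leading boundary mass (M-1)",
         call. = FALSE)
  }
  if ("proton-gain" %in% corrections && trail_n < 1L) {
    stop("proton-gain correction requires a trailing boundary mass ",
         "(M+numC+1)", call. = FALSE)
  }
  if ("obm" %in% corrections) {
    if (is.null(obm)) {
      stop("'obm' correction requested but no OBM table supplied",
           call. = FALSE)
    }
    absent <- setdiff(unique(dataset$chromatogram), obm$chromatogram)
    if (length(absent)) {
      stop("chromatogram(s) missing from the OBM table: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }

  # per-fragment quantities shared across chromatograms
  frags <- dplyr::distinct(tibble::as_tibble(dataset),
                           .data$fragment, .data$formula, .data$tracer,
                           .data$num_c)
  cms <- list()
  na_dists <- list()
  if ("na" %in% corrections) {
    cms <- stats::setNames(
      purrr::pmap(frags, function(fragment, formula, tracer, num_c) {
        build_correction_matrix(formula, num_c, tracer, table)
      }), frags$fragment)
  }
  if ("obm" %in% corrections) {
    na_dists <- stats::setNames(
      purrr::pmap(frags, function(fragment, formula, tracer, num_c) {
        normalize_fractions(na_distribution(formula, table,
                                            max_len = num_c + 1L))
      }), frags$fragment)
  }

  fb <- list()
  alphas <- list()
  keep <- logical(nrow(dataset))
  out_values <- vector("list", nrow(dataset))
  for (r in seq_len(nrow(dataset))) {
    row <- dataset[r, ]
    v <- row$values[[1]]
    if (anyNA(v)) {
      fb[[length(fb) + 1L]] <- tibble::tibble(
        fragment = row$fragment, chromatogram = row$chromatogram,
        message = "MDV contains missing values; skipped")
      next
    }
    lead <- row$leading[[1]]
    trail <- row$trailing[[1]]
    # boundary intensities are rescaled alongside the MDV whenever a
    # correction normalizes, so a later proton-shift estimate still sees
    # boundary and MDV on one scale
    rescale <- function(s) {
      v <<- v / s
      lead <<- lead / s
      trail <<- trail / s
    }
    na_applied <- FALSE
    failed <- FALSE
    for (corr in corrections) {
      if (corr %in% c("proton-loss", "proton-gain")) {
        direction <- if (corr == "proton-loss") "loss" else "gain"
        boundary <- if (direction == "loss") {
          lead[lead_n]                      # M-1 is the last leading mass
        } else {
          trail[1L]                         # M+numC+1 is the first trailing
        }
        est <- estimate_alpha(v, boundary, direction)
        alphas[[length(alphas) + 1L]] <- tibble::tibble(
          analyte = row$analyte, fragment = row$fragment,
          chromatogram = row$chromatogram, direction = direction,
          alpha = est$alpha, converged = est$converged)
        if (!est$converged) {
          fb[[length(fb) + 1L]] <- tibble::tibble(
            fragment = row$fragment, chromatogram = row$chromatogram,
            message = paste0("no stable proton-", direction,
                             " scaling factor; data left uncorrected"))
          next
        }
        v <- invert_proton_shift(v, est$alpha, direction)
        if (direction == "loss") lead[lead_n] <- 0 else trail[1L] <- 0
        rescale(sum(v))
      } else if (corr == "na") {
        z <- tryCatch(na_solve(v, cms[[row$fragment]], row$fragment),
                      error = function(e) e)
        if (inherits(z, "error")) {
          fb[[length(fb) + 1L]] <- tibble::tibble(
            fragment = row$fragment, chromatogram = row$chromatogram,
            message = conditionMessage(z))
          failed <- TRUE
          break
        }
        v <- z
        rescale(sum(v))
        na_applied <- TRUE
      } else if (corr == "obm") {
        f <- obm$obm[match(row$chromatogram, obm$chromatogram)]
        d <- if (na_applied) c(1, numeric(row$num_c))
             else na_dists[[row$fragment]]
        rescale(sum(v))
        u <- (v - f * d) / (1 - f)
        u[u < 0] <- 0
        if (f >= 1 || sum(u) <= 0) {
          fb[[length(fb) + 1L]] <- tibble::tibble(
            fragment = row$fragment, chromatogram = row$chromatogram,
            message = paste0("original-biomass correction removed the ",
                             "entire signal"))
          failed <- TRUE
          break
        }
        v <- u
        rescale(sum(v))
      }
    }
    if (failed) next
    out_values[[r]] <- normalize_fractions(v)
    keep[r] <- TRUE
  }

  corrected <- tibble::as_tibble(dataset)[keep, ]
  corrected$values <- out_values[keep]
  corrected$is_fraction <- TRUE
  corrected$leading <- NULL
  corrected$trailing <- NULL
  class(corrected) <- unique(c("mdv_dataset", class(corrected)))
  structure(
    list(dataset = corrected,
         alphas = if (length(alphas)) dplyr::bind_rows(alphas) else
           tibble::tibble(analyte = character(), fragment = character(),
                          chromatogram = character(), direction = character(),
                          alpha = double(), converged = logical()),
         feedback = if (length(fb)) dplyr::bind_rows(fb) else
           tibble::tibble(fragment = character(), chromatogram = character(),
                          message = character())),
    class = "mdv_correction_result"
  )
}

#' Tidy a proton-shift model
#'
#' @param x A `proton_shift_model` from [estimate_alpha()].
#' @param ... Unused.
#' @return A one-row tibble with columns `direction`, `alpha`, `iterations`,
#'   `converged`.
#' @export
tidy.proton_shift_model <- function(x, ...) {
  tibble::tibble(direction = x$direction, alpha = x$alpha,
                 iterations = x$iterations, converged = x$converged)
}

#' @export
print.proton_shift_model <- function(x, ...) {
  if (x$converged) {
    cat("Proton-", x$direction, " model: alpha = ",
        format(x$alpha, digits = 6), " (", x$iterations, " iterations)\n",
        sep = "")
  } else {
    cat("Proton-", x$direction, " model: no stable scaling factor found\n",
        sep = "")
  }
  invisible(x)
}
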