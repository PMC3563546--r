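test_that("the correction matrix has the documented structure", {
  cm <- build_correction_matrix("C2", num_c = 2)
  # column 0 is the natural-abundance distribution of the full formula
  expect_equal(cm[, 1], na_distribution("C2", max_len = 3),
               tolerance = 1e-12)
  expect_equal(cm[, 1], c(0.978121, 0.021758, 0.000121), tolerance = 1e-9)
  # a fully labeled molecule has no natural-isotope pool left
  expect_equal(cm[, 3], c(0, 0, 1))
  # lower-triangular, positive diagonal, columns sum to at most 1
  expect_true(all(cm[upper.tri(cm)] == 0))
  expect_true(all(diag(cm) > 0))
  expect_true(all(colSums(cm) <= 1 + 1e-9))

  # with no heavy isotopes anywhere the matrix is the identity
  tab0 <- mdvflux:::complete_isotope_table(
    tibble::tibble(element = "C", shift = 1L, abundance = 0))
  expect_equal(build_correction_matrix("C3", 3, table = tab0), diag(4))
})

test_that("correction-matrix columns match the enumeration oracle", {
  # each column must be the brute-force distribution of the formula with the
  # labeled tracer atoms taken out of the natural-isotope pool
  f <- parse_formula("C4H9NSi")
  cm <- build_correction_matrix(f, num_c = 3)
  for (j in 0:3) {
    f_j <- f
    f_j[["C"]] <- f_j[["C"]] - j
    f_j <- f_j[f_j > 0]
    expected <- c(numeric(j), brute_force_na(f_j, max_len = 4 - j))
    expect_equal(cm[, j + 1], expected, tolerance = 1e-12)
  }
})

test_that("natural-abundance correction inverts the forward convolution", {
  cm <- build_correction_matrix("C11H26NO2Si2", num_c = 3)
  # an unlabeled sample measures as the NA distribution and corrects to M+0
  measured <- cm %*% c(1, 0, 0, 0)
  expect_equal(correct_na(as.numeric(measured), cm), c(1, 0, 0, 0),
               tolerance = 1e-10)
  # a 50/50 M+0 / M+numC mixture is recovered exactly (noise-free)
  truth <- c(0.5, 0, 0, 0.5)
  expect_equal(correct_na(as.numeric(cm %*% truth), cm), truth,
               tolerance = 1e-10)
  # identity matrix only normalizes
  expect_equal(correct_na(c(2, 2, 0, 0), diag(4)), c(0.5, 0.5, 0, 0))
})

test_that("NNLS and plain inversion agree on noise-free data", {
  set.seed(3)
  cm <- build_correction_matrix("C13H30NO2Si2", num_c = 5)
  for (i in 1:10) {
    truth <- random_mdv(6)
    measured <- as.numeric(cm %*% truth)
    nnls_sol <- correct_na(measured, cm)
    plain <- solve(cm, measured)
    expect_equal(nnls_sol, plain / sum(plain), tolerance = 1e-8)
  }
})

test_that("corrected MDVs are non-negative and sum to one even with noise", {
  set.seed(4)
  cm <- build_correction_matrix("C11H26NO2Si2", num_c = 3)
  for (i in 1:20) {
    truth <- random_mdv(4)
    measured <- as.numeric(cm %*% truth) * (1 + rnorm(4, 0, 0.05))
    measured <- pmax(measured, 0)
    x <- correct_na(measured, cm)
    expect_true(all(x >= 0))
    expect_equal(sum(x), 1, tolerance = 1e-12)
  }
})

test_that("the proton-loss factor is recovered by fixed-point iteration", {
  true <- c(0.8, 0.15, 0.05)
  alpha <- 0.1
  meas <- (1 - alpha) * true + alpha * c(true[-1], 0)
  expect_equal(meas, c(0.735, 0.14, 0.045))
  boundary <- alpha * true[1]
  est <- estimate_alpha(meas, boundary, "loss")
  expect_true(est$converged)
  expect_equal(est$alpha, 0.1, tolerance = 1e-6)
  # zero boundary means no proton shift
  expect_equal(estimate_alpha(meas, 0, "loss")$alpha, 0)
  # a boundary larger than the adjacent mass cannot give alpha < 1
  bad <- estimate_alpha(c(0.1, 0.5, 0.4), boundary = 0.2, "loss")
  expect_false(bad$converged)
  expect_true(is.na(bad$alpha))
})

test_that("proton-shift correction inverts the forward equations in both
           directions", {
  true <- c(0.8, 0.15, 0.05)
  for (alpha in c(0.05, 0.1, 0.25)) {
    meas_loss <- (1 - alpha) * true + alpha * c(true[-1], 0)
    est <- estimate_alpha(meas_loss, alpha * true[1], "loss")
    expect_equal(correct_proton_shift(meas_loss, est), true,
                 tolerance = 1e-9)
    # gain is the mirror image
    mirror <- rev(true)
    meas_gain <- (1 - alpha) * mirror + alpha * c(0, mirror[-3])
    est_g <- estimate_alpha(meas_gain, alpha * mirror[3], "gain")
    expect_true(est_g$converged)
    expect_equal(est_g$alpha, alpha, tolerance = 1e-6)
    expect_equal(correct_proton_shift(meas_gain, est_g), mirror,
                 tolerance = 1e-9)
    expect_equal(correct_proton_shift(meas_gain, est_g),
                 rev(correct_proton_shift(meas_loss, est)),
                 tolerance = 1e-9)
  }
  # alpha = 0 is the identity (up to normalization)
  expect_equal(correct_proton_shift(true, 0), true)
})

test_that("original-biomass subtraction removes the unlabeled admixture", {
  na2 <- na_distribution("C2", max_len = 3)
  labeled <- c(0, 0, 1)
  f <- 0.4
  measured <- (1 - f) * labeled + f * na2
  expect_equal(measured, c(0.391248, 0.008703, 0.600048), tolerance = 1e-5)
  expect_equal(correct_obm(measured, f, na2), labeled, tolerance = 1e-9)
  # f = 0 is the identity
  expect_equal(correct_obm(labeled, 0, na2), labeled)
  # a signal entirely below the biomass contribution degenerates to zero
  d <- na2 / sum(na2)
  expect_error(correct_obm(0.5 * d, 0.8, d), "entire signal")
  expect_error(correct_obm(labeled, 1, na2), "\\[0, 1\\)")
})

test_that("normalization scales to unit sum and rejects degenerate input", {
  expect_equal(normalize_fractions(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize_fractions(c(0, 5, 0)), c(0, 1, 0))
  expect_error(normalize_fractions(c(0, 0)), "non-positive")
})

test_that("an empty correction list only normalizes", {
  ds <- make_mdv_dataset(c(200, 100, 100))
  res <- apply_corrections(ds, run_config(corrections = character()))
  expect_equal(res$dataset$values[[1]], c(0.5, 0.25, 0.25))
  expect_true(res$dataset$is_fraction[1])
  expect_false("leading" %in% names(res$dataset))
})

test_that("correction order is honored end to end", {
  spec <- simulation_spec(seed = 99)
  for (order in list(c("proton-loss", "na", "obm"),
                     c("proton-loss", "obm", "na"),
                     c("obm", "na", "proton-loss"))) {
    sp <- spec
    sp$corrections <- order
    sim <- simulate_dataset(sp)
    asm <- assemble_fragments(sim$raw, sp$fragments,
                              leading_boundary = sim$leading_boundary,
                              trailing_boundary = sim$trailing_boundary)
    cfg <- run_config(corrections = order,
                      leading_boundary = sim$leading_boundary,
                      trailing_boundary = sim$trailing_boundary)
    res <- apply_corrections(asm$dataset, cfg, obm = sim$obm)
    joined <- dplyr::inner_join(
      tibble::as_tibble(res$dataset)[c("fragment", "chromatogram", "values")],
      tibble::as_tibble(sim$truth)[c("fragment", "chromatogram", "values")],
      by = c("fragment", "chromatogram"))
    err <- max(purrr::map2_dbl(joined$values.x, joined$values.y,
                               ~ max(abs(.x - .y))))
    expect_lt(err, 1e-6)
  }
})

test_that("obm correction requires every chromatogram in the OBM table", {
  ds <- make_mdv_dataset(c(0.3, 0.3, 0.4), chromatogram = "mystery")
  cfg <- run_config(corrections = "obm")
  obm <- tibble::tibble(chromatogram = "other", obm = 0.2)
  expect_error(apply_corrections(ds, cfg, obm = obm), "mystery")
  expect_error(apply_corrections(ds, cfg), "no OBM table")
})

test_that("proton corrections demand their boundary masses", {
  ds <- make_mdv_dataset(c(0.5, 0.3, 0.2))
  expect_error(apply_corrections(ds, run_config(corrections = "proton-loss",
                                                leading_boundary = 0)),
               "leading boundary")
  expect_error(apply_corrections(ds, run_config(corrections = "proton-gain")),
               "trailing boundary")
})

test_that("MDVs with missing values are skipped with feedback", {
  ds <- dplyr::bind_rows(
    make_mdv_dataset(c(0.5, 0.3, NA), fragment = "broken"),
    make_mdv_dataset(c(0.5, 0.3, 0.2), fragment = "fine")
  )
  class(ds) <- unique(c("mdv_dataset", class(ds)))
  res <- apply_corrections(ds, run_config(corrections = "na"))
  expect_equal(res$dataset$fragment, "fine")
  expect_match(res$feedback$message, "missing")
})

test_that("a failed proton-shift estimate leaves data uncorrected with
           feedback", {
  # boundary exceeding the adjacent mass makes alpha >= 1: estimation fails
  ds <- make_mdv_dataset(c(0.1, 0.5, 0.4), leading = 0.2)
  cfg <- run_config(corrections = "proton-loss", leading_boundary = 1)
  res <- apply_corrections(ds, cfg)
  expect_match(res$feedback$message, "no stable proton-loss")
  expect_false(res$alphas$converged[1])
  # the data pass through normalized but otherwise untouched
  expect_equal(res$dataset$values[[1]], c(0.1, 0.5, 0.4))
})

test_that("round trip over random conditions recovers truth, or an exact
           alternative proton-shift interpretation of the same data", {
  # property test: random true MDVs, alpha in [0, 0.3], obm in [0, 0.8].
  # The proton-shift equation set (numC + 2 measurements, numC + 2
  # unknowns) can have several exact non-negative solutions; when the
  # fixed-point estimate locks onto an alternative root, the corrected MDV
  # must still be an exact interpretation of the measured data.
  set.seed(2024)
  n_ambiguous <- 0L
  for (i in 1:50) {
    seed_i <- sample.int(1e6, 1)
    alpha <- runif(1, 0, 0.3)
    f <- runif(1, 0, 0.8)
    sp <- simulation_spec(alpha_loss = alpha, obm = f,
                          n_chromatograms = 1L, group_sizes = 1L,
                          noise = 0, seed = seed_i)
    sim <- simulate_dataset(sp)
    asm <- assemble_fragments(sim$raw, sp$fragments,
                              leading_boundary = sim$leading_boundary)
    cfg <- run_config(corrections = c("proton-loss", "na", "obm"),
                      leading_boundary = 1)
    res <- apply_corrections(asm$dataset, cfg, obm = sim$obm)
    expect_true(all(res$alphas$converged))
    for (r in seq_len(nrow(asm$dataset))) {
      frag <- asm$dataset$fragment[r]
      got <- res$dataset$values[res$dataset$fragment == frag][[1]]
      want <- sim$truth$values[sim$truth$fragment == frag][[1]]
      a_hat <- res$alphas$alpha[res$alphas$fragment == frag]
      if (abs(a_hat - alpha) < 1e-6) {
        expect_equal(got, want, tolerance = 1e-6)
      } else {
        # alternative root: it must solve the boundary equation exactly,
        # with a fully non-negative de-shifted MDV
        n_ambiguous <- n_ambiguous + 1L
        meas <- asm$dataset$values[[r]]
        boundary <- asm$dataset$leading[[r]][1]
        primed <- mdvflux:::invert_proton_shift(meas, a_hat, "loss")
        expect_true(all(primed >= -1e-9))
        expect_equal(a_hat * primed[1], boundary,
                     tolerance = 1e-6 * boundary)
      }
    }
  }
  # ambiguity is the exception, not the rule
  expect_lt(n_ambiguous, 15L)
})
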