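make_corrected <- function() {
  ds <- dplyr::bind_rows(
    make_mdv_dataset(c(0.4, 0.4, 0.2), chromatogram = "c1"),
    make_mdv_dataset(c(0.6, 0.2, 0.2), chromatogram = "c2"),
    make_mdv_dataset(c(0.5, 0.3, 0.2), chromatogram = "c3")
  )
  ds$is_fraction <- TRUE
  ds$leading <- NULL
  ds$trailing <- NULL
  class(ds) <- unique(c("mdv_dataset", class(ds)))
  ds
}

test_that("replicate statistics use the sample SD and the 5% single-
           replicate default", {
  ds <- make_corrected()
  groups <- tibble::tibble(chromatogram = c("c1", "c2", "c3"),
                           group = c("g1", "g1", "g2"))
  st <- replicate_stats(ds, groups)
  g1 <- st[st$group == "g1", ]
  expect_equal(g1$mean, c(0.5, 0.3, 0.2))
  expect_equal(g1$sd, c(sd(c(0.4, 0.6)), sd(c(0.4, 0.2)), 0),
               tolerance = 1e-12)
  expect_equal(g1$sd[1], 0.1414, tolerance = 1e-3)
  # single replicate: default deviation of five percent at every mass
  g2 <- st[st$group == "g2", ]
  expect_equal(g2$sd, rep(0.05, 3))
  expect_equal(g2$n, rep(1L, 3))
  # mean vectors still sum to 1
  expect_equal(sum(g1$mean), 1, tolerance = 1e-9)
  expect_equal(sum(g2$mean), 1, tolerance = 1e-9)
})

test_that("two identical replicates give zero deviation", {
  ds <- dplyr::bind_rows(
    make_mdv_dataset(c(0.4, 0.4, 0.2), chromatogram = "c1"),
    make_mdv_dataset(c(0.4, 0.4, 0.2), chromatogram = "c2")
  )
  class(ds) <- unique(c("mdv_dataset", class(ds)))
  groups <- tibble::tibble(chromatogram = c("c1", "c2"), group = "g")
  st <- replicate_stats(ds, groups)
  expect_equal(st$mean, c(0.4, 0.4, 0.2))
  expect_equal(st$sd, rep(0, 3))
})

test_that("FTBL mass-spectrometry files carry one weight row per mass", {
  ds <- make_corrected()[1, ]   # one fragment, numC = 2, one group of 1
  class(ds) <- unique(c("mdv_dataset", class(ds)))
  st <- replicate_stats(ds, tibble::tibble(chromatogram = "c1",
                                           group = "wt"))
  dir <- withr::local_tempdir()
  paths <- write_ftbl_ms(st, dir, "mass-spectrometry")
  expect_equal(basename(paths), "wt.ftbl")
  lines <- readLines(paths)
  expect_equal(lines[1], "MASS_SPECTROMETRY")
  expect_match(lines[2], "META_NAME\tFRAGMENT\tWEIGHT\tVALUE\tDEVIATION")
  data_rows <- lines[-(1:2)]
  expect_length(data_rows, 3)      # weights 0, 1, 2
  cells <- strsplit(data_rows, "\t")
  expect_equal(vapply(cells, `[[`, "", 4), c("0", "1", "2"))
  # first row names analyte and carbon positions; continuations are blank
  expect_equal(cells[[1]][2:3], c("X", "1,2"))
  expect_equal(cells[[2]][2:3], c("", ""))
  # golden byte layout for the first data row
  expect_equal(data_rows[1], "\tX\t1,2\t0\t0.4\t0.05")
})

test_that("FTBL label-measurement files use the cumomer column layout", {
  ds <- make_corrected()[1, ]
  class(ds) <- unique(c("mdv_dataset", class(ds)))
  st <- replicate_stats(ds, tibble::tibble(chromatogram = "c1", group = "g"))
  dir <- withr::local_tempdir()
  paths <- write_ftbl_ms(st, dir, "label-measurements")
  lines <- readLines(paths)
  expect_equal(lines[1], "LABEL_MEASUREMENTS")
  expect_match(lines[2], "CUM_CONSTRAINTS")
  expect_equal(lines[3], "\tX\t1\t0.4\t0.05\t#M0")
})

test_that("injection into a model preserves every other line byte-for-
           byte", {
  ds <- make_corrected()
  groups <- tibble::tibble(chromatogram = c("c1", "c2", "c3"),
                           group = c("g1", "g1", "g2"))
  st <- replicate_stats(ds, groups)
  model <- c("NETWORK", "\tFLUX_NAME\tEDUCT_1", "\tv1\tA", "",
             "MASS_SPECTROMETRY",
             "\tMETA_NAME\tFRAGMENT\tWEIGHT\tVALUE\tDEVIATION",
             "\tGlc\t1,2\t0\t0.9\t0.01",
             "",
             "OPTIONS", "\tOPT_NAME\tOPT_VALUE")
  model_file <- withr::local_tempfile(fileext = ".ftbl")
  writeLines(model, model_file)
  dir <- withr::local_tempdir()
  paths <- write_ftbl_ms(st, dir, "mass-spectrometry",
                         model_file = model_file)
  expect_length(paths, 2)    # one injected model per replicate group
  out <- readLines(paths[1])
  new_rows <- setdiff(out, model)
  expect_equal(setdiff(model, out), character())   # nothing lost
  expect_true(all(startsWith(new_rows, "\t")))
  # new rows sit inside the MS section, before OPTIONS
  expect_lt(max(which(out %in% new_rows)), which(out == "OPTIONS"))
  expect_gt(min(which(out %in% new_rows)), which(out == "MASS_SPECTROMETRY"))
  # a model without the section is rejected
  bad_file <- withr::local_tempfile(fileext = ".ftbl")
  writeLines(c("NETWORK", "\tv1\tA"), bad_file)
  expect_error(write_ftbl_ms(st, dir, "mass-spectrometry",
                             model_file = bad_file),
               "no MASS_SPECTROMETRY section")
})

test_that("OpenFLUX CSV files have one data row per mass and fractions
           summing to one", {
  sp <- simulation_spec(seed = 5)
  sim <- simulate_dataset(sp)
  asm <- assemble_fragments(sim$raw, sp$fragments,
                            leading_boundary = sim$leading_boundary)
  cfg <- run_config(corrections = c("proton-loss", "na", "obm"),
                    leading_boundary = 1)
  res <- apply_corrections(asm$dataset, cfg, obm = sim$obm)
  st <- replicate_stats(res$dataset, sim$groups)
  dir <- withr::local_tempdir()
  paths <- write_openflux_csv(st, dir)
  expect_length(paths, 2)
  csv <- utils::read.csv(paths[1])
  # Gly_246 (numC 2) has 3 rows, Ala_260 (numC 3) has 4, Ala_232 has 3
  expect_equal(nrow(csv), 10)
  sums <- tapply(csv$mean, csv$fragment, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(csv$sd >= 0))
  # an empty dataset writes nothing and warns
  empty <- st[0, ]
  expect_warning(p0 <- write_openflux_csv(empty, dir), "no replicate")
  expect_length(p0, 0)
})
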