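test_that("isotope vectors carry the shipped natural abundances", {
  tab <- default_isotope_table()
  expect_equal(isotope_vector(tab, "C"), c(0.989, 0.011))
  expect_equal(isotope_vector(tab, "Si"), c(0.922, 0.047, 0.031))
  expect_equal(isotope_vector(tab, "H"), c(1 - 0.000115, 0.000115))
  expect_equal(isotope_vector(tab, "N"), c(1 - 0.00366, 0.00366))
  expect_equal(isotope_vector(tab, "O"), c(1 - 0.00038 - 0.002,
                                           0.00038, 0.002))
  expect_equal(isotope_vector(tab, "S")[3], 0.042)
  expect_error(isotope_vector(tab, "Xx"), "not in the isotope table")
})

test_that("isotope table overrides round-trip through TSV and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("element\tshift\tabundance",
               "C\t1\t0.0107",
               "Q\t1\t0"), path)
  tab <- read_isotope_table(path)
  expect_equal(isotope_vector(tab, "C"), c(1 - 0.0107, 0.0107))
  # element with no heavy isotope behaves as identity in convolution
  expect_equal(na_distribution(c(Q = 5), tab), 1)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("element\tshift\tabundance", "C\t1\t1.2"), bad)
  expect_error(read_isotope_table(bad), "\\[0, 1\\]")
})

test_that("multinomial abundance matches closed forms and enumeration", {
  cvec <- isotope_vector(default_isotope_table(), "C")
  # single atom: probability equals the abundance itself
  expect_equal(multinomial_abundance(c(1, 0), cvec), 0.989)
  # one 13C among two carbons: both arrangements
  expect_equal(multinomial_abundance(c(1, 1), cvec), 2 * 0.989 * 0.011)
  # three light carbons
  expect_equal(multinomial_abundance(c(3, 0), cvec), 0.989^3)
  expect_error(multinomial_abundance(c(1, -1), cvec), "non-negative")
})

test_that("multinomial abundance sums over assignments to the brute-force
           shift distribution", {
  # for a single-element formula, summing the multinomial over all isotope
  # count assignments with a given total shift must equal the enumeration
  sivec <- isotope_vector(default_isotope_table(), "Si")
  n <- 4L
  ref <- brute_force_na(c(Si = n))
  for (shift in 0:4) {
    total <- 0
    for (n1 in 0:min(shift, n)) {          # n1 atoms at +1, n2 at +2
      n2 <- (shift - n1) / 2
      if (n2 == floor(n2) && n1 + n2 <= n) {
        total <- total +
          multinomial_abundance(c(n - n1 - n2, n1, n2), sivec)
      }
    }
    expect_equal(total, ref[shift + 1], tolerance = 1e-12)
  }
})

test_that("na_distribution equals the exhaustive enumeration oracle", {
  expect_equal(na_distribution("C3"), brute_force_na("C3"),
               tolerance = 1e-12)
  tab <- default_isotope_table()
  expect_equal(na_distribution("H2O", tab), brute_force_na("H2O", tab),
               tolerance = 1e-12)
  # empty formula is the identity distribution
  expect_equal(na_distribution(integer(0)), 1)

  set.seed(42)
  for (i in 1:20) {
    f <- random_formula(10L)
    expect_equal(na_distribution(f), brute_force_na(f), tolerance = 1e-12)
  }
})

test_that("na_distribution is order-independent and truncation-monotone", {
  set.seed(7)
  for (i in 1:10) {
    f <- random_formula(8L)
    perm <- sample(names(f))
    expect_equal(na_distribution(f), na_distribution(f[perm]),
                 tolerance = 1e-14)
    full <- na_distribution(f)
    for (len in 1:3) {
      expect_equal(na_distribution(f, max_len = len), full[1:len],
                   tolerance = 1e-14)
    }
  }
})

test_that("formula parsing handles counts, two-letter symbols and repeats", {
  expect_equal(parse_formula("C11H26NO2Si2"),
               c(C = 11L, H = 26L, N = 1L, O = 2L, Si = 2L))
  expect_equal(parse_formula("CHCH")[["C"]], 2L)
  expect_error(parse_formula("c3"), "cannot parse")
})

test_that("fragment definitions enforce their invariants", {
  expect_error(fragment_definition("X", "X_1", "C2H4", num_c = 3,
                                   base_mass = 100),
               "exceeds")
  expect_error(fragment_definition("X", "X_1", "H4O2", num_c = 1,
                                   base_mass = 100),
               "absent from formula")
  expect_error(fragment_definition("X", "X_1", "C2", num_c = 0,
                                   base_mass = 100),
               "at least 1")
  lib <- fragment_library()
  expect_true(all(lib$num_c >= 1))
})
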