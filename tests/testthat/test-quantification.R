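test_that("relative amounts normalise assigned intensities to 100", {
  single <- tibble::tibble(composition = "Hex8HexNAc2", intensity = 42)
  expect_equal(quantify_site(single)$rel_amount, 100)
  two <- tibble::tibble(composition = c("Hex8HexNAc2", "Hex9HexNAc2"),
                        intensity = c(3, 1))
  q <- quantify_site(two)
  expect_equal(sort(q$rel_amount), c(25, 75))
  expect_error(quantify_site(tibble::tibble()), class = "glyco_validation_error")
  # repeated compositions are summed before normalisation
  dup <- tibble::tibble(composition = c("Hex8HexNAc2", "Hex8HexNAc2", "HexNAc1"),
                        intensity = c(1, 1, 2))
  qd <- quantify_site(dup)
  expect_equal(qd$rel_amount[qd$composition == "Hex8HexNAc2"], 50)
})

test_that("columns always sum to 100 and are scale-invariant", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    asn <- tibble::tibble(composition = paste0("Hex", seq_len(n), "HexNAc2"),
                          intensity = stats::runif(n, 0.01, 1e6))
    q <- quantify_site(asn)
    expect_equal(sum(q$rel_amount), 100, tolerance = 1e-9)
    scaled <- quantify_site(dplyr::mutate(asn, intensity = intensity * 1234.5))
    expect_equal(scaled$rel_amount, q$rel_amount, tolerance = 1e-12)
  }
})

test_that("unassignable decoy peaks do not perturb the quantification", {
  cand <- enumerate_glycoforms() |> theoretical_masses("NLSLSSNR")
  spec <- sim_spec("NLSLSSNR",
                   c(Hex7HexNAc2 = 0.2, Hex8HexNAc2 = 0.5, Hex9HexNAc2 = 0.3),
                   ppm_sd = 0, intensity_cv = 0, n_decoys = 0, seed = 5)
  clean <- simulate_spectrum(spec)$peaks
  q_clean <- quantify_site(match_peaks(clean, cand, tol_ppm = 10))
  noisy <- sim_spec("NLSLSSNR",
                    c(Hex7HexNAc2 = 0.2, Hex8HexNAc2 = 0.5, Hex9HexNAc2 = 0.3),
                    ppm_sd = 0, intensity_cv = 0, n_decoys = 25,
                    decoy_min_ppm = 50, seed = 5)
  with_decoys <- simulate_spectrum(noisy)$peaks
  q_decoy <- quantify_site(match_peaks(with_decoys, cand, tol_ppm = 10))
  expect_equal(q_decoy, q_clean, tolerance = 1e-12)
})

test_that("a noise-free synthetic spectrum round-trips the generating column", {
  ref <- subex_c57y_glycoforms()
  col <- dplyr::filter(ref, site == "site1", sample == "os9", rel_amount > 0)
  props <- stats::setNames(col$rel_amount / sum(col$rel_amount), col$composition)
  sim <- simulate_spectrum(sim_spec("NLSLSSNR", props, ppm_sd = 0,
                                    intensity_cv = 0, seed = 2))
  cand <- enumerate_glycoforms() |> theoretical_masses("NLSLSSNR")
  q <- quantify_site(match_peaks(sim$peaks, cand, tol_ppm = 10))
  got <- stats::setNames(q$rel_amount, q$composition)[names(props)]
  expect_equal(unname(got), unname(100 * props), tolerance = 1e-9)
})

test_that("glycoform reports round-trip through TSV", {
  tbl <- glycoform_table(tibble::tibble(
    composition = rep(c("Hex8HexNAc2", "Hex9HexNAc2", "HexNAc1"), 2),
    site = rep(c("site1", "site2"), each = 3),
    sample = "os9",
    rel_amount = c(60.5, 30.2, 9.3, 20.0, 70.0, 10.0)
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_glycoform_report(tbl, path)
  back <- read_glycoform_report(path)
  expect_equal(dplyr::arrange(tibble::as_tibble(back), site, composition),
               dplyr::arrange(tibble::as_tibble(tbl), site, composition),
               ignore_attr = TRUE)
  # footer row is present and holds the column sums
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  expect_identical(raw$composition[nrow(raw)], "total")
  expect_error(read_glycoform_report(withr::local_tempfile()),
               class = "glyco_input_error")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "1\t2"), bad)
  expect_error(read_glycoform_report(bad), class = "glyco_parse_error")
})

test_that("the reference glycoform table has the published shape", {
  ref <- subex_c57y_glycoforms()
  cols <- dplyr::distinct(ref, site, sample)
  expect_equal(nrow(cols), 6L)
  expect_setequal(unique(ref$site), c("site1", "site2", "site3"))
  expect_setequal(unique(ref$sample), c("os9", "mns4 mns5"))
  expect_equal(length(unique(ref$composition)), 10L)
  expect_true("HexNAc1" %in% ref$composition)
  sums <- ref |>
    dplyr::group_by(site, sample) |>
    dplyr::summarise(total = sum(rel_amount), .groups = "drop")
  expect_true(all(abs(sums$total - 100) <= 0.11))
})

test_that("monoglucosylated fractions reproduce the reference columns", {
  ref <- subex_c57y_glycoforms()
  ann <- subex_c57y_monoglucosylated()
  expect_equal(monoglucosylated_fraction(ref, ann, sites = "site1",
                                         samples = "os9"), 63.7)
  expect_equal(monoglucosylated_fraction(ref, ann, sites = "site2",
                                         samples = "mns4 mns5"), 58.6)
  # averaged over sites 1-2 in both genotypes the Glc1 species is ~60%
  expect_equal(monoglucosylated_fraction(ref, ann, sites = c("site1", "site2")),
               60, tolerance = 1e-9)
  # a column whose annotated composition is absent scores 0
  small <- glycoform_table(tibble::tibble(
    composition = "Hex5HexNAc2", site = "site1", sample = "os9",
    rel_amount = 100))
  expect_equal(monoglucosylated_fraction(small, ann), 0)
  expect_error(
    monoglucosylated_fraction(ref, tibble::tibble(sample = "other",
                                                  composition = "Hex8HexNAc2")),
    class = "glyco_validation_error")
})
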