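test_that("sequon scan reports all and only N-X-S/T motifs, X != P", {
  one <- find_sequons("NLSLSSNR")
  expect_equal(one$position, 1L)
  expect_identical(one$motif, "NLS")
  expect_equal(nrow(find_sequons("NPSA")), 0L)
  two <- find_sequons("NITNTS")
  expect_equal(two$position, c(1L, 4L))
  expect_identical(two$motif, c("NIT", "NTS"))
  # sequon ending on the final residue is reported; N at the tail is not
  expect_equal(find_sequons("AANGT")$position, 3L)
  expect_equal(nrow(find_sequons("AAN")), 0L)
})

test_that("sequon scan equals a regular-expression oracle on random sequences", {
  set.seed(7)
  for (i in 1:200) {
    seq <- random_peptide(sample(3:60, 1))
    got <- find_sequons(seq)$position
    expect_identical(as.integer(got), oracle_sequons(seq), info = seq)
  }
})

test_that("tryptic digestion cleaves after K/R except before P", {
  d0 <- tryptic_digest("AKRPGR")
  expect_identical(d0$peptide, c("AK", "RPGR"))
  d1 <- tryptic_digest("AKGR", max_missed = 1)
  expect_setequal(d1$peptide, c("AK", "GR", "AKGR"))
  expect_equal(d1$missed_cleavages[d1$peptide == "AKGR"], 1L)
  expect_identical(tryptic_digest("GASVT")$peptide, "GASVT")
})

test_that("fully cleaved peptides tile the protein exactly", {
  set.seed(11)
  for (i in 1:50) {
    seq <- random_peptide(sample(5:80, 1))
    d <- tryptic_digest(seq, max_missed = 0)
    expect_identical(paste(d$peptide, collapse = ""), seq, info = seq)
    expect_equal(d$start, c(1L, utils::head(d$end, -1) + 1L), info = seq)
  }
})

test_that("peptide masses match the residue-table oracle", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-5 / 75)
  expect_equal(peptide_mass("NLSLSSNR"), 889.46174, tolerance = 1e-5 / 889)
  # fixed carbamidomethylation on cysteine
  expect_equal(peptide_mass("C"), 178.04121, tolerance = 1e-5 / 178)
  set.seed(23)
  for (i in 1:300) {
    p <- random_peptide(sample(1:40, 1))
    expect_lt(abs(peptide_mass(p) - oracle_peptide_mass(p)), 1e-4)
  }
  expect_error(peptide_mass(""), class = "glyco_validation_error")
  expect_error(peptide_mass("AXZ"), class = "glyco_validation_error")
})

test_that("glycoform enumeration covers the ranges and excludes coreless glycans", {
  hexrows <- enumerate_glycoforms(hexnac = c(2, 2), hex = c(2, 10),
                                  dhex = c(0, 0), pent = c(0, 0))
  expect_equal(nrow(hexrows), 9L)
  expect_identical(hexrows$composition[1], "Hex2HexNAc2")
  defaults <- enumerate_glycoforms()
  expect_true("HexNAc1" %in% defaults$composition)
  expect_equal(nrow(enumerate_glycoforms(c(0, 0), c(0, 0), c(0, 0), c(0, 0))), 1L)
  with_zero <- enumerate_glycoforms(hexnac = c(0, 2), hex = c(0, 2),
                                    dhex = c(0, 0), pent = c(0, 0))
  expect_false(any(with_zero$hexnac == 0 & with_zero$hex > 0))
})

test_that("theoretical glycopeptide masses obey the additive invariant", {
  cand <- enumerate_glycoforms() |> theoretical_masses("NLSLSSNR")
  pick <- function(lb) cand$neutral_mass[cand$composition == lb]
  expect_equal(pick("Hex9HexNAc2"), 2754.09590, tolerance = 1e-7)
  expect_equal(pick("HexNAc1"), 1092.54112, tolerance = 1e-7)
  expect_equal(cand$neutral_mass, peptide_mass("NLSLSSNR") + cand$glycan_mass,
               tolerance = 1e-12)
})

test_that("peak matching assigns exact peaks and respects the tolerance", {
  cand <- enumerate_glycoforms() |> theoretical_masses("NLSLSSNR")
  exact <- tibble::tibble(neutral_mass = cand$neutral_mass[5], intensity = 1)
  hit <- match_peaks(exact, cand, tol_ppm = 10)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$ppm_error, 0)
  off <- tibble::tibble(neutral_mass = cand$neutral_mass[5] * (1 + 20e-6),
                        intensity = 1)
  expect_equal(nrow(match_peaks(off, cand, tol_ppm = 10)), 0L)
  expect_equal(nrow(match_peaks(off, cand, tol_ppm = 30)), 1L)
})

test_that("matching equals the all-pairs brute-force oracle on random spectra", {
  cand <- enumerate_glycoforms() |> theoretical_masses("NLSLSSNR")
  set.seed(57)
  for (i in 1:200) {
    n <- sample(3:15, 1)
    peaks <- tibble::tibble(
      neutral_mass = sort(stats::runif(n, min(cand$neutral_mass) - 50,
                                       max(cand$neutral_mass) + 50)),
      intensity = stats::runif(n, 1, 100)
    )
    tol <- sample(c(5, 10, 50, 200, 1000), 1)
    got <- match_peaks(peaks, cand, tol_ppm = tol)
    want <- oracle_match(peaks, cand, tol)
    expect_identical(got$peak, want$peak, info = paste("spectrum", i))
    expect_identical(got$composition, want$composition, info = paste("spectrum", i))
  }
})

test_that("enlarging the tolerance never loses assignments", {
  cand <- enumerate_glycoforms() |> theoretical_masses("NLSLSSNR")
  set.seed(31)
  peaks <- tibble::tibble(
    neutral_mass = cand$neutral_mass[sample(nrow(cand), 12)] *
      (1 + stats::rnorm(12, 0, 8e-6)),
    intensity = 1
  )
  counts <- vapply(c(1, 3, 5, 10, 20, 40), function(tol) {
    nrow(match_peaks(peaks, cand, tol_ppm = tol))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("hexose ladders are detected, bridged across gaps, and not invented", {
  base <- peptide_mass("NLSLSSNR") + 2 * sugar_masses()[["hexnac"]]
  rungs <- base + (5:9) * sugar_masses()[["hex"]]
  peaks <- tibble::tibble(neutral_mass = rungs, intensity = 1)
  lad <- detect_hexose_ladder(peaks, tol_ppm = 10, min_chain = 3)
  expect_equal(length(unique(lad$ladder)), 1L)
  expect_equal(nrow(lad), 5L)
  expect_equal(lad$base_mass[1], rungs[1])
  # deleting one rung breaks the chain unless a gap is allowed
  gappy <- peaks[-3, ]
  none <- detect_hexose_ladder(gappy, tol_ppm = 10, min_chain = 3, max_gap = 0)
  expect_lt(max(c(0, table(none$ladder))), 4)
  bridged <- detect_hexose_ladder(gappy, tol_ppm = 10, min_chain = 3, max_gap = 1)
  expect_equal(nrow(bridged), 4L)
  expect_equal(bridged$rung, c(0L, 1L, 3L, 4L)) # the bridged rung stays empty
  # unrelated masses carry no ladder
  set.seed(3)
  noise <- tibble::tibble(neutral_mass = sort(stats::runif(20, 900, 1100)),
                          intensity = 1)
  expect_equal(nrow(detect_hexose_ladder(noise, tol_ppm = 5, min_chain = 3)), 0L)
})
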