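# Seeded generator of synthetic deconvoluted glycopeptide spectra and
# enzymatic digestion series with known ground truth. One pseudo-random
# stream per spectrum, fixed draw order (masses, then intensities, then
# decoys), so identical seeds give byte-identical output on any platform.

#' Specification of a synthetic glycopeptide spectrum
#'
#' Describes a deconvoluted LC-ESI-MS spectrum of one tryptic glycopeptide:
#' a fixed peptide backbone carrying a distribution of glycoforms, with
#' ppm-scale normal mass error, lognormal intensity noise (unit mean) and
#' uniform decoy peaks kept away from every theoretical candidate mass.
#'
#' @param peptide Peptide backbone sequence.
#' @param proportions Named numeric vector: composition label -> fraction
#'   (must sum to 1).
#' @param total_intensity Total true-signal intensity (arbitrary units).
#' @param ppm_sd Standard deviation of the normal mass error, in ppm.
#' @param intensity_cv Coefficient of variation of the lognormal intensity
#'   noise (0 = noise-free).
#' @param n_decoys Number of decoy peaks.
#' @param decoy_window Length-2 numeric: Da range for decoy masses (default:
#'   the candidate mass range widened by 100 Da).
#' @param decoy_min_ppm Minimum ppm offset of any decoy from every
#'   theoretical candidate mass.
#' @param site,sample Labels carried into the peak list.
#' @param seed Integer seed for the spectrum's private random stream.
#' @return A list of class `sim_spec`.
#' @examples
#' sim_spec("NLSLSSNR", c(Hex8HexNAc2 = 0.7, Hex9HexNAc2 = 0.3), seed = 1)
#' @export
sim_spec <- function(peptide, proportions, total_intensity = 1e6, ppm_sd = 3,
                     intensity_cv = 0.1, n_decoys = 0, decoy_window = NULL,
                     decoy_min_ppm = 50, site = "site1", sample = "sim",
                     seed = 1L) {
  stopifnot(is.character(peptide), length(peptide) == 1L,
            is.numeric(proportions), !is.null(names(proportions)),
            total_intensity > 0, ppm_sd >= 0, intensity_cv >= 0, n_decoys >= 0,
            decoy_min_ppm > 0)
  if (abs(sum(proportions) - 1) > 1e-9) {
    rlang::abort("glycoform proportions must sum to 1",
                 class = "glyco_validation_error")
  }
  lapply(names(proportions), parse_comp_label) # validates the labels
  structure(list(peptide = peptide, proportions = proportions,
                 total_intensity = total_intensity, ppm_sd = ppm_sd,
                 intensity_cv = intensity_cv, n_decoys = as.integer(n_decoys),
                 decoy_window = decoy_window, decoy_min_ppm = decoy_min_ppm,
                 site = site, sample = sample, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a deconvoluted glycopeptide spectrum
#'
#' One peak per glycoform at its theoretical neutral mass perturbed by
#' normal ppm error, with intensity `total_intensity * fraction` times
#' unit-mean lognormal noise, plus uniformly placed decoy peaks rejected
#' within `decoy_min_ppm` of any theoretical candidate mass (bounded
#' retries; an infeasible window errors out).
#'
#' @param spec A [sim_spec()].
#' @return A list with `peaks` (tibble: `neutral_mass`, `intensity`, `site`,
#'   `sample`, sorted by mass) and `truth` (tibble: per-peak provenance
#'   `composition` or `"decoy"`, plus the true `fraction`).
#' @examples
#' sim <- simulate_spectrum(sim_spec("NLSLSSNR",
#'   c(Hex8HexNAc2 = 0.6, Hex9HexNAc2 = 0.4), ppm_sd = 0, intensity_cv = 0,
#'   seed = 7))
#' sim$peaks
#' @export
simulate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  comps <- names(spec$proportions)
  theo <- vapply(comps, function(lb) {
    peptide_mass(spec$peptide) + comp_mass(lb)
  }, numeric(1))
  # exclusion set: every theoretical candidate in the default enumeration
  cand <- theoretical_masses(enumerate_glycoforms(), spec$peptide)$neutral_mass
  withr::with_seed(spec$seed, {
    eps <- stats::rnorm(length(theo), 0, spec$ppm_sd * 1e-6)
    masses <- theo * (1 + eps)
    sdlog <- sqrt(log(1 + spec$intensity_cv^2))
    noise <- if (spec$intensity_cv > 0) {
      exp(stats::rnorm(length(theo), -sdlog^2 / 2, sdlog))
    } else rep(1, length(theo))
    intens <- spec$total_intensity * spec$proportions * noise
    win <- spec$decoy_window %||% (range(cand) + c(-100, 100))
    decoy_mass <- numeric(0)
    decoy_int <- numeric(0)
    if (spec$n_decoys > 0) {
      for (d in seq_len(spec$n_decoys)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          m <- stats::runif(1, win[1], win[2])
          if (min(abs(m - cand) / cand * 1e6) >= spec$decoy_min_ppm) {
            decoy_mass <- c(decoy_mass, m)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          rlang::abort("could not place a decoy outside the ppm exclusion zone",
                       class = c("glyco_validation_error", "glyco_error"))
        }
      }
      decoy_int <- exp(stats::rnorm(spec$n_decoys,
                                    log(0.02 * spec$total_intensity), 1))
    }
  })
  peaks <- tibble::tibble(
    neutral_mass = unname(c(masses, decoy_mass)),
    intensity = c(unname(intens), decoy_int),
    site = spec$site, sample = spec$sample
  )
  truth <- tibble::tibble(
    neutral_mass = unname(c(masses, decoy_mass)),
    composition = c(comps, rep("decoy", spec$n_decoys)),
    fraction = c(unname(spec$proportions), rep(NA_real_, spec$n_decoys))
  )
  ord <- order(peaks$neutral_mass)
  list(peaks = peaks[ord, ], truth = truth[ord, ])
}

#' Simulate a released-glycan digestion series
#'
#' Emulates an LC-ESI-MS spectrum of PNGase-released glycans after a partial
#' exoglycosidase digestion: the enzyme is run for 0..k simultaneous-removal
#' iterations, the product composition of each iteration is converted to its
#' free reducing-glycan neutral mass, and peak intensity is proportional to
#' the supplied weight of that iteration. Iterations past the fixpoint
#' collapse onto the limit-product peak.
#'
#' @param structure A `glycan_tree`, registry name or structure string.
#' @param enzyme Currently `"jbm"`.
#' @param weights Numeric vector of intensity weights for iterations
#'   `0..length(weights)-1`; must sum to 1.
#' @param total_intensity Total intensity distributed over the peaks.
#' @return A tibble peak list (`neutral_mass`, `intensity`, `composition`),
#'   sorted by mass.
#' @examples
#' simulate_digestion_series("Glc1Man7GlcNAc2", weights = c(0, 0, 1))
#' @export
simulate_digestion_series <- function(structure, enzyme = "jbm", weights,
                                      total_intensity = 1e6) {
  if (!identical(enzyme, "jbm")) {
    rlang::abort(paste0("unknown digestion enzyme: '", enzyme, "'"),
                 class = "glyco_validation_error")
  }
  stopifnot(is.numeric(weights), length(weights) >= 1, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) {
    rlang::abort("iteration weights must sum to 1", class = "glyco_validation_error")
  }
  tree <- as_glycan_tree(structure)
  rows <- purrr::map(seq_along(weights), function(i) {
    comp <- composition_of(apply_jbm(tree, iterations = i - 1)$product)
    tibble::tibble(composition = comp_label(comp),
                   neutral_mass = comp_mass(comp, released = TRUE),
                   intensity = total_intensity * weights[i])
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$composition, .data$neutral_mass) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::filter(.data$intensity > 0) |>
    dplyr::arrange(.data$neutral_mass)
}
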