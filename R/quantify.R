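# Site-specific relative glycoform quantification and report IO. Glycoform
# tables are kept long and tidy (composition x site x sample); the TSV report
# pivots them wide in the conventional one-column-per-site layout.

#' Relative glycoform abundances for one site
#'
#' Converts assigned peak intensities to relative amounts: the percentage of
#' each composition's summed intensity over the summed intensity of all
#' assigned compositions. Unassigned peaks never enter the denominator, so
#' percentages refer to identified glycoforms and each site column sums to
#' 100. Several peaks matching one composition (isotope-cluster artifacts)
#' are summed before normalisation.
#'
#' @param assignments A data frame of assignments (from [match_peaks()])
#'   with columns `composition` and `intensity`.
#' @return A tibble with columns `composition`, `intensity` and
#'   `rel_amount` (percent, sums to 100).
#' @examples
#' match_peaks(
#'   tibble::tibble(neutral_mass = 2754.0959, intensity = 3e5),
#'   enumerate_glycoforms() |> theoretical_masses("NLSLSSNR")
#' ) |> quantify_site()
#' @export
quantify_site <- function(assignments) {
  stopifnot(is.data.frame(assignments))
  if (nrow(assignments) == 0) {
    rlang::abort("no assignments: cannot quantify an empty site",
                 class = c("glyco_validation_error", "glyco_error"))
  }
  stopifnot(all(c("composition", "intensity") %in% names(assignments)))
  out <- assignments |>
    dplyr::group_by(.data$composition) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  total <- sum(out$intensity)
  if (!is.finite(total) || total <= 0) {
    rlang::abort("total assigned intensity must be positive",
                 class = c("glyco_validation_error", "glyco_error"))
  }
  out$rel_amount <- 100 * out$intensity / total
  dplyr::arrange(out, .data$composition)
}

#' Assemble a glycoform table
#'
#' Binds per-site/per-sample quantification columns into one long tidy
#' table and validates that every (site, sample) column sums to 100.
#'
#' @param x A data frame with columns `composition`, `site`, `sample`,
#'   `rel_amount`, or a list of such data frames.
#' @param tol Column-sum tolerance (default generous enough for tables
#'   transcribed at one-decimal precision).
#' @return A tibble of class `glycoform_table`.
#' @export
glycoform_table <- function(x, tol = 0.5) {
  if (!is.data.frame(x)) x <- dplyr::bind_rows(x)
  stopifnot(all(c("composition", "site", "sample", "rel_amount") %in% names(x)))
  sums <- x |>
    dplyr::group_by(.data$site, .data$sample) |>
    dplyr::summarise(total = sum(.data$rel_amount), .groups = "drop")
  off <- abs(sums$total - 100) > tol
  if (any(off)) {
    rlang::warn(paste0("glycoform columns not summing to 100: ",
                       paste(paste0(sums$site[off], "/", sums$sample[off],
                                    " (", round(sums$total[off], 2), ")"),
                             collapse = ", ")))
  }
  out <- dplyr::arrange(tibble::as_tibble(x), .data$site, .data$sample,
                        .data$composition)
  class(out) <- c("glycoform_table", class(out))
  out
}

#' Mean relative amount of the monoglucosylated glycoform
#'
#' Averages, over the selected (site, sample) columns, the relative amount
#' of the composition annotated as monoglucosylated in each column. The
#' annotation comes from isomer inference: which isobaric composition hides
#' the Glc1 species differs between samples (e.g. Hex8HexNAc2 =
#' Glc1Man7GlcNAc2 after C/B-branch trimming, Hex9HexNAc2 = Glc1Man8GlcNAc2
#' when trimming is blocked).
#'
#' @param table A `glycoform_table`.
#' @param annotations A data frame mapping `sample` (and optionally `site`)
#'   to the monoglucosylated `composition` of that column.
#' @param sites,samples Optional filters selecting the columns to average
#'   over (default: all columns in `table`).
#' @return Mean relative amount in percent (length-1 numeric).
#' @examples
#' monoglucosylated_fraction(subex_c57y_glycoforms(),
#'                           subex_c57y_monoglucosylated())
#' @export
monoglucosylated_fraction <- function(table, annotations, sites = NULL,
                                      samples = NULL) {
  stopifnot(is.data.frame(table), is.data.frame(annotations),
            all(c("sample", "composition") %in% names(annotations)))
  sel <- tibble::as_tibble(table)
  if (!is.null(sites)) sel <- dplyr::filter(sel, .data$site %in% .env$sites)
  if (!is.null(samples)) sel <- dplyr::filter(sel, .data$sample %in% .env$samples)
  if (nrow(sel) == 0) {
    rlang::abort("no glycoform columns selected", class = "glyco_validation_error")
  }
  by <- if ("site" %in% names(annotations)) c("site", "sample") else "sample"
  ann <- dplyr::rename(annotations, mono_composition = "composition")
  cols <- dplyr::distinct(sel, .data$site, .data$sample)
  cols <- dplyr::left_join(cols, ann[, c(by, "mono_composition")], by = by)
  if (any(is.na(cols$mono_composition))) {
    miss <- cols[is.na(cols$mono_composition), ]
    rlang::abort(paste0("no monoglucosylated annotation for column(s): ",
                        paste(paste0(miss$site, "/", miss$sample), collapse = ", ")),
                 class = "glyco_validation_error")
  }
  per_col <- vapply(seq_len(nrow(cols)), function(i) {
    hit <- sel$site == cols$site[i] & sel$sample == cols$sample[i] &
      sel$composition == cols$mono_composition[i]
    if (!any(hit)) 0 else sum(sel$rel_amount[hit])
  }, numeric(1))
  mean(per_col)
}

#' Write / read a glycoform report TSV
#'
#' The wide report has a `composition` first column, one `site<k>_<sample>`
#' column per (site, sample) pair (sites ascending, samples lexicographic),
#' percentages at one decimal place, and a final `total` footer row with the
#' column sums. `read_glycoform_report()` parses the format back into a long
#' [glycoform_table()], warning when a column does not sum to 100 +- 0.5
#' (printed tables accumulate rounding).
#'
#' @param table A `glycoform_table`.
#' @param path Output/input TSV path.
#' @return `write_glycoform_report()` returns `path` invisibly;
#'   `read_glycoform_report()` returns a `glycoform_table`.
#' @export
write_glycoform_report <- function(table, path) {
  stopifnot(inherits(table, "glycoform_table"))
  wide <- table |>
    dplyr::mutate(column = paste0(.data$site, "_", .data$sample)) |>
    dplyr::arrange(.data$site, .data$sample) |>
    dplyr::select("composition", "column", "rel_amount") |>
    tidyr::pivot_wider(names_from = "column", values_from = "rel_amount",
                       values_fill = 0)
  num <- names(wide)[-1]
  total <- c(composition = "total",
             vapply(wide[num], function(v) sprintf("%.1f", sum(v)), character(1)))
  body <- wide
  body[num] <- lapply(body[num], function(v) sprintf("%.1f", v))
  body <- dplyr::bind_rows(body, tibble::as_tibble(as.list(total)))
  readr::write_tsv(body, path)
  invisible(path)
}

#' @rdname write_glycoform_report
#' @export
read_glycoform_report <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("report file not found: ", path),
                 class = c("glyco_input_error", "glyco_error"))
  }
  wide <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    composition = readr::col_character(), .default = readr::col_double())))
  if (!identical(names(wide)[1], "composition") || ncol(wide) < 2) {
    rlang::abort("malformed glycoform report: first column must be 'composition'",
                 class = c("glyco_parse_error", "glyco_error"))
  }
  wide <- dplyr::filter(wide, .data$composition != "total")
  long <- tidyr::pivot_longer(wide, -"composition", names_to = "column",
                              values_to = "rel_amount")
  parts <- stringr::str_match(long$column, "^(.*?)_(.*)$")
  if (any(is.na(parts[, 1]))) {
    rlang::abort("malformed report column names (expected <site>_<sample>)",
                 class = c("glyco_parse_error", "glyco_error"))
  }
  long$site <- parts[, 2]
  long$sample <- parts[, 3]
  glycoform_table(dplyr::select(long, "composition", "site", "sample", "rel_amount"))
}

#' Reference glycoform abundances of the SUBEX-C57Y ERAD substrate
#'
#' Relative glycoform amounts (percent of identified glycoforms, LC-ESI-MS
#' of deconvoluted glycopeptide spectra) for the misfolded ERAD substrate
#' SUBEX-C57Y expressed in the Arabidopsis `os9` and `mns4 mns5` mutants, at
#' its three N-glycosylation sites (site1 = NIT, site2 = NLS, site3 = NTS).
#' Used as the reference input for summary statistics and as ground-truth
#' proportions for synthetic spectra.
#'
#' @return A `glycoform_table` with 10 compositions x 6 columns.
#' @examples
#' subex_c57y_glycoforms()
#' @export
subex_c57y_glycoforms <- function() {
  comps <- c("HexNAc1", paste0("Hex", 2:10, "HexNAc2"))
  cols <- list(
    c(site = "site1", sample = "os9"),
    c(site = "site1", sample = "mns4 mns5"),
    c(site = "site2", sample = "os9"),
    c(site = "site2", sample = "mns4 mns5"),
    c(site = "site3", sample = "os9"),
    c(site = "site3", sample = "mns4 mns5")
  )
  vals <- cbind(
    c(3.1, 0.3, 0.6, 1.3, 1.6, 2.6, 16.4, 63.7, 5.0, 5.5),
    c(3.6, 0.1, 0.3, 0.6, 1.2, 1.4, 2.8, 12.7, 56.0, 21.3),
    c(1.6, 0.0, 1.0, 3.0, 2.5, 2.5, 6.9, 61.7, 9.7, 11.2),
    c(2.5, 0.0, 0.7, 0.0, 4.1, 3.4, 3.2, 7.4, 58.6, 20.0),
    c(0.9, 0.1, 0.6, 1.3, 2.3, 3.2, 8.4, 35.0, 19.3, 28.8),
    c(0.0, 0.0, 0.0, 0.8, 1.7, 3.1, 3.2, 8.8, 36.2, 46.2)
  )
  long <- purrr::map(seq_along(cols), function(j) {
    tibble::tibble(composition = comps, site = cols[[j]][["site"]],
                   sample = cols[[j]][["sample"]], rel_amount = vals[, j])
  })
  glycoform_table(dplyr::bind_rows(long))
}

#' Monoglucosylated-composition annotations for SUBEX-C57Y
#'
#' Which isobaric composition carries the monoglucosylated structure in each
#' genotype, as resolved by digestion and elution evidence: in `os9`
#' (C-branch trimming active) Hex8HexNAc2 = Glc1Man7GlcNAc2; in `mns4 mns5`
#' (trimming blocked) Hex9HexNAc2 = Glc1Man8GlcNAc2.
#'
#' @return A tibble with columns `sample`, `composition`, `structure`.
#' @export
subex_c57y_monoglucosylated <- function() {
  tibble::tibble(
    sample = c("os9", "mns4 mns5"),
    composition = c("Hex8HexNAc2", "Hex9HexNAc2"),
    structure = c("Glc1Man7GlcNAc2", "Glc1Man8GlcNAc2")
  )
}
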