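# Shared readers/writers, pipeline configuration and the end-to-end
# orchestration from FASTA + peak lists to a glycoform report.

#' Read / write a deconvoluted peak list TSV
#'
#' Peak lists are tab-separated with header `neutral_mass_da<TAB>intensity`
#' ('.' decimal separator); masses are deconvoluted neutral monoisotopic
#' masses, not m/z. Peaks are sorted ascending on load.
#'
#' @param path TSV path.
#' @param site,sample Optional labels attached as columns.
#' @return A tibble with columns `neutral_mass`, `intensity` and any labels.
#' @export
read_peaklist <- function(path, site = NULL, sample = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("peak list not found: ", path),
                 class = c("glyco_input_error", "glyco_error"))
  }
  out <- readr::read_tsv(path, col_types = readr::cols(
    neutral_mass_da = readr::col_double(), intensity = readr::col_double()))
  if (!all(c("neutral_mass_da", "intensity") %in% names(out))) {
    rlang::abort("malformed peak list: expected columns neutral_mass_da, intensity",
                 class = c("glyco_parse_error", "glyco_error"))
  }
  if (any(is.na(out$neutral_mass_da)) || any(out$neutral_mass_da <= 0) ||
      any(out$intensity < 0)) {
    rlang::abort("peak list must have positive masses and non-negative intensities",
                 class = c("glyco_validation_error", "glyco_error"))
  }
  out <- dplyr::arrange(dplyr::rename(out, neutral_mass = "neutral_mass_da"),
                        .data$neutral_mass)
  if (!is.null(site)) out$site <- site
  if (!is.null(sample)) out$sample <- sample
  out
}

#' @rdname read_peaklist
#' @param peaks A data frame with columns `neutral_mass` and `intensity`.
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(all(c("neutral_mass", "intensity") %in% names(peaks)))
  readr::write_tsv(
    tibble::tibble(neutral_mass_da = peaks$neutral_mass,
                   intensity = peaks$intensity),
    path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated bundle of the tunable parameters shared by the pipeline stages.
#'
#' @param tol_ppm Peak-matching tolerance in ppm (Orbitrap-class default 10).
#' @param max_missed Missed tryptic cleavages allowed.
#' @param hexnac,hex,dhex,pent Glycoform enumeration ranges `c(min, max)`.
#' @param extended_mns45 Use the extended (C- then B-branch) MNS4/MNS5 rule
#'   where the pipeline applies it.
#' @param max_glc Glucosylation bound for isomer inference.
#' @param out_dir Optional directory for report TSVs.
#' @param seed Optional integer seed passed to simulation steps.
#' @param verbose Echo the effective configuration to standard error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tol_ppm = 10, max_missed = 0, hexnac = c(1, 2),
                            hex = c(0, 12), dhex = c(0, 1), pent = c(0, 1),
                            extended_mns45 = FALSE, max_glc = 1,
                            out_dir = NULL, seed = NULL, verbose = FALSE) {
  stopifnot(tol_ppm > 0, max_missed >= 0, max_glc >= 0)
  enumerate_glycoforms(hexnac, hex, dhex, pent) # validates the ranges
  cfg <- structure(list(tol_ppm = tol_ppm, max_missed = max_missed,
                        hexnac = hexnac, hex = hex, dhex = dhex, pent = pent,
                        extended_mns45 = isTRUE(extended_mns45),
                        max_glc = max_glc, out_dir = out_dir, seed = seed,
                        verbose = isTRUE(verbose)),
                   class = "pipeline_config")
  if (cfg$verbose) {
    message("glycotrim config: tol_ppm=", tol_ppm, " max_missed=", max_missed,
            " ranges=hexnac:", paste(hexnac, collapse = "-"),
            ",hex:", paste(hex, collapse = "-"),
            ",dhex:", paste(dhex, collapse = "-"),
            ",pent:", paste(pent, collapse = "-"),
            " max_glc=", max_glc,
            if (!is.null(seed)) paste0(" seed=", seed))
  }
  cfg
}

#' Run the glycopeptide annotation pipeline
#'
#' End-to-end orchestration: read the protein, check that each requested
#' glycopeptide is a tryptic peptide of it carrying exactly one sequon,
#' enumerate glycoform candidates, match each site's deconvoluted peak list
#' at ppm tolerance, quantify relative glycoform abundances, and annotate
#' isobaric compositions by isomer inference. Reruns with identical inputs
#' give identical outputs.
#'
#' @param fasta Path to a FASTA file, or a protein tibble from
#'   [read_proteins()].
#' @param peaklists Named list/vector: site label -> peak list (TSV path or
#'   a tibble with `neutral_mass`, `intensity`).
#' @param peptides Named character vector: site label -> glycopeptide
#'   sequence (a single unnamed peptide is recycled to all sites).
#' @param sample Sample/genotype label for the report columns.
#' @param config A [pipeline_config()].
#' @return A list with `assignments` (per-site tibble), `table`
#'   (`glycoform_table`), `inference` (isomer candidates per observed
#'   composition) and `config`. With `config$out_dir` set, also writes
#'   `assignments_<site>.tsv`, `glycoform_table.tsv` and `inference.tsv`.
#' @export
run_pipeline <- function(fasta, peaklists, peptides, sample = "sample",
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  proteins <- if (is.character(fasta)) read_proteins(fasta) else as_protein_tbl(fasta)
  sites <- names(peaklists)
  if (is.null(sites) || any(sites == "")) {
    rlang::abort("peaklists must be named by site label",
                 class = c("glyco_validation_error", "glyco_error"))
  }
  if (is.null(names(peptides)) && length(peptides) == 1L) {
    peptides <- stats::setNames(rep(peptides, length(sites)), sites)
  }
  if (!all(sites %in% names(peptides))) {
    rlang::abort("every site needs a peptide", class = "glyco_validation_error")
  }
  sequons <- find_sequons(proteins)
  if (nrow(sequons) == 0) {
    rlang::abort("no N-glycosylation sequon in the supplied protein(s)",
                 class = c("glyco_validation_error", "glyco_error"))
  }
  digest <- tryptic_digest(proteins, max_missed = config$max_missed)
  glycoforms <- enumerate_glycoforms(config$hexnac, config$hex,
                                     config$dhex, config$pent)
  per_site <- purrr::map(sites, function(s) {
    pep <- peptides[[s]]
    hit <- digest[digest$peptide == pep, , drop = FALSE]
    if (nrow(hit) == 0) {
      rlang::abort(paste0("'", pep, "' is not a tryptic peptide of the protein(s)"),
                   class = c("glyco_validation_error", "glyco_error"))
    }
    n_seq <- sum(sequons$id == hit$id[1] &
                   sequons$position >= hit$start[1] &
                   sequons$position <= hit$end[1])
    if (n_seq == 0) {
      rlang::abort(paste0("no sequon in requested peptide '", pep, "'"),
                   class = c("glyco_validation_error", "glyco_error"))
    }
    if (n_seq > 1) {
      rlang::warn(paste0("peptide '", pep, "' carries ", n_seq,
                         " sequons; site-specific assignment is ambiguous"))
    }
    pk <- peaklists[[s]]
    if (is.character(pk)) pk <- read_peaklist(pk)
    cand <- theoretical_masses(glycoforms, pep)
    asn <- match_peaks(pk, cand, tol_ppm = config$tol_ppm)
    asn$site <- s
    asn$sample <- sample
    asn
  })
  names(per_site) <- sites
  table <- glycoform_table(purrr::map(sites, function(s) {
    q <- quantify_site(per_site[[s]])
    q$site <- s
    q$sample <- sample
    q
  }))
  observed <- unique(unlist(purrr::map(per_site, "composition")))
  observed <- observed[vapply(observed, function(lb) {
    as_glycan_comp(lb)[["hexnac"]] == 2
  }, logical(1))]
  inference <- dplyr::bind_rows(purrr::map(sort(observed), function(lb) {
    res <- suppressWarnings(infer_isomer(lb, max_glc = config$max_glc))
    if (nrow(res)) res$observed <- lb
    res
  }))
  out <- list(assignments = per_site, table = table, inference = inference,
              config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in sites) {
      readr::write_tsv(per_site[[s]],
                       file.path(config$out_dir, paste0("assignments_", s, ".tsv")))
    }
    write_glycoform_report(table, file.path(config$out_dir, "glycoform_table.tsv"))
    readr::write_tsv(inference, file.path(config$out_dir, "inference.tsv"))
  }
  out
}
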