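# Protein-side operations: FASTA input, sequon scanning, in-silico trypsin
# digestion and peptide monoisotopic masses.

.aa_formulas <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2", P = "C5H7NO",  V = "C5H9NO",
  T = "C4H7NO2", C = "C3H5NOS",  L = "C6H11NO", I = "C6H11NO", N = "C4H6N2O2",
  D = "C4H5NO3", Q = "C5H8N2O2", K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",
  H = "C6H7N3O", F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2", W = "C11H10N2O"
)

.aa_residue_masses <- function() formula_mass(.aa_formulas)

# fixed S-carbamidomethylation of cysteines (iodoacetamide alkylation)
.cam_mass <- function() unname(formula_mass("C2H3NO"))

#' Read protein sequences from FASTA
#'
#' @param path Path to an amino-acid FASTA file.
#' @return A tibble with columns `id` (first word of the header) and
#'   `sequence`.
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("FASTA file not found: ", path),
                 class = c("glyco_input_error", "glyco_error"))
  }
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    id = vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L),
    sequence = as.character(aa)
  )
}

as_protein_tbl <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein", seq_along(proteins))
    proteins <- tibble::tibble(id = ids, sequence = unname(proteins))
  }
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  if (any(nchar(proteins$sequence) == 0)) {
    rlang::abort("empty protein sequence", class = "glyco_validation_error")
  }
  bad <- grepl(paste0("[^", paste(names(.aa_formulas), collapse = ""), "]"),
               proteins$sequence)
  if (any(bad)) {
    rlang::abort(paste0("non-standard residues in sequence of: ",
                        paste(proteins$id[bad], collapse = ", ")),
                 class = "glyco_validation_error")
  }
  tibble::as_tibble(proteins)
}

#' Find N-glycosylation sequons
#'
#' Scans for the N-glycosylation consensus Asn-X-Ser/Thr with X any amino
#' acid except proline. Overlapping sequons are all reported; the sequon's
#' last residue may be the protein's final residue.
#'
#' @param proteins A data frame with columns `id` and `sequence` (as from
#'   [read_proteins()]), or a character vector of sequences.
#' @return A tibble with columns `id`, `position` (1-based index of the
#'   asparagine) and `motif` (the three-residue window).
#' @examples
#' find_sequons("NLSLSSNR")
#' find_sequons("NITNTS")   # overlapping sequons at 1 and 4
#' @export
find_sequons <- function(proteins) {
  proteins <- as_protein_tbl(proteins)
  one <- function(id, seq) {
    n <- nchar(seq)
    if (n < 3) return(NULL)
    ch <- strsplit(seq, "")[[1]]
    pos <- which(ch[seq_len(n - 2)] == "N" &
                   ch[seq(2, n - 1)] != "P" &
                   ch[seq(3, n)] %in% c("S", "T"))
    if (length(pos) == 0) return(NULL)
    tibble::tibble(id = id, position = pos,
                   motif = substring(seq, pos, pos + 2))
  }
  out <- purrr::map2(proteins$id, proteins$sequence, one)
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(id = character(), position = integer(), motif = character()))
  }
  dplyr::arrange(out, .data$id, .data$position)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine and arginine, except when the next residue
#' is proline, and emits every peptide with up to `max_missed` internal
#' missed cleavage sites.
#'
#' @inheritParams find_sequons
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return A tibble with columns `id`, `peptide`, `start`, `end` (1-based
#'   inclusive) and `missed_cleavages`.
#' @examples
#' tryptic_digest("AKRPGR")              # KR|P is not cleaved
#' tryptic_digest("AKGR", max_missed = 1)
#' @export
tryptic_digest <- function(proteins, max_missed = 0) {
  stopifnot(max_missed >= 0)
  proteins <- as_protein_tbl(proteins)
  one <- function(id, seq) {
    n <- nchar(seq)
    ch <- strsplit(seq, "")[[1]]
    cut <- which(ch %in% c("K", "R"))
    cut <- cut[cut < n & ch[cut + 1L] != "P"]
    cut <- c(cut[cut < n], n)                 # segment end positions
    starts <- c(1L, utils::head(cut, -1) + 1L)
    segs <- tibble::tibble(start = starts, end = cut)
    out <- purrr::map(seq_len(nrow(segs)), function(i) {
      js <- i:min(nrow(segs), i + max_missed)
      tibble::tibble(id = id,
                     peptide = substring(seq, segs$start[i], segs$end[js]),
                     start = segs$start[i], end = segs$end[js],
                     missed_cleavages = js - i)
    })
    dplyr::bind_rows(out)
  }
  dplyr::bind_rows(purrr::map2(proteins$id, proteins$sequence, one))
}

#' Monoisotopic peptide mass
#'
#' Sums residue monoisotopic masses (computed from atomic masses) plus one
#' water, with the fixed carbamidomethyl modification (+57.021464 Da) applied
#' to every cysteine; variable modifications are not supported.
#'
#' @param peptide Character vector of peptide sequences (standard residues).
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' peptide_mass("NLSLSSNR")
#' @export
peptide_mass <- function(peptide) {
  stopifnot(is.character(peptide))
  if (any(is.na(peptide)) || any(nchar(peptide) == 0)) {
    rlang::abort("empty peptide sequence", class = "glyco_validation_error")
  }
  masses <- .aa_residue_masses()
  w <- .water_mass()
  cam <- .cam_mass()
  vapply(peptide, function(p) {
    ch <- strsplit(p, "")[[1]]
    if (!all(ch %in% names(masses))) {
      rlang::abort(paste0("non-standard residue in peptide: '", p, "'"),
                   class = "glyco_validation_error")
    }
    sum(masses[ch]) + w + cam * sum(ch == "C")
  }, numeric(1), USE.NAMES = FALSE)
}
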