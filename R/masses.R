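# Monoisotopic atomic masses (IUPAC 2021); >= 6 decimals because glycopeptide
# matching is ppm-scale on kDa neutral masses.
.atomic_masses <- c(
  C = 12.000000,
  H = 1.007825032,
  N = 14.003074004,
  O = 15.994914620,
  S = 31.972071174
)

#' Monoisotopic mass of a CHNOS molecular formula
#'
#' Computes the monoisotopic mass of a condensed molecular formula such as
#' `"C6H10O5"` from tabulated atomic masses. Only the elements C, H, N, O and
#' S are supported, which covers unmodified peptides and neutral glycans.
#'
#' @param formula Character vector of condensed formulas, e.g. `"C8H13NO5"`.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' formula_mass("H2O")
#' formula_mass("C6H10O5") # hexose residue
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula))
  vapply(formula, function(f) {
    m <- gregexpr("([CHNOS])([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    if (length(parts) == 0L || sum(attr(m, "match.length")) != nchar(f)) {
      rlang::abort(paste0("cannot parse molecular formula: '", f, "'"),
                   class = "glyco_parse_error")
    }
    el <- substr(parts, 1L, 1L)
    n <- as.integer(sub("^[CHNOS]", "", paste0(parts, "")))
    n[is.na(n)] <- 1L
    sum(.atomic_masses[el] * n)
  }, numeric(1), USE.NAMES = TRUE)
}

# residue (dehydrated) formulas of the monosaccharide classes
.sugar_formulas <- c(
  hex    = "C6H10O5",
  hexnac = "C8H13NO5",
  dhex   = "C6H10O4",
  pent   = "C5H8O4"
)

#' Monoisotopic residue masses of the monosaccharide classes
#'
#' @return Named numeric vector with elements `hex`, `hexnac`, `dhex`, `pent`
#'   (residue masses, i.e. after loss of water on glycosidic bond formation).
#' @export
sugar_masses <- function() formula_mass(.sugar_formulas)

.water_mass <- function() unname(formula_mass("H2O"))

#' Glycan composition
#'
#' A glycan composition counts monosaccharide residues by mass class: hexose
#' (Glc and Man are indistinguishable by MS), N-acetylhexosamine,
#' deoxyhexose and pentose. Compositions are the unit of glycopeptide
#' identification and quantification; structures (trees) refine them.
#'
#' @param hex,hexnac,dhex,pent Non-negative integer counts.
#' @return An object of class `glycan_comp`.
#' @examples
#' glycan_comp(hex = 9, hexnac = 2)
#' comp_label(glycan_comp(hex = 8, hexnac = 2))
#' @export
glycan_comp <- function(hex = 0, hexnac = 0, dhex = 0, pent = 0) {
  x <- c(hex = hex, hexnac = hexnac, dhex = dhex, pent = pent)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    rlang::abort("composition counts must be non-negative integers",
                 class = "glyco_validation_error")
  }
  structure(as.integer(round(x)), names = names(x), class = "glycan_comp")
}

#' @export
print.glycan_comp <- function(x, ...) {
  cat("<glycan_comp> ", comp_label(x), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.glycan_comp <- function(e1, e2) {
  if (.Generic %in% c("+", "-")) {
    out <- unclass(e1)
    out <- get(.Generic)(out, unclass(e2))
    return(glycan_comp(out[["hex"]], out[["hexnac"]], out[["dhex"]], out[["pent"]]))
  }
  if (.Generic == "==") return(all(unclass(e1) == unclass(e2)))
  if (.Generic == "!=") return(!all(unclass(e1) == unclass(e2)))
  rlang::abort(paste0("operation '", .Generic, "' not defined for glycan_comp"))
}

#' Display label of a glycan composition
#'
#' Formats a composition in the `HexN HexNAcM` nomenclature used in
#' glycoproteomics reports (e.g. `"Hex9HexNAc2"`, `"HexNAc1"`). Classes with a
#' zero count are omitted; the empty composition is labelled `"Hex0HexNAc0"`.
#'
#' @param comp A `glycan_comp`.
#' @return A character scalar.
#' @export
comp_label <- function(comp) {
  stopifnot(inherits(comp, "glycan_comp"))
  parts <- c(
    if (comp[["hex"]] > 0) paste0("Hex", comp[["hex"]]),
    if (comp[["hexnac"]] > 0) paste0("HexNAc", comp[["hexnac"]]),
    if (comp[["dhex"]] > 0) paste0("dHex", comp[["dhex"]]),
    if (comp[["pent"]] > 0) paste0("Pent", comp[["pent"]])
  )
  if (length(parts) == 0) "Hex0HexNAc0" else paste(parts, collapse = "")
}

#' Parse a composition label
#'
#' Inverse of [comp_label()]: turns a label such as `"Hex8HexNAc2"` back into
#' a `glycan_comp`.
#'
#' @param label Character scalar.
#' @return A `glycan_comp`.
#' @export
parse_comp_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  pat <- "(Hex(?!NAc)|HexNAc|dHex|Pent)([0-9]+)"
  m <- gregexpr(pat, label, perl = TRUE)[[1]]
  parts <- regmatches(label, list(m))[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(label)) {
    rlang::abort(paste0("cannot parse composition label: '", label, "'"),
                 class = "glyco_parse_error")
  }
  counts <- c(hex = 0L, hexnac = 0L, dhex = 0L, pent = 0L)
  key <- c(Hex = "hex", HexNAc = "hexnac", dHex = "dhex", Pent = "pent")
  for (p in parts) {
    cls <- key[[sub("[0-9]+$", "", p)]]
    counts[[cls]] <- counts[[cls]] + as.integer(sub("^[A-Za-z]+", "", p))
  }
  glycan_comp(counts[["hex"]], counts[["hexnac"]], counts[["dhex"]], counts[["pent"]])
}

as_glycan_comp <- function(x) {
  if (inherits(x, "glycan_comp")) x else parse_comp_label(x)
}

#' Neutral monoisotopic mass of a glycan composition
#'
#' Sums residue masses over the composition. By default the glycan is treated
#' as peptide-bound (residue masses only); with `released = TRUE` one water
#' is added, giving the mass of the free reducing glycan as obtained after
#' PNGase release.
#'
#' @param comp A `glycan_comp` or a composition label.
#' @param released Logical; add one water for a free reducing-end glycan.
#' @return Monoisotopic mass in Da.
#' @examples
#' comp_mass(glycan_comp(hex = 9, hexnac = 2))
#' comp_mass("Hex5HexNAc2", released = TRUE)
#' @export
comp_mass <- function(comp, released = FALSE) {
  comp <- as_glycan_comp(comp)
  sm <- sugar_masses()
  sum(unclass(comp) * sm[names(comp)]) + if (isTRUE(released)) .water_mass() else 0
}
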