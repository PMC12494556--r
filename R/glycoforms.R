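# Glycoform enumeration, theoretical glycopeptide mass tables, ppm-tolerance
# peak matching and hexose-ladder detection.

#' Enumerate glycan compositions within per-class ranges
#'
#' Full Cartesian product of HexNAc/Hex/dHex/Pent counts within the given
#' ranges, excluding chemically implausible compositions with no HexNAc but
#' other residues present (N-glycans are built on a GlcNAc core). Default
#' ranges cover the oligomannosidic series plus the single-GlcNAc remnant.
#'
#' @param hexnac,hex,dhex,pent Length-2 integer vectors `c(min, max)`.
#' @return A tibble with columns `hexnac`, `hex`, `dhex`, `pent` and
#'   `composition` (label), in deterministic ascending order.
#' @examples
#' enumerate_glycoforms(hexnac = c(2, 2), hex = c(2, 10),
#'                      dhex = c(0, 0), pent = c(0, 0))
#' @export
enumerate_glycoforms <- function(hexnac = c(1, 2), hex = c(0, 12),
                                 dhex = c(0, 1), pent = c(0, 1)) {
  rng <- function(r, what) {
    if (length(r) == 1) r <- c(r, r)
    if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
      rlang::abort(paste0("invalid range for ", what),
                   class = "glyco_validation_error")
    }
    seq.int(r[1], r[2])
  }
  grid <- tidyr::expand_grid(hexnac = rng(hexnac, "hexnac"), hex = rng(hex, "hex"),
                             dhex = rng(dhex, "dhex"), pent = rng(pent, "pent"))
  grid <- dplyr::filter(grid, !(.data$hexnac == 0 &
                                  (.data$hex + .data$dhex + .data$pent) > 0))
  grid <- dplyr::arrange(grid, .data$hexnac, .data$hex, .data$dhex, .data$pent)
  grid$composition <- vapply(seq_len(nrow(grid)), function(i) {
    comp_label(glycan_comp(grid$hex[i], grid$hexnac[i], grid$dhex[i], grid$pent[i]))
  }, character(1))
  grid
}

#' Theoretical glycopeptide masses
#'
#' Attaches one glycan per composition to a peptide backbone and computes
#' neutral monoisotopic masses (peptide mass plus glycan residue masses; the
#' glycosidic bond to Asn costs no water because residue masses are already
#' dehydrated).
#'
#' @param glycoforms A tibble from [enumerate_glycoforms()] (columns
#'   `hexnac`, `hex`, `dhex`, `pent`).
#' @param peptide A single peptide sequence.
#' @return The input tibble with `peptide`, `glycan_mass` and `neutral_mass`
#'   columns added.
#' @examples
#' enumerate_glycoforms() |> theoretical_masses("NLSLSSNR")
#' @export
theoretical_masses <- function(glycoforms, peptide) {
  stopifnot(is.data.frame(glycoforms),
            all(c("hexnac", "hex", "dhex", "pent") %in% names(glycoforms)),
            is.character(peptide), length(peptide) == 1L)
  pm <- peptide_mass(peptide)
  sm <- sugar_masses()
  out <- tibble::as_tibble(glycoforms)
  if (!"composition" %in% names(out)) {
    out$composition <- vapply(seq_len(nrow(out)), function(i) {
      comp_label(glycan_comp(out$hex[i], out$hexnac[i], out$dhex[i], out$pent[i]))
    }, character(1))
  }
  out$peptide <- peptide
  out$glycan_mass <- out$hex * sm[["hex"]] + out$hexnac * sm[["hexnac"]] +
    out$dhex * sm[["dhex"]] + out$pent * sm[["pent"]]
  out$neutral_mass <- pm + out$glycan_mass
  out
}

#' Match deconvoluted peaks to glycopeptide candidates
#'
#' Assigns each peak to the candidate with the smallest absolute ppm error
#' within tolerance; a candidate can win at most one peak (the peak with the
#' smaller |ppm| error; ties go to the lower peak mass), and a peak choosing
#' between equally distant candidates takes the lower candidate mass.
#'
#' @param peaks A data frame with columns `neutral_mass` and `intensity`
#'   (deconvoluted neutral masses, not m/z).
#' @param candidates A data frame with columns `composition` and
#'   `neutral_mass` (as from [theoretical_masses()]).
#' @param tol_ppm Matching tolerance in parts per million (> 0).
#' @return A tibble of assignments: `peak`, `neutral_mass`, `intensity`,
#'   `composition`, `theoretical_mass`, `ppm_error` (signed). Unassigned
#'   peaks are dropped.
#' @export
match_peaks <- function(peaks, candidates, tol_ppm = 10) {
  stopifnot(is.data.frame(peaks), all(c("neutral_mass", "intensity") %in% names(peaks)),
            is.data.frame(candidates),
            all(c("composition", "neutral_mass") %in% names(candidates)),
            tol_ppm > 0)
  empty <- tibble::tibble(peak = integer(), neutral_mass = numeric(),
                          intensity = numeric(), composition = character(),
                          theoretical_mass = numeric(), ppm_error = numeric())
  if (nrow(peaks) == 0 || nrow(candidates) == 0) return(empty)
  # per peak: best candidate within tolerance
  best <- purrr::map(seq_len(nrow(peaks)), function(i) {
    ppm <- (peaks$neutral_mass[i] - candidates$neutral_mass) /
      candidates$neutral_mass * 1e6
    ok <- which(abs(ppm) <= tol_ppm)
    if (length(ok) == 0) return(NULL)
    ok <- ok[order(abs(ppm[ok]), candidates$neutral_mass[ok])]
    j <- ok[1]
    tibble::tibble(peak = i, neutral_mass = peaks$neutral_mass[i],
                   intensity = peaks$intensity[i],
                   composition = candidates$composition[j],
                   theoretical_mass = candidates$neutral_mass[j],
                   ppm_error = ppm[j])
  })
  out <- dplyr::bind_rows(best)
  if (nrow(out) == 0) return(empty)
  # per candidate: best peak wins, others are unassigned
  out <- dplyr::arrange(out, abs(.data$ppm_error), .data$neutral_mass)
  out <- dplyr::distinct(out, .data$composition, .keep_all = TRUE)
  dplyr::arrange(out, .data$peak)
}

#' Detect hexose ladders in a peak list
#'
#' Finds maximal chains of peaks whose consecutive mass differences equal
#' the hexose residue mass (162.0528 Da) within a ppm tolerance — the
#' characteristic mass-shift pattern of glycoforms sharing a peptide
#' backbone. Up to `max_gap` missing rungs may be bridged.
#'
#' @inheritParams match_peaks
#' @param min_chain Minimum number of member peaks to report (>= 2).
#' @param max_gap Maximum number of consecutive missing rungs bridged.
#' @return A tibble with one row per ladder member: `ladder` (id), `rung`
#'   (hexose index, base = 0), `peak` (row in `peaks`), `neutral_mass`,
#'   `base_mass`.
#' @export
detect_hexose_ladder <- function(peaks, tol_ppm = 10, min_chain = 2, max_gap = 0) {
  stopifnot(is.data.frame(peaks), "neutral_mass" %in% names(peaks),
            min_chain >= 2, max_gap >= 0, tol_ppm > 0)
  hx <- sugar_masses()[["hex"]]
  ord <- order(peaks$neutral_mass)
  mz <- peaks$neutral_mass[ord]
  n <- length(mz)
  used <- rep(FALSE, n)
  ladders <- list()
  for (s in seq_len(n)) {
    if (used[s]) next
    chain <- s
    rungs <- 0L
    cur <- s
    repeat {
      found <- FALSE
      for (k in seq_len(max_gap + 1L)) {
        expect <- mz[cur] + k * hx
        err <- abs(mz - expect) / expect * 1e6
        cand <- which(err <= tol_ppm & !used & seq_len(n) > cur)
        if (length(cand)) {
          nxt <- cand[which.min(err[cand])]
          chain <- c(chain, nxt)
          rungs <- c(rungs, rungs[length(rungs)] + k)
          cur <- nxt
          found <- TRUE
          break
        }
      }
      if (!found) break
    }
    if (length(chain) >= min_chain) {
      used[chain] <- TRUE
      ladders[[length(ladders) + 1L]] <- tibble::tibble(
        ladder = length(ladders) + 1L, rung = rungs,
        peak = ord[chain], neutral_mass = mz[chain], base_mass = mz[chain[1]]
      )
    }
  }
  if (length(ladders) == 0) {
    return(tibble::tibble(ladder = integer(), rung = integer(), peak = integer(),
                          neutral_mass = numeric(), base_mass = numeric()))
  }
  dplyr::bind_rows(ladders)
}
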