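# Independent oracles used across the suite. These deliberately use
# different data sources / algorithms from the package implementation:
# literature residue-mass tables instead of elemental formulas, regex
# instead of a position scan, all-pairs loops instead of vectorised
# matching, depth-first recursion instead of breadth-first search.

# monoisotopic amino-acid residue masses (standard literature table)
ORACLE_AA <- c(
  G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527638,
  V = 99.0684139, T = 101.0476785, C = 103.0091848, L = 113.0840640,
  I = 113.0840640, N = 114.0429274, D = 115.0269430, Q = 128.0585775,
  K = 128.0949630, E = 129.0425931, M = 131.0404849, H = 137.0589119,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793129
)
ORACLE_WATER <- 18.0105647
ORACLE_CAM <- 57.0214637
# monosaccharide residue masses (standard literature table)
ORACLE_SUGAR <- c(hex = 162.0528234, hexnac = 203.0793725,
                  dhex = 146.0579088, pent = 132.0422587)

oracle_peptide_mass <- function(p) {
  ch <- strsplit(p, "")[[1]]
  sum(ORACLE_AA[ch]) + ORACLE_WATER + ORACLE_CAM * sum(ch == "C")
}

oracle_sequons <- function(seq) {
  m <- gregexpr("N(?=[^P][ST])", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

# all-pairs nearest-neighbour matcher with the same assignment semantics:
# each peak takes its nearest candidate within tolerance (tie: lower
# candidate mass); each candidate keeps only its best peak (tie: lower peak
# mass).
oracle_match <- function(peaks, candidates, tol_ppm) {
  picks <- list()
  for (i in seq_len(nrow(peaks))) {
    best_j <- NA_integer_
    best_ppm <- Inf
    for (j in seq_len(nrow(candidates))) {
      ppm <- (peaks$neutral_mass[i] - candidates$neutral_mass[j]) /
        candidates$neutral_mass[j] * 1e6
      if (abs(ppm) > tol_ppm) next
      if (abs(ppm) < abs(best_ppm) - 1e-12 ||
          (abs(abs(ppm) - abs(best_ppm)) <= 1e-12 && !is.na(best_j) &&
           candidates$neutral_mass[j] < candidates$neutral_mass[best_j])) {
        best_j <- j
        best_ppm <- ppm
      }
    }
    if (!is.na(best_j)) {
      picks[[length(picks) + 1]] <- list(peak = i, cand = best_j, ppm = best_ppm)
    }
  }
  kept <- list()
  for (p in picks) {
    key <- as.character(p$cand)
    if (is.null(kept[[key]])) {
      kept[[key]] <- p
    } else {
      old <- kept[[key]]
      better <- abs(p$ppm) < abs(old$ppm) - 1e-12 ||
        (abs(abs(p$ppm) - abs(old$ppm)) <= 1e-12 &&
         peaks$neutral_mass[p$peak] < peaks$neutral_mass[old$peak])
      if (better) kept[[key]] <- p
    }
  }
  if (length(kept) == 0) {
    return(data.frame(peak = integer(), composition = character()))
  }
  out <- do.call(rbind, lapply(kept, function(p) {
    data.frame(peak = p$peak, composition = candidates$composition[p$cand])
  }))
  out[order(out$peak), , drop = FALSE]
}

# depth-first recursive closure over the enzyme rules; tracks the best
# (smallest) depth per state so depth-limited enumeration is exact
oracle_reachable <- function(start, rules, max_steps) {
  best <- new.env(parent = emptyenv())
  visit <- function(tree, depth) {
    key <- format_structure(tree)
    prev <- if (exists(key, envir = best, inherits = FALSE)) get(key, envir = best) else Inf
    if (prev <= depth) return(invisible())
    assign(key, depth, envir = best)
    if (depth >= max_steps) return(invisible())
    for (rule in rules) {
      for (res in glycotrim:::.rule_steps(tree, rule)) visit(res$product, depth + 1)
    }
  }
  visit(glycotrim:::as_glycan_tree(start), 0)
  sort(ls(envir = best))
}

random_peptide <- function(len) {
  paste(sample(names(ORACLE_AA), len, replace = TRUE), collapse = "")
}
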