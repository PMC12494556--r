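# Deterministic rewrite rules for the ER N-glycan processing enzymes and the
# diagnostic glycosidases. Every rule consumes a glycan_tree and returns a
# digestion_result; a tree that does not satisfy the rule's substrate
# requirement raises a condition of class "glyco_not_substrate".

not_substrate <- function(enzyme, why) {
  rlang::abort(paste0(enzyme, ": not a substrate (", why, ")"),
               class = c("glyco_not_substrate", "glyco_error"))
}

digestion_result <- function(product, released, steps) {
  structure(list(product = product, released = released, steps = steps),
            class = "digestion_result")
}

#' @export
print.digestion_result <- function(x, ...) {
  rel <- if (length(x$released)) {
    paste(vapply(x$released, comp_label, character(1)), collapse = ", ")
  } else "none"
  cat("<digestion_result>\n",
      "  steps:    ", paste(x$steps, collapse = " -> "), "\n",
      "  product:  ", comp_label(composition_of(x$product)),
      " (", structure_name(x$product), ")\n",
      "  released: ", rel, "\n", sep = "")
  invisible(x)
}

.terminal_with <- function(tree, sugar, linkage_prefix = NULL, linkage = NULL) {
  ids <- terminal_residues(tree)
  i <- match(ids, tree$residue_id)
  keep <- tree$sugar[i] == sugar
  if (!is.null(linkage)) keep <- keep & tree$linkage[i] %in% linkage
  if (!is.null(linkage_prefix))
    keep <- keep & startsWith(tree$linkage[i], linkage_prefix)
  ids[keep & !is.na(keep)]
}

#' Glucosidase I (GCSI): remove the terminal alpha-1,2 glucose
#'
#' GCSI removes the single outermost alpha-1,2-linked glucose of the
#' triglucose cap on branch A, the first processing step after transfer of
#' Glc3Man9GlcNAc2 to the nascent chain.
#'
#' @param tree A `glycan_tree`, registry name or structure string.
#' @return A `digestion_result` (product tree, released compositions, step log).
#' @examples
#' apply_gcs1(glycan_canonical("Glc3Man9GlcNAc2"))
#' @export
apply_gcs1 <- function(tree) {
  tree <- as_glycan_tree(tree)
  hit <- .terminal_with(tree, "Glc", linkage = "a1-2")
  if (length(hit) == 0) not_substrate("GCSI", "no terminal alpha-1,2 Glc")
  digestion_result(remove_residues(tree, hit[1], "GCSI"),
                   list(glycan_comp(hex = 1)), "GCSI")
}

#' Glucosidase II (GCSII): remove one terminal alpha-1,3 glucose
#'
#' GCSII trims the two inner alpha-1,3-linked glucoses one at a time;
#' complete deglucosylation releases the glycoprotein from the
#' calnexin/calreticulin lectin cycle.
#'
#' @inheritParams apply_gcs1
#' @return A `digestion_result`.
#' @examples
#' apply_gcs2(glycan_canonical("Glc1Man9GlcNAc2")) # -> Man9GlcNAc2
#' @export
apply_gcs2 <- function(tree) {
  tree <- as_glycan_tree(tree)
  hit <- .terminal_with(tree, "Glc", linkage = "a1-3")
  if (length(hit) == 0) not_substrate("GCSII", "no terminal alpha-1,3 Glc")
  digestion_result(remove_residues(tree, hit[1], "GCSII"),
                   list(glycan_comp(hex = 1)), "GCSII")
}

#' UGGT: reglucosylate the A-branch tip
#'
#' The folding sensor UDP-glucose:glycoprotein glucosyltransferase adds one
#' alpha-1,3 glucose back onto the terminal A-branch mannose of a fully
#' deglucosylated glycan, returning a misfolded glycoprotein to the
#' calnexin/calreticulin cycle. It requires a glucose-free glycan with the
#' A-tip mannose present and terminal: after endomannosidase has removed the
#' Glc-alpha-1,3-Man disaccharide the acceptor is gone and reglucosylation
#' is permanently blocked.
#'
#' @inheritParams apply_gcs1
#' @return A `digestion_result` (nothing released; residue count +1).
#' @examples
#' apply_uggt(glycan_canonical("Man9GlcNAc2")) # -> Glc1Man9GlcNAc2
#' @export
apply_uggt <- function(tree) {
  tree <- as_glycan_tree(tree)
  if (glc_count(tree) > 0) not_substrate("UGGT", "glycan already glucosylated")
  if (!has_residue(tree, .pos$a_tip) || !(.pos$a_tip %in% terminal_residues(tree)))
    not_substrate("UGGT", "A-branch tip mannose absent or not terminal")
  res <- tibble::add_row(tibble::as_tibble(tree),
                         residue_id = .pos$glc1, sugar = "Glc",
                         linkage = "a1-3", branch = "cap", parent = .pos$a_tip)
  digestion_result(new_glycan_tree(res, c(attr(tree, "provenance"), "UGGT")),
                   list(), "UGGT")
}

#' MNS4/MNS5: trim the C-branch (and optionally B-branch) tip mannose
#'
#' The EDEM-type alpha-mannosidases MNS4 and MNS5 hydrolyse the terminal
#' alpha-1,2 mannose of the C-branch, exposing the alpha-1,6-linked mannose
#' that the lectin OS9 reads as a degradation signal (see
#' [os9_signal_exposed()]). With `extended = TRUE` the B-branch tip mannose
#' is also removed, yielding the fully processed form (Glc1Man9GlcNAc2 ->
#' Glc1Man7GlcNAc2); whether a second ER mannosidase performs the B-branch
#' trim is left open, so both behaviours are exposed behind the flag. If
#' the B-tip is already absent the extended call removes only the C-tip.
#'
#' @inheritParams apply_gcs1
#' @param extended Logical; also remove the B-branch tip mannose.
#' @return A `digestion_result`.
#' @examples
#' apply_mns45("Glc1Man9GlcNAc2", extended = TRUE) # -> Glc1Man7GlcNAc2
#' @export
apply_mns45 <- function(tree, extended = FALSE) {
  tree <- as_glycan_tree(tree)
  ok <- has_residue(tree, .pos$c_tip) &&
    .pos$c_tip %in% terminal_residues(tree) &&
    tree$sugar[match(.pos$c_tip, tree$residue_id)] == "Man"
  if (!ok) not_substrate("MNS4/MNS5", "C-branch tip mannose absent or not terminal")
  ids <- .pos$c_tip
  steps <- "MNS4/MNS5(C)"
  if (isTRUE(extended) && has_residue(tree, .pos$b_tip) &&
      .pos$b_tip %in% terminal_residues(tree)) {
    ids <- c(ids, .pos$b_tip)
    steps <- c(steps, "MNS4/MNS5(B)")
  }
  digestion_result(remove_residues(tree, ids, steps),
                   rep(list(glycan_comp(hex = 1)), length(ids)), steps)
}

#' Endomannosidase: cleave the Glc-alpha-1,3-Man disaccharide
#'
#' Endo-alpha-mannosidase removes the glucose together with the A-branch tip
#' mannose it caps, as one disaccharide, from a monoglucosylated glycan.
#' This irreversibly destroys the UGGT acceptor site. Glycans with zero or
#' more than one glucose are rejected (the action on di-/triglucosylated
#' glycans is disputed).
#'
#' @inheritParams apply_gcs1
#' @return A `digestion_result`; `released` holds one Hex2 fragment.
#' @examples
#' apply_endom(glycan_canonical("Glc1Man9GlcNAc2")) # -> Man8GlcNAc2-A
#' @export
apply_endom <- function(tree) {
  tree <- as_glycan_tree(tree)
  ng <- glc_count(tree)
  if (ng != 1) not_substrate("EndoM", paste0(ng, " glucose residues (needs exactly 1)"))
  if (!has_residue(tree, .pos$glc1) || !has_residue(tree, .pos$a_tip))
    not_substrate("EndoM", "glucose not alpha-1,3 on the A-branch tip mannose")
  if (!(.pos$glc1 %in% terminal_residues(tree)))
    not_substrate("EndoM", "glucose is capped")
  digestion_result(remove_residues(tree, c(.pos$glc1, .pos$a_tip), "EndoM"),
                   list(glycan_comp(hex = 2)), "EndoM")
}

#' Jack bean alpha-mannosidase digestion
#'
#' The diagnostic exoglycosidase JBM removes terminal alpha-linked mannoses;
#' glucose is never a substrate, so a glucose-capped A-branch is fully
#' protected, and the beta-1,4 core mannose always survives. Each iteration
#' removes every currently terminal alpha-mannose simultaneously, which
#' makes partial-digestion series deterministic; `iterations = Inf` runs to
#' the fixpoint (limit digest), which is idempotent. A tree with no
#' substrate is returned unchanged (no error).
#'
#' @inheritParams apply_gcs1
#' @param iterations Number of simultaneous-removal rounds; `Inf` for the
#'   limit digest.
#' @return A `digestion_result`.
#' @examples
#' apply_jbm("Man9GlcNAc2")$product        # -> Hex1HexNAc2
#' apply_jbm("Glc1Man7GlcNAc2")$product    # -> Hex5HexNAc2 (capped arm survives)
#' @export
apply_jbm <- function(tree, iterations = Inf) {
  tree <- as_glycan_tree(tree)
  stopifnot(iterations >= 0)
  released <- list()
  steps <- character()
  it <- 0
  while (it < iterations) {
    hit <- .terminal_with(tree, "Man", linkage_prefix = "a")
    if (length(hit) == 0) break
    it <- it + 1
    step <- paste0("JBM(round ", it, ": -", length(hit), " Man)")
    tree <- remove_residues(tree, hit, step)
    released <- c(released, rep(list(glycan_comp(hex = 1)), length(hit)))
    steps <- c(steps, step)
  }
  if (length(steps) == 0) steps <- "JBM(no substrate)"
  digestion_result(tree, released, steps)
}

#' Is the OS9 degradation signal exposed?
#'
#' TRUE iff the C-branch stem alpha-1,6 mannose is present and terminal —
#' the state produced by MNS4/MNS5 trimming of the C-branch tip, read by the
#' mannose-binding lectin OS9 as the commitment signal for ERAD.
#'
#' @inheritParams apply_gcs1
#' @return Logical scalar.
#' @examples
#' os9_signal_exposed("Glc1Man8GlcNAc2") # TRUE
#' os9_signal_exposed("Man9GlcNAc2")     # FALSE
#' @export
os9_signal_exposed <- function(tree) {
  tree <- as_glycan_tree(tree)
  has_residue(tree, .pos$c_stem) && .pos$c_stem %in% terminal_residues(tree)
}

# all possible single applications of a named rule; returns a list of
# digestion_results (possibly empty)
.rule_steps <- function(tree, rule) {
  try_one <- function(expr) {
    tryCatch(list(expr), glyco_not_substrate = function(e) list())
  }
  switch(
    rule,
    gcs1 = try_one(apply_gcs1(tree)),
    gcs2 = try_one(apply_gcs2(tree)),
    uggt = try_one(apply_uggt(tree)),
    mns45_c = try_one(apply_mns45(tree, extended = FALSE)),
    mns45_b = {
      ok <- has_residue(tree, .pos$b_tip) && .pos$b_tip %in% terminal_residues(tree)
      if (ok) {
        list(digestion_result(remove_residues(tree, .pos$b_tip, "MNS4/MNS5(B)"),
                              list(glycan_comp(hex = 1)), "MNS4/MNS5(B)"))
      } else list()
    },
    endom = try_one(apply_endom(tree)),
    a12man = {
      hits <- .terminal_with(tree, "Man", linkage = "a1-2")
      lapply(hits, function(id) {
        digestion_result(remove_residues(tree, id, paste0("a12-mannosidase(", id, ")")),
                         list(glycan_comp(hex = 1)),
                         paste0("a12-mannosidase(", id, ")"))
      })
    },
    rlang::abort(paste0("unknown enzyme rule: '", rule, "'"),
                 class = "glyco_validation_error")
  )
}

#' Enumerate structures reachable under a set of enzyme rules
#'
#' Breadth-first closure of single-step rule applications starting from a
#' structure, deduplicated by tree identity (canonical structure string).
#' Rule names: `"gcs1"`, `"gcs2"`, `"uggt"`, `"mns45_c"`, `"mns45_b"`,
#' `"endom"`, `"a12man"` (generic alpha-1,2 mannosidase, one terminal
#' mannose per step).
#'
#' @param start A `glycan_tree`, registry name or structure string.
#' @param rules Character vector of rule names.
#' @param max_steps Maximum number of BFS levels; `Inf` for the full closure
#'   (always finite: residue counts are bounded).
#' @return A tibble with one row per distinct structure: `name`, `structure`
#'   (condensed string), `composition`, `n_hex`, `n_glc`, `n_steps` (BFS
#'   depth at first discovery) and a `tree` list-column.
#' @examples
#' reachable_structures("Man9GlcNAc2", rules = "a12man", max_steps = 1)
#' @export
reachable_structures <- function(start,
                                 rules = c("gcs1", "gcs2", "uggt", "a12man",
                                           "mns45_c", "mns45_b"),
                                 max_steps = Inf) {
  stopifnot(max_steps >= 0)
  start <- as_glycan_tree(start)
  key0 <- format_structure(start)
  seen <- new.env(parent = emptyenv())
  assign(key0, TRUE, envir = seen)
  acc <- list(list(tree = start, depth = 0L))
  frontier <- list(start)
  depth <- 0L
  while (length(frontier) > 0 && depth < max_steps) {
    depth <- depth + 1L
    nxt <- list()
    for (tr in frontier) {
      for (rule in rules) {
        for (res in .rule_steps(tr, rule)) {
          key <- format_structure(res$product)
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            acc[[length(acc) + 1L]] <- list(tree = res$product, depth = depth)
            nxt[[length(nxt) + 1L]] <- res$product
          }
        }
      }
    }
    frontier <- nxt
  }
  out <- tibble::tibble(
    name = vapply(acc, function(a) structure_name(a$tree), character(1)),
    structure = vapply(acc, function(a) format_structure(a$tree), character(1)),
    composition = vapply(acc, function(a) comp_label(composition_of(a$tree)), character(1)),
    n_hex = vapply(acc, function(a) composition_of(a$tree)[["hex"]], integer(1)),
    n_glc = vapply(acc, function(a) glc_count(a$tree), integer(1)),
    n_steps = vapply(acc, function(a) a$depth, integer(1)),
    tree = lapply(acc, `[[`, "tree")
  )
  dplyr::arrange(out, .data$n_steps, dplyr::desc(.data$n_glc), .data$name)
}

#' Infer candidate structures for an observed isobaric composition
#'
#' MS sees only compositions; isobaric structures (e.g. Man8GlcNAc2 vs
#' Glc1Man7GlcNAc2, both Hex8HexNAc2) are disambiguated from digestion
#' evidence. Candidates are the ER-reachable structures (closure of
#' GCSI/GCSII, UGGT, generic alpha-1,2 mannosidase and the MNS4/MNS5
#' sub-rules from Glc3Man9GlcNAc2) whose composition matches, filtered by
#' the observed limit-JBM product (glucose caps protect the A-arm, so
#' glucosylated species stop at Hex5 rather than Hex1) and by
#' endomannosidase sensitivity; a distinct PGC elution from glucose-free
#' standards is recorded as supporting evidence for glucosylated candidates.
#'
#' @param observed Observed composition (a `glycan_comp` or label such as
#'   `"Hex8HexNAc2"`); must contain exactly two HexNAc.
#' @param jbm_limit Optional composition of the limit JBM digestion product.
#' @param endom_sensitive Optional logical: did endomannosidase digest the
#'   glycan?
#' @param elutes_off_standard Optional logical: did the released glycan elute
#'   apart from the Man9/Man8 standards on porous graphitic carbon?
#' @param max_glc Maximum candidate glucosylation state (default 1: GCSI and
#'   GCSII act co-translationally, so di/triglucosylated candidates are only
#'   considered on request).
#' @return A tibble of candidates ordered by glucose count (descending) then
#'   name: `name`, `structure`, `composition`, `n_glc`, `jbm_limit`,
#'   `endom_sensitive`, `evidence`. Zero rows (with a warning) if no
#'   candidate is consistent with all evidence.
#' @examples
#' infer_isomer("Hex8HexNAc2", jbm_limit = "Hex5HexNAc2") # Glc1Man7GlcNAc2
#' @export
infer_isomer <- function(observed, jbm_limit = NULL, endom_sensitive = NULL,
                         elutes_off_standard = NULL, max_glc = 1) {
  observed <- as_glycan_comp(observed)
  if (observed[["hexnac"]] != 2) {
    rlang::abort("isomer inference is defined for HexNAc2 (N-glycan) compositions",
                 class = "glyco_validation_error")
  }
  cands <- reachable_structures("Glc3Man9GlcNAc2")
  cands <- dplyr::filter(cands, .data$n_glc <= max_glc,
                         .data$composition == comp_label(observed))
  cands$jbm_limit <- vapply(cands$tree, function(tr) {
    comp_label(composition_of(apply_jbm(tr)$product))
  }, character(1))
  cands$endom_sensitive <- vapply(cands$tree, function(tr) {
    tryCatch({apply_endom(tr); TRUE}, glyco_not_substrate = function(e) FALSE)
  }, logical(1))
  notes <- function(row) {
    ev <- character()
    if (!is.null(jbm_limit))
      ev <- c(ev, paste0("limit JBM product ", row$jbm_limit))
    if (!is.null(endom_sensitive))
      ev <- c(ev, paste0("EndoM ", if (row$endom_sensitive) "sensitive" else "resistant"))
    if (isTRUE(elutes_off_standard) && row$n_glc > 0)
      ev <- c(ev, "distinct PGC elution consistent with glucosylation")
    if (length(ev) == 0) "composition only" else paste(ev, collapse = "; ")
  }
  if (!is.null(jbm_limit)) {
    jl <- comp_label(as_glycan_comp(jbm_limit))
    cands <- dplyr::filter(cands, .data$jbm_limit == .env$jl)
  }
  if (!is.null(endom_sensitive)) {
    es <- isTRUE(endom_sensitive)
    cands <- dplyr::filter(cands, .data$endom_sensitive == .env$es)
  }
  cands <- dplyr::arrange(cands, dplyr::desc(.data$n_glc), .data$name)
  cands$evidence <- vapply(seq_len(nrow(cands)),
                           function(i) notes(cands[i, ]), character(1))
  if (nrow(cands) == 0) {
    rlang::warn(paste0("no candidate structure is consistent with all evidence for ",
                       comp_label(observed)))
  }
  dplyr::select(cands, "name", "structure", "composition", "n_glc",
                "jbm_limit", "endom_sensitive", "evidence")
}
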