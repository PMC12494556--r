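# Glycan trees are tibbles with one row per monosaccharide residue:
#   residue_id  : path from the reducing end, e.g. "R/b1-4/b1-4/a1-3"
#   sugar       : Glc | Man | GlcNAc
#   linkage     : a1-2 | a1-3 | a1-6 | b1-4 (NA for the reducing end)
#   branch      : core | A | B | C | cap (NA for positions off the canonical
#                 Glc3Man9GlcNAc2 scaffold)
#   parent      : residue_id of the parent (NA for the reducing end)
# Path ids are unique because no two children of a residue share a linkage.

.linkages <- c("a1-2", "a1-3", "a1-6", "b1-4")

# canonical Glc3Man9GlcNAc2 scaffold (branches A/B/C fixed here, never
# recomputed): chitobiose core, beta-Man, alpha-1,3 arm carrying branch A and
# the triglucose cap, alpha-1,6 arm carrying branches B and C.
.scaffold <- local({
  row <- function(sugar, linkage, parent, branch) {
    id <- if (is.na(parent)) "R" else paste(parent, linkage, sep = "/")
    list(residue_id = id, sugar = sugar, linkage = linkage,
         branch = branch, parent = parent)
  }
  p <- function(...) paste(..., sep = "/")
  rows <- list(
    row("GlcNAc", NA, NA, "core"),
    row("GlcNAc", "b1-4", "R", "core"),
    row("Man", "b1-4", p("R", "b1-4"), "core"),
    row("Man", "a1-3", p("R", "b1-4", "b1-4"), "core"),                  # 3-arm
    row("Man", "a1-2", p("R", "b1-4", "b1-4", "a1-3"), "A"),             # A-stem
    row("Man", "a1-2", p("R", "b1-4", "b1-4", "a1-3", "a1-2"), "A"),     # A-tip
    row("Glc", "a1-3", p("R", "b1-4", "b1-4", "a1-3", "a1-2", "a1-2"), "cap"),
    row("Glc", "a1-3", p("R", "b1-4", "b1-4", "a1-3", "a1-2", "a1-2", "a1-3"), "cap"),
    row("Glc", "a1-2", p("R", "b1-4", "b1-4", "a1-3", "a1-2", "a1-2", "a1-3", "a1-3"), "cap"),
    row("Man", "a1-6", p("R", "b1-4", "b1-4"), "core"),                  # 6-arm
    row("Man", "a1-3", p("R", "b1-4", "b1-4", "a1-6"), "B"),             # B-stem
    row("Man", "a1-2", p("R", "b1-4", "b1-4", "a1-6", "a1-3"), "B"),     # B-tip
    row("Man", "a1-6", p("R", "b1-4", "b1-4", "a1-6"), "C"),             # C-stem
    row("Man", "a1-2", p("R", "b1-4", "b1-4", "a1-6", "a1-6"), "C")      # C-tip
  )
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
})

# named residue positions used by the enzyme rules
.pos <- list(
  root   = "R",
  bman   = "R/b1-4/b1-4",
  arm3   = "R/b1-4/b1-4/a1-3",
  a_stem = "R/b1-4/b1-4/a1-3/a1-2",
  a_tip  = "R/b1-4/b1-4/a1-3/a1-2/a1-2",
  glc1   = "R/b1-4/b1-4/a1-3/a1-2/a1-2/a1-3",
  arm6   = "R/b1-4/b1-4/a1-6",
  b_stem = "R/b1-4/b1-4/a1-6/a1-3",
  b_tip  = "R/b1-4/b1-4/a1-6/a1-3/a1-2",
  c_stem = "R/b1-4/b1-4/a1-6/a1-6",
  c_tip  = "R/b1-4/b1-4/a1-6/a1-6/a1-2"
)

.branch_of_path <- function(path) {
  i <- match(path, .scaffold$residue_id)
  ifelse(is.na(i), NA_character_, .scaffold$branch[i])
}

new_glycan_tree <- function(residues, provenance = character()) {
  res <- tibble::as_tibble(residues)[, c("residue_id", "sugar", "linkage",
                                         "branch", "parent")]
  out <- structure(res, class = c("glycan_tree", class(res)),
                   provenance = provenance)
  validate_glycan_tree(out)
}

#' Validate a glycan tree
#'
#' Checks the structural invariants of a residue table: exactly one
#' reducing-end residue, every other residue reaches the root through its
#' parent chain, known sugars and linkages, and no two children of a residue
#' sharing the same linkage.
#'
#' @param tree A `glycan_tree`.
#' @return The tree, invisibly usable in pipes; errors on violation.
#' @export
validate_glycan_tree <- function(tree) {
  res <- tree
  bad <- function(msg) rlang::abort(msg, class = "glyco_validation_error")
  if (nrow(res) == 0) bad("glycan tree has no residues")
  if (!all(res$sugar %in% c("Glc", "Man", "GlcNAc"))) bad("unknown sugar in tree")
  roots <- which(is.na(res$parent))
  if (length(roots) != 1L) bad("glycan tree must have exactly one reducing-end residue")
  if (res$sugar[roots] != "GlcNAc") bad("reducing-end residue must be GlcNAc")
  if (!all(is.na(res$linkage) == is.na(res$parent)))
    bad("linkage must be absent exactly for the reducing end")
  if (!all(res$linkage[-roots] %in% .linkages)) bad("unknown linkage in tree")
  if (!all(res$parent[-roots] %in% res$residue_id)) bad("orphan residue in tree")
  if (anyDuplicated(res$residue_id)) bad("duplicate residue ids")
  key <- paste(res$parent, res$linkage)[-roots]
  if (anyDuplicated(key)) bad("two children of one residue share a linkage")
  # connectivity: walk up from every residue; path ids make cycles impossible
  # but a detached subtree would not reach the root
  reach <- vapply(seq_len(nrow(res)), function(i) {
    seen <- 0L
    while (!is.na(res$parent[i])) {
      i <- match(res$parent[i], res$residue_id)
      seen <- seen + 1L
      if (seen > nrow(res)) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!all(reach)) bad("glycan tree is not connected")
  tree
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat("<glycan_tree> ", comp_label(composition_of(x)), ", ",
      nrow(x), " residues\n", sep = "")
  cat("  ", format_structure(x), "\n", sep = "")
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  provenance: ", paste(prov, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Terminal residues of a glycan tree
#'
#' A residue is terminal iff it has no children; exo-glycosidase rules act
#' only on terminal residues.
#'
#' @param tree A `glycan_tree`.
#' @return Character vector of terminal residue ids.
#' @export
terminal_residues <- function(tree) {
  setdiff(tree$residue_id, tree$parent[!is.na(tree$parent)])
}

#' Composition of a glycan tree
#'
#' Collapses a structure to its mass-class composition: Glc and Man both
#' count as hexose (MS cannot distinguish them — the central analytical
#' ambiguity this package exists to resolve), GlcNAc as N-acetylhexosamine.
#'
#' @param tree A `glycan_tree`.
#' @return A `glycan_comp`.
#' @examples
#' composition_of(glycan_canonical("Glc3Man9GlcNAc2")) # Hex12HexNAc2
#' @export
composition_of <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  glycan_comp(hex = sum(tree$sugar %in% c("Glc", "Man")),
              hexnac = sum(tree$sugar == "GlcNAc"))
}

glc_count <- function(tree) sum(tree$sugar == "Glc")

has_residue <- function(tree, id) id %in% tree$residue_id

remove_residues <- function(tree, ids, step) {
  res <- tree[!tree$residue_id %in% ids, , drop = FALSE]
  new_glycan_tree(res, provenance = c(attr(tree, "provenance"), step))
}

# subtree ids (residue and all descendants)
descendants <- function(tree, id) {
  out <- id
  frontier <- id
  while (length(frontier)) {
    frontier <- tree$residue_id[!is.na(tree$parent) & tree$parent %in% frontier]
    out <- c(out, frontier)
  }
  out
}

#' Canonical structure registry
#'
#' Names of the canonical ER processing intermediates that
#' [glycan_canonical()] can build. All are derived from the hardcoded
#' Glc3Man9GlcNAc2 topology by enzyme rules; Man8 isomers are named for the
#' branch whose tip mannose is missing.
#'
#' @return Character vector of registry names.
#' @export
glycan_registry <- function() {
  c("Glc3Man9GlcNAc2", "Glc2Man9GlcNAc2", "Glc1Man9GlcNAc2", "Man9GlcNAc2",
    "Glc1Man8GlcNAc2", "Glc1Man7GlcNAc2",
    "Man8GlcNAc2-A", "Man8GlcNAc2-B", "Man8GlcNAc2-C",
    "Man7GlcNAc2", "Man6GlcNAc2")
}

#' Build a canonical glycan structure
#'
#' Returns the rooted residue tree of a named canonical structure. The
#' unprocessed Glc3Man9GlcNAc2 topology is hardcoded (chitobiose core,
#' beta-mannose, the three branches A, B and C, and the triglucose cap on
#' branch A); every other registry entry is derived from it by applying the
#' enzyme rules, so registry structures are consistent with the rule engine
#' by construction.
#'
#' @param name A name from [glycan_registry()].
#' @return A `glycan_tree`.
#' @examples
#' glycan_canonical("Man9GlcNAc2")
#' @export
glycan_canonical <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  root <- new_glycan_tree(.scaffold, provenance = "Glc3Man9GlcNAc2")
  build <- switch(
    name,
    "Glc3Man9GlcNAc2" = function() root,
    "Glc2Man9GlcNAc2" = function() apply_gcs1(root)$product,
    "Glc1Man9GlcNAc2" = function() apply_gcs2(apply_gcs1(root)$product)$product,
    "Man9GlcNAc2"     = function() {
      apply_gcs2(apply_gcs2(apply_gcs1(root)$product)$product)$product
    },
    "Glc1Man8GlcNAc2" = function() {
      apply_mns45(glycan_canonical("Glc1Man9GlcNAc2"))$product
    },
    "Glc1Man7GlcNAc2" = function() {
      apply_mns45(glycan_canonical("Glc1Man9GlcNAc2"), extended = TRUE)$product
    },
    "Man8GlcNAc2-A"   = function() apply_endom(glycan_canonical("Glc1Man9GlcNAc2"))$product,
    "Man8GlcNAc2-B"   = function() {
      remove_residues(glycan_canonical("Man9GlcNAc2"), .pos$b_tip, "a12-mannosidase(B)")
    },
    "Man8GlcNAc2-C"   = function() apply_mns45(glycan_canonical("Man9GlcNAc2"))$product,
    "Man7GlcNAc2"     = function() {
      apply_mns45(glycan_canonical("Man9GlcNAc2"), extended = TRUE)$product
    },
    "Man6GlcNAc2"     = function() apply_endom(glycan_canonical("Glc1Man7GlcNAc2"))$product,
    rlang::abort(paste0("unknown canonical structure name: '", name, "'"),
                 class = "glyco_unknown_structure")
  )
  tree <- build()
  attr(tree, "provenance") <- c("Glc3Man9GlcNAc2",
                                setdiff(attr(tree, "provenance"), "Glc3Man9GlcNAc2"))
  tree
}

as_glycan_tree <- function(x) {
  if (inherits(x, "glycan_tree")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% glycan_registry()) return(glycan_canonical(x))
    return(parse_structure(x))
  }
  rlang::abort("expected a glycan_tree, registry name or structure string",
               class = "glyco_validation_error")
}

# --- condensed linear structure strings -------------------------------------

#' Format a glycan tree as a condensed structure string
#'
#' Serialises a tree to the condensed linear dialect with the reducing end
#' rightmost, linkages as `(a1-2)`, `(a1-3)`, `(a1-6)`, `(b1-4)` and side
#' branches bracketed. Children are emitted in the fixed linkage order
#' a1-2 < a1-3 < a1-6 < b1-4, the highest-ordered child continuing the main
#' chain, which makes the output deterministic: equal strings iff equal
#' trees.
#'
#' @param tree A `glycan_tree`.
#' @return A character scalar.
#' @examples
#' format_structure(glycan_canonical("Man9GlcNAc2"))
#' @export
format_structure <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  token <- function(i) {
    paste0(tree$sugar[i],
           if (!is.na(tree$linkage[i])) paste0("(", tree$linkage[i], ")") else "")
  }
  fmt <- function(id) {
    i <- match(id, tree$residue_id)
    kids <- which(!is.na(tree$parent) & tree$parent == id)
    kids <- kids[order(match(tree$linkage[kids], .linkages))]
    if (length(kids) == 0) return(token(i))
    main <- kids[length(kids)]
    side <- kids[-length(kids)]
    paste0(fmt(tree$residue_id[main]),
           paste0(vapply(side, function(k) paste0("[", fmt(tree$residue_id[k]), "]"),
                         character(1)), collapse = ""),
           token(i))
  }
  fmt(tree$residue_id[is.na(tree$parent)])
}

#' Parse a condensed glycan structure string
#'
#' Inverse of [format_structure()]. Branch labels are looked up from the
#' position in the canonical Glc3Man9GlcNAc2 scaffold (positions off the
#' scaffold get `NA`), never inferred from the string.
#'
#' @param text A structure string, reducing end rightmost, e.g.
#'   `"Man(b1-4)GlcNAc(b1-4)GlcNAc"`.
#' @return A `glycan_tree`.
#' @export
parse_structure <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- "(Glc(?:NAc)?|Man)(\\((a1-[236]|b1-4)\\))?|\\[|\\]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (m[1] == -1 || covered != nchar(text)) {
    # locate the first offending character for the error message
    ends <- if (m[1] == -1) integer() else m + attr(m, "match.length") - 1L
    pos <- if (length(ends)) max(ends) + 1L else 1L
    # the mismatch may be before the first match too
    if (length(m) && m[1] > 1) pos <- 1L
    rlang::abort(paste0("cannot parse structure string near: '",
                        substr(text, pos, min(nchar(text), pos + 11L)), "'"),
                 class = "glyco_parse_error")
  }
  # recursive descent from the right
  parse_chain <- function(toks) {
    n <- length(toks)
    if (n == 0) rlang::abort("empty chain in structure string",
                             class = "glyco_parse_error")
    head_tok <- toks[n]
    if (head_tok %in% c("[", "]"))
      rlang::abort("misplaced bracket in structure string",
                   class = "glyco_parse_error")
    sugar <- sub("\\(.*$", "", head_tok)
    linkage <- if (grepl("\\(", head_tok)) sub("^.*\\((.*)\\)$", "\\1", head_tok) else NA_character_
    rest <- toks[-n]
    children <- list()
    repeat {
      k <- length(rest)
      if (k == 0 || rest[k] != "]") break
      depth <- 1L
      j <- k - 1L
      while (j >= 1L && depth > 0L) {
        if (rest[j] == "]") depth <- depth + 1L
        if (rest[j] == "[") depth <- depth - 1L
        if (depth == 0L) break
        j <- j - 1L
      }
      if (depth != 0L) rlang::abort("unbalanced brackets in structure string",
                                    class = "glyco_parse_error")
      children <- c(children, list(parse_chain(rest[(j + 1L):(k - 1L)])))
      rest <- rest[seq_len(j - 1L)]
    }
    if (length(rest)) children <- c(children, list(parse_chain(rest)))
    list(sugar = sugar, linkage = linkage, children = children)
  }
  node <- parse_chain(toks)
  if (!is.na(node$linkage)) {
    rlang::abort("reducing-end residue must not carry a linkage",
                 class = "glyco_parse_error")
  }
  rows <- list()
  walk <- function(node, parent) {
    id <- if (is.null(parent)) "R" else paste(parent, node$linkage, sep = "/")
    rows[[length(rows) + 1L]] <<- data.frame(
      residue_id = id, sugar = node$sugar,
      linkage = if (is.null(parent)) NA_character_ else node$linkage,
      branch = .branch_of_path(id),
      parent = if (is.null(parent)) NA_character_ else parent,
      stringsAsFactors = FALSE
    )
    for (ch in node$children) {
      if (is.na(ch$linkage))
        rlang::abort("internal residue missing a linkage",
                     class = "glyco_parse_error")
      walk(ch, id)
    }
  }
  walk(node, NULL)
  new_glycan_tree(do.call(rbind, rows), provenance = "parsed")
}

#' Name a glycan structure
#'
#' Derives a human-readable name for a tree reachable from Glc3Man9GlcNAc2:
#' `GlcgManmGlcNAcn`, suffixed by the branches whose residues are missing
#' relative to Man9GlcNAc2 when the trimming state is not the canonical
#' C-then-B processing order (so `Man8GlcNAc2-A/-B/-C` isomers stay
#' distinguishable while MNS4/MNS5 products keep their plain names).
#'
#' @param tree A `glycan_tree`.
#' @return A character scalar.
#' @export
structure_name <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  g <- glc_count(tree)
  m <- sum(tree$sugar == "Man")
  n <- sum(tree$sugar == "GlcNAc")
  base <- paste0(if (g > 0) paste0("Glc", g), "Man", m, "GlcNAc", n)
  miss <- c(A = !has_residue(tree, .pos$a_tip),
            `A'` = !has_residue(tree, .pos$a_stem),
            B = !has_residue(tree, .pos$b_tip),
            C = !has_residue(tree, .pos$c_tip))
  missing <- names(miss)[miss]
  canonical_orders <- list(character(), "C", c("B", "C"), c("A", "B", "C"))
  if (any(vapply(canonical_orders, function(o) setequal(missing, o), logical(1)))) {
    # plain name, except glucose-free Man8 which is always branch-suffixed
    if (g == 0 && m == 8 && length(missing) == 1L)
      return(paste0(base, "-", missing))
    return(base)
  }
  paste0(base, "-", paste(sort(missing), collapse = ""))
}
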