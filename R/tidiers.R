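# broom-style tidiers for the package's non-tabular objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a glycan tree into its residue table
#'
#' @param x A `glycan_tree`.
#' @param ... Ignored.
#' @return A tibble with one row per residue (`residue_id`, `sugar`,
#'   `linkage`, `branch`, `parent`, `terminal`).
#' @export
tidy.glycan_tree <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$terminal <- out$residue_id %in% terminal_residues(x)
  out
}

#' @rdname tidy.glycan_tree
#' @return `glance()` returns a one-row summary: name, composition, residue
#'   and terminal counts, glucose count, OS9-signal state.
#' @export
glance.glycan_tree <- function(x, ...) {
  tibble::tibble(
    name = structure_name(x),
    composition = comp_label(composition_of(x)),
    n_residues = nrow(x),
    n_terminal = length(terminal_residues(x)),
    n_glc = glc_count(x),
    os9_signal = os9_signal_exposed(x)
  )
}

#' Tidy a digestion result into its step log
#'
#' @param x A `digestion_result`.
#' @param ... Ignored.
#' @return A tibble with one row per rule application (`step`, `rule`).
#' @export
tidy.digestion_result <- function(x, ...) {
  tibble::tibble(step = seq_along(x$steps), rule = x$steps)
}

#' @rdname tidy.digestion_result
#' @return `glance()` returns a one-row summary of the digestion: product
#'   name and composition, number of steps, released residue count.
#' @export
glance.digestion_result <- function(x, ...) {
  rel <- if (length(x$released)) Reduce(`+`, x$released) else glycan_comp()
  tibble::tibble(
    product = structure_name(x$product),
    product_composition = comp_label(composition_of(x$product)),
    n_steps = length(x$steps),
    released = comp_label(rel)
  )
}
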