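#' Encode an alignment for maximum-likelihood analysis
#'
#' Applies the missing-data coding used throughout the pipeline: columns
#' inserted relative to the reference are dropped entirely; in the taxa that
#' carry them, deletion gaps and the three bases of each nonsense codon are
#' recoded as missing (`?`); every remaining gap or `N` also becomes `?`.
#'
#' @param alignment A [codon_alignment()].
#' @param mutations Mutations from [classify_orf()] on the same alignment.
#' @return An object of class `phylo_matrix`: `taxa`, `states` (character
#'   matrix over `A,C,G,T,?`), `n_sites`, and `site_to_column` mapping each
#'   encoded site back to its 1-based alignment column.
#' @examples
#' sim <- simulate_pinniped_fixture(seed = 1)
#' scan <- classify_orf(sim$alignment)
#' mat <- encode_for_ml(sim$alignment, scan$mutations)
#' mat$n_sites
#' @export
encode_for_ml <- function(alignment, mutations = list()) {
  fm <- build_frame_map(alignment)
  states <- alignment$seqs
  for (m in mutations) {
    if (!all(m$taxa %in% alignment$taxa)) {
      stop_pseudophy("usage_error", sprintf(
        "mutation %s names taxa absent from the alignment", mutation_id(m)))
    }
    if (m$start_col < 1L || m$end_col > alignment$n_columns) {
      stop_pseudophy("usage_error", sprintf(
        "mutation %s lies outside the alignment", mutation_id(m)))
    }
    if (m$kind %in% c("frameshift_deletion", "nonsense_substitution")) {
      states[m$taxa, m$start_col:m$end_col] <- "?"
    }
  }
  keep <- which(!fm$inserted)
  states <- states[, keep, drop = FALSE]
  states[states %in% c("-", "N")] <- "?"
  structure(list(taxa = alignment$taxa, states = states,
                 n_sites = length(keep), site_to_column = keep),
            class = "phylo_matrix")
}

#' @export
print.phylo_matrix <- function(x, ...) {
  cat(sprintf("phylo_matrix: %d taxa x %d sites (%.1f%% missing)\n",
              length(x$taxa), x$n_sites, 100 * mean(x$states == "?")))
  invisible(x)
}

# Collapse identical site patterns. Returns integer tip-state matrix
# (patterns x taxa; 0=A 1=C 2=G 3=T 4=missing) plus pattern weights.
compress_patterns <- function(states) {
  code <- matrix(4L, nrow(states), ncol(states))
  for (i in seq_along(c("A", "C", "G", "T"))) {
    code[states == c("A", "C", "G", "T")[i]] <- i - 1L
  }
  key <- apply(code, 2L, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(tip_states = t(code[, first, drop = FALSE]),
       weights = as.numeric(tab))
}

# Precompute everything logL needs for one (topology, data) pair so branch
# sweeps only vary edge lengths. Tree must keep its current topology.
prepare_loglik <- function(tree, matrix) {
  if (!all(tree$tip.label %in% matrix$taxa)) {
    stop_pseudophy("usage_error", sprintf(
      "tree leaves missing from matrix: %s",
      paste(setdiff(tree$tip.label, matrix$taxa), collapse = ", ")))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  cp <- compress_patterns(matrix$states[tree$tip.label, , drop = FALSE])
  list(tree = tree, edge = tree$edge, n_tip = length(tree$tip.label),
       tip_states = cp$tip_states, weights = cp$weights)
}

loglik_prepared <- function(prep, lengths, model) {
  hky_pruning_loglik_cpp(prep$edge, lengths, prep$n_tip, prep$tip_states,
                         prep$weights, model$kappa, unname(model$pi),
                         gamma_category_rates(model))
}

#' Phylogenetic log-likelihood under HKY (+ gamma)
#'
#' Felsenstein pruning: the sum over sites of the log of the
#' category-averaged conditional likelihood at the root. Missing states (`?`)
#' contribute a partial likelihood of 1 for every nucleotide. Because the
#' model is time-reversible the value is invariant to the rooting of the
#' tree.
#'
#' @param tree An [ape::phylo] with branch lengths (expected
#'   substitutions/site); its leaves must be a subset of the matrix taxa.
#' @param matrix A [encode_for_ml()] result.
#' @param model An [hky_gamma_model()].
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(tree, matrix, model) {
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    stop_pseudophy("usage_error",
                   "tree must have finite non-negative branch lengths")
  }
  prep <- prepare_loglik(tree, matrix)
  # reorder.phylo permutes edges jointly with edge.length
  loglik_prepared(prep, prep$tree$edge.length, model)
}
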