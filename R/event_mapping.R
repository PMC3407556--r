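#' Binary presence/absence matrix of mutations
#'
#' @param mutations Merged mutation list from [classify_orf()].
#' @param taxa All taxa of the alignment (matrix rows).
#' @return Integer 0/1 matrix, taxa x events; column names are event ids
#'   (`kind_start_end`).
#' @export
build_event_matrix <- function(mutations, taxa) {
  for (m in mutations) {
    unknown <- setdiff(m$taxa, taxa)
    if (length(unknown) > 0L) {
      stop_pseudophy("usage_error", sprintf(
        "mutation %s affects unknown taxa: %s", mutation_id(m),
        paste(unknown, collapse = ", ")))
    }
  }
  M <- matrix(0L, length(taxa), length(mutations),
              dimnames = list(taxa,
                              vapply(mutations, mutation_id, character(1))))
  for (j in seq_along(mutations)) {
    M[mutations[[j]]$taxa, j] <- 1L
  }
  M
}

# Fitch small-parsimony step count for a binary character on a rooted tree.
# Postorder edge traversal: a child's state set is final before its edge is
# reached, so each edge folds one child into its parent's running set.
fitch_steps <- function(tree, states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- unname(states[tree$tip.label[i]])
  steps <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    c_ <- tree$edge[e, 2]
    if (is.null(sets[[p]])) {
      sets[[p]] <- sets[[c_]]
    } else {
      inter <- intersect(sets[[p]], sets[[c_]])
      if (length(inter) > 0L) {
        sets[[p]] <- inter
      } else {
        sets[[p]] <- union(sets[[p]], sets[[c_]])
        steps <- steps + 1L
      }
    }
  }
  steps
}

#' Place mutations on ancestral branches
#'
#' Under the single-origin (Dollo) reading, each mutation is assigned to the
#' edge above the most recent common ancestor (MRCA) of the taxa carrying it.
#' The placement is Dollo-consistent when the carriers are exactly that
#' clade; otherwise the number of extra steps required by Fitch parsimony on
#' the binary character (minimum changes minus one) is reported, and the
#' homoplasy is surfaced, never silently resolved. Events whose carriers span
#' the root (MRCA = root) cannot be assigned to a branch and are flagged.
#'
#' @param rooted_tree A rooted [ape::phylo] containing every carrier taxon.
#' @param event_matrix A [build_event_matrix()] result (taxa x events).
#' @return Data frame (one row per event): `event`, `child_node` (the node
#'   under the assigned edge; `NA` when root-spanning), `branch` (the tip
#'   label for terminal edges, otherwise `"mrca(<first>,<last>)"`),
#'   `n_taxa`, `dollo_consistent`, `extra_steps`, `root_spanning`.
#' @export
place_events <- function(rooted_tree, event_matrix) {
  if (ncol(event_matrix) == 0L) {
    return(data.frame(event = character(), child_node = integer(),
                      branch = character(), n_taxa = integer(),
                      dollo_consistent = logical(), extra_steps = integer(),
                      root_spanning = logical(), stringsAsFactors = FALSE))
  }
  if (!all(rownames(event_matrix) %in% c(rooted_tree$tip.label))) {
    miss <- setdiff(rownames(event_matrix)[rowSums(event_matrix) > 0],
                    rooted_tree$tip.label)
    if (length(miss) > 0L) {
      stop_pseudophy("usage_error", sprintf(
        "tree lacks carrier taxa: %s", paste(miss, collapse = ", ")))
    }
  }
  n_tip <- length(rooted_tree$tip.label)
  root <- n_tip + 1L
  sets <- node_leafsets(rooted_tree)
  rows <- lapply(colnames(event_matrix), function(ev) {
    carriers <- rownames(event_matrix)[event_matrix[, ev] == 1L]
    if (length(carriers) == 0L) {
      stop_pseudophy("usage_error", sprintf(
        "event %s has an empty carrier set", ev))
    }
    node <- if (length(carriers) == 1L) {
      match(carriers, rooted_tree$tip.label)
    } else {
      ape::getMRCA(rooted_tree, carriers)
    }
    clade <- sets[[node]]
    consistent <- setequal(clade, carriers)
    extra <- 0L
    if (!consistent) {
      states <- setNames(as.integer(rooted_tree$tip.label %in% carriers),
                         rooted_tree$tip.label)
      extra <- fitch_steps(rooted_tree, states) - 1L
    }
    spanning <- node == root
    branch <- if (spanning) NA_character_
      else if (node <= n_tip) rooted_tree$tip.label[node]
      else sprintf("mrca(%s,%s)", clade[1], clade[length(clade)])
    data.frame(event = ev,
               child_node = if (spanning) NA_integer_ else node,
               branch = branch, n_taxa = length(carriers),
               dollo_consistent = consistent, extra_steps = extra,
               root_spanning = spanning, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# node ids on the path from a node to the root (exclusive of the node).
ancestor_nodes <- function(tree, node) {
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  out <- integer()
  nd <- node
  while (!is.na(parent[as.character(nd)])) {
    nd <- parent[[as.character(nd)]]
    out <- c(out, nd)
  }
  out
}

#' Partial temporal order of placed events
#'
#' Event A precedes event B when A's branch is a strict ancestor of B's
#' branch in the rooted tree; events on the same branch or in disjoint
#' clades are incomparable and omitted.
#'
#' @param placements A [place_events()] result.
#' @param rooted_tree The same rooted tree the placements refer to.
#' @return Data frame with columns `first`, `then` listing every ordered pair.
#' @export
order_events <- function(placements, rooted_tree) {
  placed <- placements[!placements$root_spanning, , drop = FALSE]
  pairs <- list()
  for (i in seq_len(nrow(placed))) {
    for (j in seq_len(nrow(placed))) {
      if (i == j) next
      # i precedes j iff i's child node is a strict ancestor of j's
      if (placed$child_node[i] %in% ancestor_nodes(rooted_tree,
                                                   placed$child_node[j])) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(first = placed$event[i], then = placed$event[j],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(first = character(), then = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, pairs))
}
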