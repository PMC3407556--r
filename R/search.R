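# --- low-level tree surgery -------------------------------------------------
# Trees are ape::phylo objects. Unrooted binary trees are stored with a basal
# trichotomy (root node of degree 3), the ape convention.

# Insert a new tip into edge `edge_index`, splitting it at its midpoint.
insert_tip <- function(tree, label, edge_index, tip_length = 0.05) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  edge <- tree$edge
  len <- tree$edge.length
  # renumber: old internal k -> k + 1; new tip = n_tip + 1;
  # new internal node = n_tip + n_node + 2
  edge[edge > n_tip] <- edge[edge > n_tip] + 1L
  new_tip <- n_tip + 1L
  new_node <- n_tip + n_node + 2L
  p <- edge[edge_index, 1]
  c_ <- edge[edge_index, 2]
  half <- len[edge_index] / 2
  edge[edge_index, ] <- c(p, new_node)
  len[edge_index] <- half
  edge <- rbind(edge, c(new_node, c_), c(new_node, new_tip))
  len <- c(len, half, tip_length)
  out <- list(edge = edge, tip.label = c(tree$tip.label, label),
              edge.length = len, Nnode = n_node + 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "postorder")
}

# All NNI neighbours of an unrooted binary tree (two per internal edge).
# Swapping reassigns parents in the edge matrix; branch lengths stay with
# their edge rows and are re-optimised by the caller.
nni_neighbors <- function(tree) {
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  root <- n_tip + 1L
  out <- list()
  internal <- which(edge[, 2] > n_tip)
  for (e in internal) {
    u <- edge[e, 1]
    v <- edge[e, 2]
    ch_v <- which(edge[, 1] == v)          # two child rows of v
    b_row <- which(edge[, 1] == u & edge[, 2] != v)[1]  # a side subtree at u
    for (cr in ch_v) {
      nb <- tree
      tmp <- nb$edge[b_row, 2]
      nb$edge[b_row, 2] <- nb$edge[cr, 2]
      nb$edge[cr, 2] <- tmp
      nb <- ape::reorder.phylo(nb, "postorder")
      attr(nb, "nni_nodes") <- c(u, v)   # node ids survive the reorder
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

# Unrooted 3-taxon star.
star3 <- function(labels, length = 0.05) {
  out <- list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), 3, 2, byrow = TRUE),
              tip.label = labels, edge.length = rep(length, 3), Nnode = 1L)
  class(out) <- "phylo"
  out
}

# Leaf labels under each node: list indexed by node id.
node_leafsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    c_ <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[c_]])
  }
  lapply(sets, sort)
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaves in two; a bipartition is identified by
#' the sorted labels of the side not containing the alphabetically first leaf,
#' so keys are rooting-invariant.
#'
#' @param tree An [ape::phylo].
#' @return Character vector of bipartition keys (one per internal edge).
#' @export
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  all_leaves <- sort(tree$tip.label)
  anchor <- all_leaves[1]
  sets <- node_leafsets(tree)
  keys <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next
    side <- sets[[child]]
    if (anchor %in% side) side <- setdiff(all_leaves, side)
    if (length(side) >= 2L && length(side) <= n_tip - 2L) {
      keys <- c(keys, paste(side, collapse = "|"))
    }
  }
  sort(unique(keys))
}

same_topology <- function(a, b) {
  setequal(a$tip.label, b$tip.label) &&
    identical(tree_bipartitions(a), tree_bipartitions(b))
}

# Rooting-invariant canonical Newick (topology only), used for deterministic
# tie-breaking among equal-likelihood trees.
canonical_newick <- function(tree) {
  tr <- if (length(tree$tip.label) > 3L) ape::unroot(tree) else tree
  n_tip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  canon <- function(nd) {
    if (nd <= n_tip) return(tr$tip.label[nd])
    parts <- sort(vapply(kids[[as.character(nd)]], canon, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(canon(n_tip + 1L), ";")
}

# --- scoring context --------------------------------------------------------
# Site patterns are compressed once; per-topology scoring only permutes tip
# columns and calls the compiled pruning kernel.

make_search_context <- function(matrix, model) {
  cp <- compress_patterns(matrix$states[matrix$taxa, , drop = FALSE])
  list(taxa = matrix$taxa, tip_states = cp$tip_states,
       weights = cp$weights, kappa = model$kappa, pi = unname(model$pi),
       rates = gamma_category_rates(model))
}

ctx_loglik <- function(ctx, tree) {
  tipmap <- match(tree$tip.label, ctx$taxa)
  hky_pruning_loglik_cpp(tree$edge, tree$edge.length,
                         length(tree$tip.label),
                         ctx$tip_states[, tipmap, drop = FALSE],
                         ctx$weights, ctx$kappa, ctx$pi, ctx$rates)
}

# Brent sweeps over branch lengths with fixed model parameters; tree must be
# in postorder. Returns the tree with optimised lengths and attr "logL".
ctx_optimize_lengths <- function(ctx, tree, max_sweeps = 25L) {
  tipmap <- match(tree$tip.label, ctx$taxa)
  tips <- ctx$tip_states[, tipmap, drop = FALSE]
  n_tip <- length(tree$tip.label)
  lengths <- pmin(pmax(tree$edge.length, BL_MIN), BL_MAX)
  f <- function(lens) hky_pruning_loglik_cpp(tree$edge, lens, n_tip, tips,
                                             ctx$weights, ctx$kappa, ctx$pi,
                                             ctx$rates)
  cur <- f(lengths)
  sweep <- 0L
  repeat {
    sweep <- sweep + 1L
    prev <- cur
    for (e in seq_along(lengths)) {
      opt <- optimize(function(x) {
        lengths[e] <- x
        f(lengths)
      }, interval = c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-4)
      if (opt$objective > cur) {
        lengths[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < LOGL_TOL || sweep >= max_sweeps) break
  }
  tree$edge.length <- lengths
  attr(tree, "logL") <- cur
  tree
}

# Random-addition-order stepwise addition: each taxon is tried on every edge
# and placed where the (unoptimised) likelihood is highest.
stepwise_tree <- function(ctx, order_taxa) {
  tree <- star3(order_taxa[1:3])
  for (tx in order_taxa[-(1:3)]) {
    best <- NULL
    best_logl <- -Inf
    for (e in seq_len(nrow(tree$edge))) {
      cand <- insert_tip(tree, tx, e)
      logl <- ctx_loglik(ctx, cand)
      if (logl > best_logl) {
        best_logl <- logl
        best <- cand
      }
    }
    tree <- best
  }
  tree
}

# Brent passes over selected edge rows only (the NNI-local refinement).
ctx_optimize_local <- function(ctx, tree, nodes, n_passes = 1L) {
  tipmap <- match(tree$tip.label, ctx$taxa)
  tips <- ctx$tip_states[, tipmap, drop = FALSE]
  n_tip <- length(tree$tip.label)
  lengths <- pmin(pmax(tree$edge.length, BL_MIN), BL_MAX)
  rows <- which(tree$edge[, 1] %in% nodes | tree$edge[, 2] %in% nodes)
  f <- function(lens) hky_pruning_loglik_cpp(tree$edge, lens, n_tip, tips,
                                             ctx$weights, ctx$kappa, ctx$pi,
                                             ctx$rates)
  cur <- f(lengths)
  for (pass in seq_len(n_passes)) {
    for (e in rows) {
      opt <- optimize(function(x) {
        lengths[e] <- x
        f(lengths)
      }, interval = c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-4)
      if (opt$objective > cur) {
        lengths[e] <- opt$maximum
        cur <- opt$objective
      }
    }
  }
  tree$edge.length <- lengths
  attr(tree, "logL") <- cur
  tree
}

# NNI hill-climb to a local optimum: neighbours are screened with inherited
# branch lengths; the best is accepted after a light re-optimisation (its
# likelihood can only rise above the screen value). When no neighbour
# screens above the current tree, the top few are re-screened with the five
# branch lengths around the swap locally optimised -- inherited lengths
# penalise a rearrangement, and this refinement escapes the resulting
# spurious local optima. At convergence no neighbour screens above the
# fully optimised current tree.
nni_climb <- function(ctx, tree, light_sweeps = 2L, max_moves = 200L,
                      deep_check = 5L) {
  tree <- ctx_optimize_lengths(ctx, tree, light_sweeps)
  cur <- attr(tree, "logL")
  moves <- 0L
  repeat {
    nb <- nni_neighbors(tree)
    scores <- vapply(nb, function(t) ctx_loglik(ctx, t), numeric(1))
    moves <- moves + 1L
    if (moves > max_moves) return(ctx_optimize_lengths(ctx, tree))
    if (max(scores) <= cur) {
      top <- order(scores, decreasing = TRUE)[
        seq_len(min(deep_check, length(scores)))]
      improved <- FALSE
      for (t in top) {
        cand <- ctx_optimize_local(ctx, nb[[t]],
                                   attr(nb[[t]], "nni_nodes"))
        if (attr(cand, "logL") > cur + LOGL_TOL) {
          tree <- ctx_optimize_lengths(ctx, cand, light_sweeps)
          cur <- attr(tree, "logL")
          improved <- TRUE
          break
        }
      }
      if (improved) next
      full <- ctx_optimize_lengths(ctx, tree)
      if (attr(full, "logL") > cur + LOGL_TOL) {
        tree <- full
        cur <- attr(full, "logL")
        next    # lengths moved; re-screen neighbours
      }
      return(full)
    }
    cand <- ctx_optimize_lengths(ctx, nb[[which.max(scores)]], light_sweeps)
    tree <- cand
    cur <- attr(cand, "logL")
  }
}

# Enumerate all unrooted topologies by recursive tip insertion (3, 15, 105,
# 945 ... topologies for 4, 5, 6, 7 taxa).
all_topologies <- function(taxa) {
  trees <- list(star3(taxa[1:3]))
  for (tx in taxa[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr)
      lapply(seq_len(nrow(tr$edge)), function(e) insert_tip(tr, tx, e))),
      recursive = FALSE)
  }
  trees
}

search_core <- function(matrix, model, n_restarts) {
  taxa <- matrix$taxa
  n <- length(taxa)
  ctx <- make_search_context(matrix, model)
  if (n == 3L) {
    return(ctx_optimize_lengths(ctx, star3(taxa)))
  }
  if (n <= 7L) {
    cands <- all_topologies(taxa)
    light <- lapply(cands, function(tr) ctx_optimize_lengths(ctx, tr, 2L))
    logls <- vapply(light, attr, numeric(1), "logL")
    top <- order(logls, decreasing = TRUE)[seq_len(min(3L, length(light)))]
    full <- lapply(light[top], function(tr) ctx_optimize_lengths(ctx, tr))
    best <- pick_best_tree(full)
    return(best)
  }
  results <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    order_taxa <- sample(taxa)
    results[[r]] <- nni_climb(ctx, stepwise_tree(ctx, order_taxa))
  }
  pick_best_tree(results)
}

# Highest likelihood wins; exact ties go to the lexicographically smallest
# canonical Newick string so results are reproducible.
pick_best_tree <- function(trees) {
  logls <- vapply(trees, attr, numeric(1), "logL")
  best <- which(logls == max(logls))
  if (length(best) > 1L) {
    keys <- vapply(trees[best], canonical_newick, character(1))
    best <- best[order(keys)[1]]
  }
  trees[[best[1]]]
}

#' Heuristic maximum-likelihood tree search
#'
#' For up to 7 taxa the search is exhaustive over all unrooted topologies
#' (each receives a light branch-length pass; the top three are optimised
#' fully). For larger problems it performs `n_restarts` random-addition-order
#' stepwise-addition starts, each followed by NNI hill-climbing to a local
#' optimum, and returns the best tree found. Model parameters are held fixed
#' during the search (fit them first, e.g. with [select_model()]); branch
#' lengths are optimised. Deterministic for a given `seed`.
#'
#' @param matrix A [encode_for_ml()] result.
#' @param model An [hky_gamma_model()].
#' @param n_restarts Number of random-addition starts (default 5).
#' @param seed Integer seed controlling addition orders.
#' @return An unrooted [ape::phylo] with optimised branch lengths and the
#'   final log-likelihood in `attr(tree, "logL")`.
#' @export
search_ml_tree <- function(matrix, model, n_restarts = 5L, seed = 1L) {
  if (length(matrix$taxa) < 3L) {
    stop_pseudophy("usage_error", "tree search needs at least 3 taxa")
  }
  withr::with_seed(seed, search_core(matrix, model, n_restarts))
}

#' Nonparametric bootstrap support
#'
#' Resamples encoded sites with replacement `n_replicates` times, reruns the
#' tree search on each pseudoreplicate, and reports for every internal edge
#' of the maximum-likelihood tree the percentage of replicate trees
#' containing the same bipartition. Deterministic for a given `seed`.
#'
#' @inheritParams search_ml_tree
#' @param ml_tree The tree whose bipartitions are annotated (typically the
#'   [search_ml_tree()] result).
#' @param n_replicates Number of pseudoreplicates (>= 1).
#' @param n_restarts Stepwise-addition starts per replicate search (default 2;
#'   replicate searches trade restarts for speed).
#' @return A list: `tree` (the `ml_tree` with internal-node labels set to
#'   rounded support percentages) and `supports` (data frame of bipartition
#'   keys and support percentages).
#' @export
bootstrap_support <- function(matrix, model, ml_tree, n_replicates = 1000L,
                              seed = 1L, n_restarts = 2L) {
  if (n_replicates < 1L) {
    stop_pseudophy("usage_error", "n_replicates must be >= 1")
  }
  target <- tree_bipartitions(ml_tree)
  hits <- setNames(numeric(length(target)), target)
  withr::with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(matrix$n_sites, replace = TRUE)
      mat_b <- structure(
        list(taxa = matrix$taxa,
             states = matrix$states[, idx, drop = FALSE],
             n_sites = matrix$n_sites,
             site_to_column = matrix$site_to_column[idx]),
        class = "phylo_matrix")
      rep_tree <- search_core(mat_b, model, n_restarts)
      found <- tree_bipartitions(rep_tree)
      present <- target %in% found
      hits[present] <- hits[present] + 1
    }
  })
  supports <- data.frame(bipartition = target,
                         support = 100 * unname(hits) / n_replicates,
                         stringsAsFactors = FALSE)
  list(tree = annotate_supports(ml_tree, supports), supports = supports)
}

# Write support percentages onto internal node labels of `tree`.
annotate_supports <- function(tree, supports) {
  n_tip <- length(tree$tip.label)
  all_leaves <- sort(tree$tip.label)
  anchor <- all_leaves[1]
  sets <- node_leafsets(tree)
  labs <- rep("", tree$Nnode)
  for (nd in (n_tip + 1L):(n_tip + tree$Nnode)) {
    side <- sets[[nd]]
    if (anchor %in% side) side <- setdiff(all_leaves, side)
    key <- paste(side, collapse = "|")
    i <- match(key, supports$bipartition)
    if (!is.na(i)) labs[nd - n_tip] <- format(round(supports$support[i]))
  }
  tree$node.label <- labs
  tree
}

#' Root a tree with a designated outgroup
#'
#' Places the root on the edge separating the outgroup taxa from the rest.
#' The outgroup must be exclusive (form one side of an edge) in the unrooted
#' tree; otherwise a rooting error reporting the offending bipartition is
#' raised.
#'
#' @param tree An [ape::phylo] (unrooted or rooted).
#' @param outgroup_taxa Character vector of outgroup leaf labels.
#' @return A rooted [ape::phylo].
#' @export
root_tree <- function(tree, outgroup_taxa) {
  if (!all(outgroup_taxa %in% tree$tip.label)) {
    stop_pseudophy("lookup_error", sprintf(
      "outgroup taxa not in tree: %s",
      paste(setdiff(outgroup_taxa, tree$tip.label), collapse = ", ")))
  }
  n_tip <- length(tree$tip.label)
  if (n_tip == 2L) return(tree)   # trivial rooting on the single edge
  if (length(outgroup_taxa) >= 2L && length(outgroup_taxa) <= n_tip - 2L) {
    og <- sort(outgroup_taxa)
    comp <- sort(setdiff(tree$tip.label, og))
    anchor <- sort(tree$tip.label)[1]
    key <- if (anchor %in% og) paste(comp, collapse = "|") else
      paste(og, collapse = "|")
    if (!key %in% tree_bipartitions(tree)) {
      stop_pseudophy("rooting_error", sprintf(
        "outgroup {%s} is not exclusive in the unrooted tree (no edge gives bipartition {%s} | {%s})",
        paste(og, collapse = ", "), paste(og, collapse = ", "),
        paste(comp, collapse = ", ")), bipartition = key)
    }
  }
  if (length(outgroup_taxa) == n_tip) {
    stop_pseudophy("rooting_error",
                   "outgroup cannot contain every taxon")
  }
  rooted <- ape::root(tree, outgroup = outgroup_taxa, resolve.root = TRUE)
  ape::reorder.phylo(rooted, "postorder")
}
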