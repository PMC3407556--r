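BASES <- c("A", "C", "G", "T")

#' Planted mutation events for the simulator
#'
#' Events are attached to the branch above the most recent common ancestor of
#' `clade` and are inherited by every descendant leaf. Positions are 1-based
#' coordinates in the ungapped reference sequence (the simulated segment
#' before any insertion columns are added).
#'
#' * `planted_insertion()` inserts `payload` immediately after
#'   `after_ref_pos`; a payload length that is not a multiple of 3 shifts the
#'   downstream reading frame.
#' * `planted_deletion()` removes `length` bases starting at `ref_pos`.
#' * `planted_nonsense()` converts the reference-frame codon starting at
#'   `codon_start` into a stop, substituting the minimal number of bases to
#'   reach `TGA`, or `TAA` when `TGA` is not reachable in one change.
#' * `planted_substitution()` overwrites bases starting at `ref_pos` with
#'   `bases`; the simulator uses it to plant deterministic shifted-frame stop
#'   codons downstream of planted frameshifts. It is generator machinery, not
#'   an inactivating mutation, and does not appear in the truth list.
#'
#' @param clade Character vector of leaf labels defining the branch (the edge
#'   above their MRCA); must correspond exactly to a clade of the tree.
#' @param after_ref_pos,ref_pos,codon_start Reference-coordinate anchors.
#' @param payload,bases Bases to insert / substitute.
#' @param length Number of deleted bases.
#' @return A `planted_event` list.
#' @export
planted_insertion <- function(clade, after_ref_pos, payload) {
  payload <- toupper(payload)
  if (nchar(payload) < 1L) {
    stop_pseudophy("spec_error", "planted insertion payload must be non-empty")
  }
  structure(list(kind = "insertion", clade = clade,
                 after_ref_pos = as.integer(after_ref_pos),
                 payload = payload),
            class = "planted_event")
}

#' @rdname planted_insertion
#' @export
planted_deletion <- function(clade, ref_pos, length) {
  structure(list(kind = "deletion", clade = clade,
                 ref_pos = as.integer(ref_pos), length = as.integer(length)),
            class = "planted_event")
}

#' @rdname planted_insertion
#' @export
planted_nonsense <- function(clade, codon_start) {
  structure(list(kind = "nonsense", clade = clade,
                 codon_start = as.integer(codon_start)),
            class = "planted_event")
}

#' @rdname planted_insertion
#' @export
planted_substitution <- function(clade, ref_pos, bases) {
  structure(list(kind = "substitution", clade = clade,
                 ref_pos = as.integer(ref_pos), bases = toupper(bases)),
            class = "planted_event")
}

#' Simulation specification
#'
#' Bundles everything [simulate_alignment()] needs: a rooted tree with branch
#' lengths (expected substitutions/site), a substitution model, the segment
#' length in codons, planted events, the reference taxon (which must carry no
#' events) and a seed.
#'
#' @param tree Rooted binary [ape::phylo] with branch lengths.
#' @param model An [hky_gamma_model()].
#' @param n_codons Number of complete reference codons to simulate.
#' @param events List of planted events (see [planted_insertion()]).
#' @param reference_taxon Leaf used as the intact reference.
#' @param seed Integer seed; the same seed reproduces the alignment byte for
#'   byte.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(tree, model, n_codons, events = list(),
                            reference_taxon, seed = 1L) {
  if (!inherits(tree, "phylo") || is.null(tree$edge.length)) {
    stop_pseudophy("usage_error", "tree must be a phylo with branch lengths")
  }
  if (!ape::is.rooted(tree)) {
    stop_pseudophy("usage_error", "simulation tree must be rooted")
  }
  if (!reference_taxon %in% tree$tip.label) {
    stop_pseudophy("lookup_error", sprintf(
      "reference taxon '%s' is not a leaf of the tree", reference_taxon))
  }
  n_sites <- 3L * as.integer(n_codons)
  for (ev in events) {
    pos <- switch(ev$kind,
                  insertion = ev$after_ref_pos,
                  deletion = ev$ref_pos + ev$length - 1L,
                  nonsense = ev$codon_start + 2L,
                  substitution = ev$ref_pos + nchar(ev$bases) - 1L)
    if (pos < 1L || pos > n_sites) {
      stop_pseudophy("spec_error", "planted event lies outside the segment")
    }
    if (reference_taxon %in% ev$clade) {
      stop_pseudophy("spec_error",
                     "the reference taxon cannot carry planted events")
    }
    if (!all(ev$clade %in% tree$tip.label)) {
      stop_pseudophy("lookup_error", "event clade names unknown leaves")
    }
    if (ev$kind == "nonsense" && (ev$codon_start - 1L) %% 3L != 0L) {
      stop_pseudophy("spec_error",
                     "planted nonsense must start on a codon boundary")
    }
    clade_node(tree, ev$clade)   # errors unless the clade matches a branch
  }
  structure(list(tree = tree, model = model,
                 n_codons = as.integer(n_codons), events = events,
                 reference_taxon = reference_taxon,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# --- internals --------------------------------------------------------------

# Exact clade node for a set of leaves; errors unless the set is a clade.
clade_node <- function(tree, clade) {
  node <- if (length(clade) == 1L) {
    match(clade, tree$tip.label)
  } else {
    ape::getMRCA(tree, clade)
  }
  leaves <- node_leafsets(tree)[[node]]
  if (!setequal(leaves, clade)) {
    stop_pseudophy("spec_error", sprintf(
      "{%s} is not a clade of the simulation tree",
      paste(sort(clade), collapse = ", ")))
  }
  node
}

# Evolve integer base vector (1..4) along one branch; frozen/deleted sites
# are left untouched. site_cat indexes the per-site gamma category.
evolve_branch <- function(seq, t, model, rates, site_cat, mutable) {
  out <- seq
  for (k in seq_along(rates)) {
    P <- hky_transition_matrix(t * rates[k], model$kappa, unname(model$pi))
    for (b in 1:4) {
      idx <- which(mutable & site_cat == k & seq == b)
      if (length(idx) > 0L) {
        out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
      }
    }
  }
  out
}

is_stop_int <- function(codon) {
  paste(BASES[codon], collapse = "") %in% STOP_CODONS
}

# Force every reference-frame codon that must stay sense back to a sense
# codon (rejection sampling from the parent's bases; deterministic fallback).
enforce_sense <- function(seq, parent_seq, t, model, rates, site_cat,
                          frozen, deleted, exempt_codons, n_codons) {
  repairs <- integer()
  for (ci in seq_len(n_codons)) {
    cs <- 3L * ci - 2L
    sites <- cs:(cs + 2L)
    if (cs %in% exempt_codons) next
    if (any(deleted[sites])) next
    if (!is_stop_int(seq[sites])) next
    mutable <- sites[!frozen[sites]]
    ok <- FALSE
    for (try in seq_len(50L)) {
      for (s in mutable) {
        P <- hky_transition_matrix(t * rates[site_cat[s]], model$kappa,
                                   unname(model$pi))
        seq[s] <- sample.int(4L, 1L, prob = P[parent_seq[s], ])
      }
      if (!is_stop_int(seq[sites])) {
        ok <- TRUE
        break
      }
    }
    if (!ok && length(mutable) > 0L) {
      seq[mutable[1]] <- 2L   # C: no stop codon contains C
    }
    repairs <- c(repairs, ci)
  }
  list(seq = seq, repairs = repairs)
}

#' Simulate a codon alignment with planted inactivating events
#'
#' The root sequence is drawn codon-wise from the model's base frequencies,
#' rejecting in-frame stops. Sequences then evolve down the tree under
#' HKY (+ discrete gamma: each site keeps one rate category throughout).
#' Planted events are applied on their branch and inherited by all
#' descendants; event sites are frozen against further substitution in
#' carrier lineages so shared events remain identical across taxa. Any
#' accidental in-frame stop arising in a codon that is not a carried planted
#' nonsense codon is repaired by resampling, so every taxon without planted
#' events translates cleanly in the reference frame. Insertion payloads
#' appear as gap columns in all non-carrier rows. Deterministic given the
#' spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `alignment` (a [codon_alignment()], reference frame offset
#'   1), `truth` (the planted inactivating mutations as
#'   [inactivating_mutation()] records in alignment coordinates), `tree` (the
#'   generating rooted tree), `repairs` (data frame logging stop-codon
#'   repairs).
#' @examples
#' sim <- simulate_pinniped_fixture(seed = 1)
#' sim$alignment
#' @export
simulate_alignment <- function(spec) {
  withr::with_seed(spec$seed, simulate_alignment_impl(spec))
}

simulate_alignment_impl <- function(spec) {
  tree <- ape::reorder.phylo(spec$tree, "postorder")
  model <- spec$model
  n_sites <- 3L * spec$n_codons
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  rates <- gamma_category_rates(model)
  site_cat <- sample.int(length(rates), n_sites, replace = TRUE)

  # root: sense codons drawn base-wise from pi
  root_seq <- integer(n_sites)
  for (ci in seq_len(spec$n_codons)) {
    repeat {
      cod <- sample.int(4L, 3L, replace = TRUE, prob = unname(model$pi))
      if (!is_stop_int(cod)) break
    }
    root_seq[(3L * ci - 2L):(3L * ci)] <- cod
  }

  ev_nodes <- vapply(spec$events, function(ev) clade_node(tree, ev$clade),
                     integer(1))

  # preorder walk carrying per-lineage state
  state0 <- list(seq = root_seq, frozen = logical(n_sites),
                 deleted = logical(n_sites), exempt = integer(),
                 carries = logical(length(spec$events)))
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- state0
  repairs <- list()
  pre <- rev(seq_len(nrow(tree$edge)))   # reverse postorder = preorder
  for (e in pre) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    st <- states[[p]]
    parent_seq <- st$seq
    mutable <- !st$frozen & !st$deleted
    st$seq <- evolve_branch(st$seq, t, model, rates, site_cat, mutable)
    for (j in which(ev_nodes == ch)) {
      ev <- spec$events[[j]]
      st$carries[j] <- TRUE
      if (ev$kind == "deletion") {
        st$deleted[ev$ref_pos:(ev$ref_pos + ev$length - 1L)] <- TRUE
      } else if (ev$kind == "nonsense") {
        sites <- ev$codon_start:(ev$codon_start + 2L)
        resident <- st$seq[sites]
        target <- choose_stop_target(resident)
        st$seq[sites] <- target
        st$frozen[sites] <- TRUE
        st$exempt <- c(st$exempt, ev$codon_start)
      } else if (ev$kind == "substitution") {
        b <- match(strsplit(ev$bases, "")[[1]], BASES)
        sites <- ev$ref_pos:(ev$ref_pos + length(b) - 1L)
        st$seq[sites] <- b
        st$frozen[sites] <- TRUE
      }
      # insertions carry no reference-coordinate change; payload added later
    }
    fixed <- enforce_sense(st$seq, parent_seq, t, model, rates, site_cat,
                           st$frozen, st$deleted, st$exempt, spec$n_codons)
    st$seq <- fixed$seq
    if (length(fixed$repairs) > 0L) {
      repairs[[length(repairs) + 1L]] <- data.frame(
        node = ch, codon = fixed$repairs, stringsAsFactors = FALSE)
    }
    states[[ch]] <- st
  }

  # column layout: reference positions interleaved with insertion blocks
  ins_idx <- which(vapply(spec$events, `[[`, character(1), "kind") ==
                     "insertion")
  ins_idx <- ins_idx[order(vapply(spec$events[ins_idx], `[[`, integer(1),
                                  "after_ref_pos"))]
  ins_len <- vapply(spec$events[ins_idx], function(ev) nchar(ev$payload),
                    integer(1))
  ins_after <- vapply(spec$events[ins_idx], `[[`, integer(1), "after_ref_pos")
  # column of reference position p
  ref_col <- function(p) p + sum(ins_len[ins_after < p])
  n_columns <- n_sites + sum(ins_len)
  ins_start_col <- vapply(seq_along(ins_idx), function(i)
    ref_col(ins_after[i]) + 1L, integer(1))

  rows <- matrix("-", n_tip, n_columns,
                 dimnames = list(tree$tip.label, NULL))
  ref_cols <- vapply(seq_len(n_sites), ref_col, integer(1))
  for (i in seq_len(n_tip)) {
    st <- states[[i]]
    chars <- BASES[st$seq]
    chars[st$deleted] <- "-"
    rows[i, ref_cols] <- chars
    for (k in seq_along(ins_idx)) {
      if (st$carries[ins_idx[k]]) {
        block <- ins_start_col[k]:(ins_start_col[k] + ins_len[k] - 1L)
        rows[i, block] <- strsplit(spec$events[[ins_idx[k]]]$payload, "")[[1]]
      }
    }
  }

  alignment <- codon_alignment(rows, spec$reference_taxon, frame_offset = 1L)

  truth <- list()
  leafsets <- node_leafsets(tree)
  for (j in seq_along(spec$events)) {
    ev <- spec$events[[j]]
    carriers <- sort(leafsets[[ev_nodes[j]]])
    if (ev$kind == "insertion") {
      k <- match(j, ins_idx)
      truth[[length(truth) + 1L]] <- inactivating_mutation(
        "frameshift_insertion", ins_start_col[k],
        ins_start_col[k] + ins_len[k] - 1L, ins_len[k], carriers,
        bases = ev$payload)
    } else if (ev$kind == "deletion") {
      if (ev$length %% 3L == 0L) next     # in-frame, not inactivating
      truth[[length(truth) + 1L]] <- inactivating_mutation(
        "frameshift_deletion", ref_col(ev$ref_pos),
        ref_col(ev$ref_pos + ev$length - 1L), ev$length, carriers,
        bases = paste(BASES[root_seq[ev$ref_pos:(ev$ref_pos + ev$length - 1L)]],
                      collapse = ""))
    } else if (ev$kind == "nonsense") {
      # all carriers share the frozen planted codon
      leaf1 <- match(carriers[1], tree$tip.label)
      codon <- paste(BASES[states[[leaf1]]$seq[
        ev$codon_start:(ev$codon_start + 2L)]], collapse = "")
      truth[[length(truth) + 1L]] <- inactivating_mutation(
        "nonsense_substitution", ref_col(ev$codon_start),
        ref_col(ev$codon_start + 2L), 3L, carriers, bases = codon)
    }
  }

  list(alignment = alignment, truth = truth, tree = spec$tree,
       repairs = if (length(repairs) > 0L) do.call(rbind, repairs) else
         data.frame(node = integer(), codon = integer()))
}

# Minimal-change stop codon: TGA when reachable in <= 1 substitution,
# else TAA when reachable in one, else TGA.
choose_stop_target <- function(resident) {
  tga <- match(c("T", "G", "A"), BASES)
  taa <- match(c("T", "A", "A"), BASES)
  if (sum(resident != tga) <= 1L) return(tga)
  if (sum(resident != taa) <= 1L) return(taa)
  tga
}

# The deletion truth record reports the reference bases as they stood at the
# root; detect_indels reports the current reference row instead. Tests
# compare positions/kind/taxa, not deletion bases.

#' The 14-taxon pinniped fixture
#'
#' A canonical simulation specification emulating the structure of the real
#' study alignment: 149 reference codons (447 bp, 453 aligned columns once
#' the two planted insertions are included), 14 carnivoran taxa with the
#' domestic dog as intact reference and both canids as outgroup, and five
#' planted inactivating events -- a 4-bp insertion at alignment columns
#' 188-191 on the stem of the four phocids, a 1-bp deletion at column 61 plus
#' a nonsense codon at column 248 on the northern elephant seal terminal
#' branch, a nonsense codon at column 61 on the stem of the two otariids, and
#' a 2-bp insertion at columns 297-298 on the giant panda terminal branch.
#' Deterministic shifted-frame stop codons are planted directly downstream of
#' each frameshift. Default model: kappa 4, pi (0.30, 0.20, 0.25, 0.25),
#' alpha 0.5 with 4 categories; branch lengths 0.02-0.15.
#'
#' @param seed Integer seed passed into the spec.
#' @return A [simulation_spec()]; `attr(spec, "groups")` holds the taxon
#'   groups (phocids, otariids, outgroup).
#' @export
make_pinniped_fixture <- function(seed = 1L) {
  newick <- paste0(
    "((domestic_dog:0.05,red_fox:0.05):0.06,",
    "((intact_carnivoran_1:0.08,intact_carnivoran_2:0.08):0.05,",
    "(((polar_bear:0.06,giant_panda:0.07):0.04,",
    "((((spotted_seal:0.02,harbor_seal:0.02):0.02,caspian_seal:0.03):0.02,",
    "n_elephant_seal:0.05):0.04,",
    "(australian_sea_lion:0.03,s_american_sea_lion:0.03):0.05):0.04):0.03,",
    "(intact_carnivoran_3:0.09,intact_carnivoran_4:0.09):0.05):0.03):0.04);")
  tree <- ape::read.tree(text = newick)
  phocids <- c("spotted_seal", "harbor_seal", "caspian_seal",
               "n_elephant_seal")
  otariids <- c("australian_sea_lion", "s_american_sea_lion")
  events <- list(
    planted_insertion(phocids, after_ref_pos = 187L, payload = "ACCT"),
    planted_substitution(phocids, ref_pos = 189L, bases = "TGA"),
    planted_deletion("n_elephant_seal", ref_pos = 61L, length = 1L),
    planted_substitution("n_elephant_seal", ref_pos = 62L, bases = "TGA"),
    planted_nonsense("n_elephant_seal", codon_start = 244L),
    planted_nonsense(otariids, codon_start = 61L),
    planted_insertion("giant_panda", after_ref_pos = 292L, payload = "CT"),
    planted_substitution("giant_panda", ref_pos = 293L, bases = "TGA"))
  spec <- simulation_spec(
    tree = tree,
    model = hky_gamma_model(kappa = 4, pi = c(0.30, 0.20, 0.25, 0.25),
                            alpha = 0.5, n_categories = 4L),
    n_codons = 149L, events = events, reference_taxon = "domestic_dog",
    seed = seed)
  attr(spec, "groups") <- list(phocids = phocids, otariids = otariids,
                               outgroup = c("domestic_dog", "red_fox"))
  spec
}

#' @rdname make_pinniped_fixture
#' @export
simulate_pinniped_fixture <- function(seed = 1L) {
  spec <- make_pinniped_fixture(seed)
  out <- simulate_alignment(spec)
  attr(out, "groups") <- attr(spec, "groups")
  out
}

#' Simulate unconstrained sites along a tree
#'
#' Plain HKY (+ gamma) site simulator without codon structure, planted events
#' or stop-codon handling; used for likelihood and parameter-recovery
#' checks.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param model An [hky_gamma_model()].
#' @param n_sites Number of independent sites.
#' @param seed Integer seed.
#' @return Character matrix (taxa x sites) over `A,C,G,T`.
#' @export
simulate_sites <- function(tree, model, n_sites, seed = 1L) {
  withr::with_seed(seed, {
    tree <- ape::reorder.phylo(tree, "postorder")
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    rates <- gamma_category_rates(model)
    site_cat <- sample.int(length(rates), n_sites, replace = TRUE)
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample.int(4L, n_sites, replace = TRUE,
                               prob = unname(model$pi))
    for (e in rev(seq_len(nrow(tree$edge)))) {
      p <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      seqs[[ch]] <- evolve_branch(seqs[[p]], tree$edge.length[e], model,
                                  rates, site_cat, rep(TRUE, n_sites))
    }
    out <- matrix("", n_tip, n_sites, dimnames = list(tree$tip.label, NULL))
    for (i in seq_len(n_tip)) out[i, ] <- BASES[seqs[[i]]]
    out
  })
}

#' Wrap a raw site matrix as a phylo_matrix
#'
#' Convenience for analysing [simulate_sites()] output with the likelihood
#' machinery directly.
#'
#' @param states Character matrix (taxa x sites) over `A,C,G,T,?`.
#' @return A `phylo_matrix`.
#' @export
as_phylo_matrix <- function(states) {
  structure(list(taxa = rownames(states), states = states,
                 n_sites = ncol(states),
                 site_to_column = seq_len(ncol(states))),
            class = "phylo_matrix")
}
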