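test_that("event matrices tabulate carriers", {
  sim <- get_fixture(1)
  scan <- classify_orf(sim$alignment)
  M <- build_event_matrix(scan$mutations, sim$alignment$taxa)
  expect_equal(dim(M), c(14L, 5L))
  expect_equal(sum(M[, "frameshift_insertion_188_191"]), 4)
  expect_equal(unname(colSums(M)), c(1, 2, 4, 1, 1))

  expect_equal(ncol(build_event_matrix(list(), sim$alignment$taxa)), 0L)

  all_mut <- inactivating_mutation("frameshift_deletion", 1, 1, 1,
                                   sim$alignment$taxa)
  expect_true(all(build_event_matrix(list(all_mut),
                                     sim$alignment$taxa) == 1L))
  bad <- inactivating_mutation("frameshift_deletion", 1, 1, 1, "nope")
  expect_error(build_event_matrix(list(bad), sim$alignment$taxa),
               class = "pseudophy_usage_error")
})

test_that("fixture events map to their generating branches", {
  sim <- get_fixture(1)
  scan <- classify_orf(sim$alignment)
  groups <- fixture_groups()
  rooted <- ape::reorder.phylo(sim$tree, "postorder")
  M <- build_event_matrix(scan$mutations, sim$alignment$taxa)
  pl <- place_events(rooted, M)
  expect_true(all(pl$dollo_consistent))
  expect_true(all(pl$extra_steps == 0L))
  sets <- pseudophy:::node_leafsets(rooted)
  clade_of <- function(ev) sort(sets[[pl$child_node[pl$event == ev]]])
  expect_equal(clade_of("frameshift_insertion_188_191"),
               sort(groups$phocids))
  expect_equal(clade_of("nonsense_substitution_61_63"),
               sort(groups$otariids))
  expect_equal(clade_of("frameshift_deletion_61_61"), "n_elephant_seal")
  expect_equal(clade_of("nonsense_substitution_248_250"), "n_elephant_seal")
  expect_equal(clade_of("frameshift_insertion_297_298"), "giant_panda")
})

test_that("single-carrier events land on terminal branches", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  M <- matrix(c(0, 0, 1, 0), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), "ev"))
  pl <- place_events(tr, M)
  expect_equal(pl$branch, "c")
  expect_true(pl$dollo_consistent)
})

test_that("homoplasy is flagged with Fitch extra steps, never resolved", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  M <- matrix(c(1, 0, 1, 0), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), "ev"))
  pl <- place_events(tr, M)
  expect_false(pl$dollo_consistent)
  expect_true(pl$root_spanning)   # mrca(a, c) is the root
  expect_equal(pl$extra_steps, 1L)

  # nested non-clade carrier set with an identifiable MRCA
  tr8 <- ape::read.tree(text = paste0(
    "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);"))
  M8 <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), 8, 1,
               dimnames = list(letters[1:8], "ev"))
  pl8 <- place_events(tr8, M8)
  expect_false(pl8$dollo_consistent)
  expect_false(pl8$root_spanning)
  st <- setNames(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), letters[1:8])
  expect_equal(pl8$extra_steps, oracle_min_steps(tr8, st) - 1L)
})

test_that("Fitch step counts equal the brute-force minimum", {
  withr::local_seed(23)
  for (i in 1:30) {
    tr <- random_phylo(sample(4:8, 1))
    st <- setNames(sample(0:1, ape::Ntip(tr), replace = TRUE),
                   tr$tip.label)
    if (all(st == st[1])) st[1] <- 1L - st[1]
    expect_equal(pseudophy:::fitch_steps(tr, st), oracle_min_steps(tr, st))
  }
})

test_that("event ordering follows lineage ancestry", {
  sim <- get_fixture(1)
  scan <- classify_orf(sim$alignment)
  rooted <- ape::reorder.phylo(sim$tree, "postorder")
  M <- build_event_matrix(scan$mutations, sim$alignment$taxa)
  pl <- place_events(rooted, M)
  ord <- order_events(pl, rooted)
  # the shared phocid insertion precedes both elephant-seal-only events
  expect_true(any(ord$first == "frameshift_insertion_188_191" &
                    ord$then == "frameshift_deletion_61_61"))
  expect_true(any(ord$first == "frameshift_insertion_188_191" &
                    ord$then == "nonsense_substitution_248_250"))
  # the two elephant-seal events share a branch: incomparable
  expect_false(any(ord$first == "frameshift_deletion_61_61" &
                     ord$then == "nonsense_substitution_248_250"))
  expect_false(any(ord$first == "nonsense_substitution_248_250" &
                     ord$then == "frameshift_deletion_61_61"))
  # disjoint clades are incomparable
  expect_false(any(ord$first == "nonsense_substitution_61_63" |
                     ord$then == "nonsense_substitution_61_63"))
})

test_that("placement is invariant to leaf order and rotations", {
  sim <- get_fixture(1)
  scan <- classify_orf(sim$alignment)
  M <- build_event_matrix(scan$mutations, sim$alignment$taxa)
  base <- ape::reorder.phylo(sim$tree, "postorder")
  pl1 <- place_events(base, M)
  rotated <- ape::rotateConstr(sim$tree, rev(sort(sim$tree$tip.label)))
  pl2 <- place_events(ape::reorder.phylo(rotated, "postorder"),
                      M[rev(rownames(M)), , drop = FALSE])
  sets1 <- pseudophy:::node_leafsets(base)
  sets2 <- pseudophy:::node_leafsets(ape::reorder.phylo(rotated,
                                                        "postorder"))
  for (ev in pl1$event) {
    c1 <- sets1[[pl1$child_node[pl1$event == ev]]]
    c2 <- sets2[[pl2$child_node[pl2$event == ev]]]
    expect_setequal(c1, c2)
  }
  expect_equal(pl1$dollo_consistent, pl2$dollo_consistent[
    match(pl1$event, pl2$event)])
})
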