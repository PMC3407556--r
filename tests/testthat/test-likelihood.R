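test_that("encoding drops insertions and codes disrupted sites as missing", {
  sim <- get_fixture(1)
  scan <- classify_orf(sim$alignment)
  mat <- encode_for_ml(sim$alignment, scan$mutations)
  expect_equal(mat$n_sites, 447L)
  expect_false(any(c(188:191, 297:298) %in% mat$site_to_column))

  seal <- mat$states["n_elephant_seal", ]
  q_cols <- mat$site_to_column[seal == "?"]
  expect_true(all(c(61L, 248L, 249L, 250L) %in% q_cols))
  # the otariid nonsense codon is missing only in the otariids
  ota <- mat$states["australian_sea_lion", match(61:63, mat$site_to_column)]
  expect_equal(ota, rep("?", 3))
  dog <- mat$states["domestic_dog", ]
  expect_false(any(dog == "?"))

  # no mutations, no gaps: the matrix is the alignment
  aln <- codon_alignment(c(a = "ATGGAA", b = "ATGCAA"), "a")
  m0 <- encode_for_ml(aln, list())
  expect_identical(m0$states, aln$seqs)

  expect_error(
    encode_for_ml(aln, list(inactivating_mutation(
      "nonsense_substitution", 4, 6, 3, "zz", bases = "TAA"))),
    class = "pseudophy_usage_error")
})

test_that("zero-distance limit gives log stationary frequency", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  mat <- as_phylo_matrix(matrix(c("A", "A"), 2, 1,
                                dimnames = list(c("a", "b"), NULL)))
  model <- hky_gamma_model(3, c(0.3, 0.2, 0.25, 0.25), NULL)
  expect_equal(log_likelihood(tr, mat, model), log(0.3), tolerance = 1e-12)
})

test_that("two-sequence likelihood matches the Jukes-Cantor closed form", {
  withr::local_seed(5)
  model <- hky_gamma_model(1, rep(0.25, 4), NULL)
  for (d in c(0.05, 0.3, 1.2)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
    n_same <- 40L
    n_diff <- 25L
    st <- cbind(matrix("A", 2, n_same),
                rbind(rep("A", n_diff), rep("G", n_diff)))
    rownames(st) <- c("a", "b")
    mat <- as_phylo_matrix(st)
    p_same <- 0.25 + 0.75 * exp(-4 * d / 3)
    p_diff <- 0.25 - 0.25 * exp(-4 * d / 3)
    expected <- n_same * log(0.25 * p_same) + n_diff * log(0.25 * p_diff)
    expect_equal(log_likelihood(tr, mat, model), expected, tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force summation over ancestral states", {
  withr::local_seed(9)
  for (i in 1:20) {
    n_tip <- sample(3:5, 1)
    tr <- random_phylo(n_tip)
    model <- random_model()
    st <- random_states(tr$tip.label, sample(5:15, 1))
    mat <- as_phylo_matrix(st)
    expect_equal(log_likelihood(tr, mat, model),
                 oracle_loglik(tr, st, model), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to re-rooting", {
  withr::local_seed(13)
  tr <- random_phylo(6)
  model <- random_model(gamma = TRUE)
  st <- random_states(tr$tip.label, 40)
  mat <- as_phylo_matrix(st)
  ref <- log_likelihood(tr, mat, model)
  expect_equal(log_likelihood(ape::unroot(tr), mat, model), ref,
               tolerance = 1e-8)
  for (og in c("t1", "t3", "t6")) {
    rerooted <- ape::root(ape::unroot(tr), og, resolve.root = TRUE)
    expect_equal(log_likelihood(rerooted, mat, model), ref,
                 tolerance = 1e-8)
  }
})

test_that("site-pattern compression does not change the likelihood", {
  withr::local_seed(17)
  tr <- random_phylo(5)
  model <- random_model()
  st <- random_states(tr$tip.label, 30, missing_frac = 0.2)
  # duplicating every site doubles the log-likelihood exactly
  l1 <- log_likelihood(tr, as_phylo_matrix(st), model)
  l2 <- log_likelihood(tr, as_phylo_matrix(cbind(st, st)), model)
  expect_equal(l2, 2 * l1, tolerance = 1e-10)
  # permuting sites changes nothing
  perm <- sample(ncol(st))
  l3 <- log_likelihood(tr, as_phylo_matrix(st[, perm]), model)
  expect_equal(l3, l1, tolerance = 1e-10)
})

test_that("likelihood agrees with phangorn's pml", {
  withr::local_seed(21)
  tr <- random_phylo(5)
  model <- hky_gamma_model(3.2, c(0.31, 0.18, 0.24, 0.27), 0.6, 4L)
  st <- random_states(tr$tip.label, 60, missing_frac = 0)
  dat <- phangorn::phyDat(st, type = "DNA")
  fit <- phangorn::pml(tr, dat, bf = unname(model$pi),
                       Q = c(1, 3.2, 1, 1, 3.2, 1), k = 4, shape = 0.6)
  expect_equal(log_likelihood(tr, as_phylo_matrix(st), model),
               as.numeric(fit$logLik), tolerance = 1e-6)
})

test_that("leaf/taxon mismatches are rejected", {
  tr <- ape::read.tree(text = "(a:0.1,(b:0.1,zzz:0.1):0.1);")
  mat <- as_phylo_matrix(random_states(c("a", "b", "c"), 5))
  expect_error(log_likelihood(tr, mat, hky_gamma_model()),
               class = "pseudophy_usage_error")
})
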