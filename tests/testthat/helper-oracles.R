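# Independent oracles: everything here avoids the package's closed-form
# transition matrix and pruning kernel so the two routes stay separate.

# HKY transition probabilities via eigendecomposition of the rate matrix
# (symmetrised through the stationary distribution).
oracle_pmat <- function(t, kappa, pi) {
  transitions <- matrix(c(FALSE, FALSE, TRUE, FALSE,
                          FALSE, FALSE, FALSE, TRUE,
                          TRUE, FALSE, FALSE, FALSE,
                          FALSE, TRUE, FALSE, FALSE), 4, 4)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) Q[i, j] <- pi[j] * ifelse(transitions[i, j], kappa, 1)
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / d) %*% eg$vectors %*% diag(exp(eg$values * t)) %*%
    t(eg$vectors) %*% diag(d)
  pmax(P, 0)
}

# Likelihood by brute-force summation over all internal-node state
# assignments (trees of <= 5 taxa). `states` is a character matrix
# (taxa x sites) over A,C,G,T,? .
oracle_loglik <- function(tree, states, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  internals <- sort(unique(tree$edge[, 1]))
  m <- length(internals)
  root <- tree$edge[nrow(tree$edge), 1]
  n_sites <- ncol(states)
  base_idx <- function(ch) match(ch, c("A", "C", "G", "T"))
  rates <- pseudophy::gamma_category_rates(model)
  pi <- unname(model$pi)
  site_lik <- rep(0, n_sites)
  for (rate in rates) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      oracle_pmat(tree$edge.length[e] * rate, model$kappa, pi))
    grid <- as.matrix(expand.grid(rep(list(1:4), m)))
    for (g in seq_len(nrow(grid))) {
      assign_state <- integer(n_tip + tree$Nnode)
      assign_state[internals] <- grid[g, ]
      lik <- rep(pi[assign_state[root]], n_sites)
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]
        ch <- tree$edge[e, 2]
        if (ch <= n_tip) {
          obs <- states[tree$tip.label[ch], ]
          f <- rep(1, n_sites)
          known <- obs != "?"
          f[known] <- Ps[[e]][assign_state[p], base_idx(obs[known])]
          lik <- lik * f
        } else {
          lik <- lik * Ps[[e]][assign_state[p], assign_state[ch]]
        }
      }
      site_lik <- site_lik + lik
    }
  }
  sum(log(site_lik / length(rates)))
}

# Minimum number of changes of a binary character by exhaustive search over
# ancestral labelings (small trees only).
oracle_min_steps <- function(tree, states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  internals <- sort(unique(tree$edge[, 1]))
  m <- length(internals)
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- integer(n_tip + tree$Nnode)
    lab[seq_len(n_tip)] <- states[tree$tip.label]
    lab[internals] <- grid[g, ]
    steps <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, steps)
  }
  best
}

random_phylo <- function(n_tip, min_len = 0.02, max_len = 0.5) {
  tr <- ape::rtree(n_tip, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
  tr$tip.label <- paste0("t", seq_len(n_tip))
  tr
}

random_model <- function(gamma = NA) {
  pi <- runif(4, 0.1, 1)
  pi <- pi / sum(pi)
  use_gamma <- if (is.na(gamma)) runif(1) < 0.5 else gamma
  hky_gamma_model(kappa = runif(1, 0.5, 8), pi = pi,
                  alpha = if (use_gamma) runif(1, 0.2, 2) else NULL,
                  n_categories = 4L)
}

random_states <- function(taxa, n_sites, missing_frac = 0.1) {
  st <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * n_sites,
                      replace = TRUE),
               length(taxa), n_sites, dimnames = list(taxa, NULL))
  miss <- runif(length(st)) < missing_frac
  st[miss] <- "?"
  st
}
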