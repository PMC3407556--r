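# Branch-length bounds (expected substitutions/site) and convergence
# tolerance (log-likelihood units) for all optimisers in the package.
BL_MIN <- 1e-8
BL_MAX <- 10
LOGL_TOL <- 1e-6
KAPPA_RANGE <- c(0.02, 100)
ALPHA_RANGE <- c(0.05, 20)

observed_base_freqs <- function(matrix) {
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    sum(matrix$states == b), numeric(1))
  counts <- counts + 1e-6   # guard against absent bases
  counts / sum(counts)
}

model_spec_table <- function() {
  data.frame(
    type = rep(c("jc", "k80", "f81", "hky"), 2L),
    gamma = rep(c(FALSE, TRUE), each = 4L),
    n_subst_par = rep(c(0L, 1L, 3L, 4L), 2L) + rep(c(0L, 1L), each = 4L),
    stringsAsFactors = FALSE)
}

#' Fit a substitution model on a fixed topology
#'
#' Coordinate-ascent maximum likelihood: each sweep optimises every branch
#' length (Brent search on `[1e-8, 10]`), then `kappa` (K80/HKY) and the
#' gamma shape `alpha` (when rate variation is modelled) on log scale. Base
#' frequencies are the observed frequencies (F81/HKY) or 1/4 (JC/K80). Sweeps
#' repeat until the log-likelihood improves by less than `1e-6` or
#' `max_sweeps` is reached; the log-likelihood is non-decreasing across
#' sweeps.
#'
#' The AIC parameter count `k` comprises the substitution-model free
#' parameters (JC 0, K80 1, F81 3, HKY 4; +1 for gamma) plus one branch
#' length per edge.
#'
#' @param tree Fixed topology ([ape::phylo]); existing branch lengths are
#'   used as the starting point when present.
#' @param matrix A [encode_for_ml()] result.
#' @param type Substitution model: `"jc"`, `"k80"`, `"f81"` or `"hky"`.
#' @param gamma Model among-site rate variation with a discrete gamma?
#' @param n_categories Gamma categories (default 4).
#' @param max_sweeps Cap on coordinate-ascent sweeps.
#' @return An object of class `model_fit`: `model` ([hky_gamma_model()] with
#'   the constrained parameters), `tree` (optimised branch lengths), `logL`,
#'   `k`, `aic`, `type`, `gamma`, `n_sweeps`.
#' @export
fit_model <- function(tree, matrix, type = "hky", gamma = TRUE,
                      n_categories = 4L, max_sweeps = 50L) {
  type <- match.arg(type, c("jc", "k80", "f81", "hky"))
  prep <- prepare_loglik(tree, matrix)
  n_edge <- nrow(prep$edge)
  lengths <- prep$tree$edge.length %||% rep(0.05, n_edge)
  lengths <- pmin(pmax(lengths, BL_MIN), BL_MAX)

  pi <- if (type %in% c("f81", "hky")) observed_base_freqs(matrix) else
    rep(0.25, 4)
  kappa <- if (type %in% c("k80", "hky")) 2 else 1
  alpha <- if (gamma) 0.5 else NULL

  mk_model <- function() hky_gamma_model(kappa, pi, alpha, n_categories)
  cur <- loglik_prepared(prep, lengths, mk_model())
  if (!is.finite(cur)) {
    stop_pseudophy("numeric_error", "non-finite likelihood at starting point")
  }

  sweep <- 0L
  repeat {
    sweep <- sweep + 1L
    prev <- cur
    model <- mk_model()
    for (e in seq_len(n_edge)) {
      opt <- optimize(function(x) {
        lengths[e] <- x
        loglik_prepared(prep, lengths, model)
      }, interval = c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-4)
      if (opt$objective > cur) {
        lengths[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (type %in% c("k80", "hky")) {
      opt <- optimize(function(lk) {
        loglik_prepared(prep, lengths,
                        hky_gamma_model(exp(lk), pi, alpha, n_categories))
      }, interval = log(KAPPA_RANGE), maximum = TRUE, tol = 1e-4)
      if (opt$objective > cur) {
        kappa <- exp(opt$maximum)
        cur <- opt$objective
      }
    }
    if (gamma) {
      opt <- optimize(function(la) {
        loglik_prepared(prep, lengths,
                        hky_gamma_model(kappa, pi, exp(la), n_categories))
      }, interval = log(ALPHA_RANGE), maximum = TRUE, tol = 1e-4)
      if (opt$objective > cur) {
        alpha <- exp(opt$maximum)
        cur <- opt$objective
      }
    }
    if (cur - prev < LOGL_TOL || sweep >= max_sweeps) break
  }

  fitted_tree <- prep$tree
  fitted_tree$edge.length <- lengths
  n_subst <- switch(type, jc = 0L, k80 = 1L, f81 = 3L, hky = 4L) +
    as.integer(gamma)
  k <- n_subst + n_edge
  structure(
    list(model = mk_model(), tree = fitted_tree, logL = cur, k = k,
         aic = 2 * k - 2 * cur, type = type, gamma = gamma,
         n_sweeps = sweep),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s%s fit: logL = %.4f, k = %d, AIC = %.4f\n",
              toupper(x$type), if (x$gamma) "+G" else "", x$logL, x$k, x$aic))
  invisible(x)
}

#' Select a substitution model by AIC
#'
#' Fits the nested candidate set {JC69, K80, F81, HKY85} x {uniform rates,
#' +gamma} on the given topology and returns the fit minimising
#' `AIC = 2k - 2 logL`; ties are broken toward fewer parameters.
#'
#' @inheritParams fit_model
#' @return The winning `model_fit`, with the full comparison in
#'   `$candidates` (a data frame of type, gamma, logL, k, AIC).
#' @export
select_model <- function(matrix, tree, n_categories = 4L) {
  specs <- model_spec_table()
  fits <- lapply(seq_len(nrow(specs)), function(i)
    fit_model(tree, matrix, specs$type[i], specs$gamma[i], n_categories))
  tab <- data.frame(
    type = specs$type, gamma = specs$gamma,
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE)
  best <- order(tab$aic, tab$k)[1]
  fit <- fits[[best]]
  fit$candidates <- tab
  fit
}
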