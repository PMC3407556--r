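#' HKY85 (+ discrete gamma) substitution model
#'
#' Parameter container for the nucleotide substitution model family used by
#' the likelihood machinery: transition/transversion rate ratio `kappa`, base
#' frequencies `pi` (A, C, G, T), and optional gamma-distributed among-site
#' rate variation with shape `alpha` discretised into `n_categories`
#' equal-probability categories (category rates are category means and average
#' exactly 1). Special cases: `kappa = 1` and equal `pi` gives JC69;
#' `kappa = 1` alone gives F81; equal `pi` alone gives K80.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param pi Base frequencies in A, C, G, T order; positive, summing to 1.
#' @param alpha Gamma shape (> 0), or `NULL` for rate homogeneity.
#' @param n_categories Number of discrete gamma categories (default 4).
#' @return An object of class `hky_gamma_model`.
#' @examples
#' m <- hky_gamma_model(kappa = 4, pi = c(0.3, 0.2, 0.25, 0.25), alpha = 0.5)
#' gamma_category_rates(m)
#' @export
hky_gamma_model <- function(kappa = 4, pi = rep(0.25, 4), alpha = NULL,
                            n_categories = 4L) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    stop_pseudophy("usage_error", "kappa must be a positive number")
  }
  if (length(pi) != 4L || any(!is.finite(pi)) || any(pi <= 0)) {
    stop_pseudophy("usage_error", "pi must be 4 positive frequencies")
  }
  if (abs(sum(pi) - 1) > 1e-8) {
    stop_pseudophy("usage_error", "pi must sum to 1")
  }
  pi <- pi / sum(pi)
  if (!is.null(alpha)) {
    if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
        alpha <= 0) {
      stop_pseudophy("usage_error", "alpha must be a positive number or NULL")
    }
  }
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) {
    stop_pseudophy("usage_error", "n_categories must be >= 1")
  }
  structure(list(kappa = kappa, pi = setNames(pi, c("A", "C", "G", "T")),
                 alpha = alpha, n_categories = n_categories),
            class = "hky_gamma_model")
}

#' @export
print.hky_gamma_model <- function(x, ...) {
  cat(sprintf("HKY%s model: kappa = %.4g, pi = (%s)%s\n",
              if (is.null(x$alpha)) "" else "+G", x$kappa,
              paste(sprintf("%.3f", x$pi), collapse = ", "),
              if (is.null(x$alpha)) "" else
                sprintf(", alpha = %.4g (%d categories)", x$alpha,
                        x$n_categories)))
  invisible(x)
}

#' Discrete-gamma category rates (mean rule)
#'
#' Rates of `k` equal-probability categories of a Gamma(shape = alpha,
#' rate = alpha) distribution, each category represented by its conditional
#' mean, renormalised so the rates average exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  q <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  # E[X | a < X <= b] over equal-probability slices via the Gamma(alpha+1)
  # identity; multiplying the probability-mass differences by k gives means
  p <- pgamma(c(0, q, Inf), shape = alpha + 1, rate = alpha)
  r <- diff(p) * k
  r / mean(r)
}

#' Category rates of a model
#'
#' @param model An [hky_gamma_model()].
#' @return Numeric vector of per-category relative rates (just `1` for a
#'   rate-homogeneous model).
#' @export
gamma_category_rates <- function(model) {
  if (is.null(model$alpha)) return(1)
  discrete_gamma_rates(model$alpha, model$n_categories)
}

#' HKY transition probability matrix
#'
#' Closed-form P(t) for the HKY85 rate matrix scaled to one expected
#' substitution per site per unit time.
#'
#' @param t Branch length (expected substitutions/site), >= 0.
#' @param kappa Transition/transversion rate ratio.
#' @param pi Base frequencies (A, C, G, T).
#' @return 4x4 row-stochastic matrix with rows/columns A, C, G, T.
#' @export
hky_transition_matrix <- function(t, kappa, pi) {
  P <- hky_transition_matrix_cpp(t, kappa, pi)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}
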