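#' Fit a Gaussian mixture to NUPT percent-identity values
#'
#' Percent identity to the plastid donor decays with insertion age, so the
#' identity distribution of a two-episode NUPT complement is bimodal. A
#' k-component univariate Gaussian mixture is fitted by
#' expectation-maximization with deterministic initialization: component
#' means at evenly spaced sample quantiles (the 25th/75th percentiles for
#' k = 2), equal weights, pooled standard deviation. Components are
#' reported sorted ascending by mean, so component 1 is always the older
#' (lower-identity) episode.
#'
#' @param identities numeric vector of percent identities in \[0, 100\],
#'   n >= 10.
#' @param k number of components (1, 2 or 3; default 2).
#' @param seed integer recorded in the fit (the fit itself is
#'   deterministic).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return object of class `nupt_mixture`: list with `k`, `means`, `sds`,
#'   `weights`, `loglik`, `loglik_trace`, `n_iter`, `converged`, `seed`,
#'   `n`.
#' @export
fit_identity_mixture <- function(identities, k = 2, seed = 1L,
                                 tol = 1e-8, max_iter = 1000L) {
  x <- as.numeric(identities)
  if (any(!is.finite(x))) stop("identities must be finite")
  if (length(x) < 10L) stop("need at least 10 identity values")
  if (any(x < 0 | x > 100)) stop("identities must lie in [0, 100]")
  if (!(k %in% 1:3)) stop("k must be 1, 2 or 3")
  if (stats::sd(x) == 0) stop("degenerate fit: all identity values identical")

  sd_floor <- 1e-3
  n <- length(x)

  if (k == 1L) {
    mu <- mean(x)
    sigma <- max(sqrt(mean((x - mu)^2)), sd_floor)  # population MLE
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(structure(list(k = 1L, means = mu, sds = sigma, weights = 1,
                          loglik = ll, loglik_trace = ll, n_iter = 0L,
                          converged = TRUE, seed = seed, n = n),
                     class = "nupt_mixture"))
  }

  probs <- (2 * seq_len(k) - 1) / (2 * k)   # k=2 -> 0.25, 0.75
  mu <- as.numeric(stats::quantile(x, probs, names = FALSE))
  if (any(duplicated(mu))) mu <- mu + (seq_len(k) - 1) * 1e-6
  sigma <- rep(max(stats::sd(x), sd_floor), k)
  w <- rep(1 / k, k)

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  gamma <- NULL
  while (it < max_iter) {
    it <- it + 1L
    # E-step in log space
    logdens <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE),
      numeric(n))
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    gamma <- exp(logdens - lse)
    # M-step
    nk <- colSums(gamma)
    w <- nk / n
    mu <- colSums(gamma * x) / nk
    sigma <- pmax(sqrt(colSums(gamma * (outer(x, mu, "-"))^2) / nk),
                  sd_floor)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  ord <- order(mu)
  structure(list(k = as.integer(k), means = mu[ord], sds = sigma[ord],
                 weights = w[ord], loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace, n_iter = it,
                 converged = converged, seed = seed, n = n),
            class = "nupt_mixture")
}

#' @export
print.nupt_mixture <- function(x, ...) {
  cat("Gaussian mixture on percent identity (k =", x$k, ")\n")
  for (j in seq_len(x$k))
    cat(sprintf("  component %d: mean %.3f, sd %.3f, weight %.3f\n",
                j, x$means[j], x$sds[j], x$weights[j]))
  cat(sprintf("  loglik %.4f after %d iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Posterior component probabilities for identity values
#' @param fit a `nupt_mixture`.
#' @param identities numeric vector in \[0, 100\].
#' @return matrix (n x k) of posteriors; rows sum to 1.
#' @export
mixture_posterior <- function(fit, identities) {
  x <- as.numeric(identities)
  if (any(!is.finite(x) | x < 0 | x > 100))
    stop("identities must be finite and in [0, 100]")
  logdens <- vapply(seq_len(fit$k), function(j)
    log(fit$weights[j]) + stats::dnorm(x, fit$means[j], fit$sds[j],
                                       log = TRUE),
    numeric(length(x)))
  logdens <- matrix(logdens, nrow = length(x))
  m <- apply(logdens, 1, max)
  exp(logdens - (m + log(rowSums(exp(logdens - m)))))
}

#' Assign NUPTs to age classes by posterior probability
#'
#' The lower-mean component is episode I (older, more diverged), the
#' higher-mean component episode II (younger). A NUPT is labeled only when
#' its maximum posterior reaches the threshold; otherwise it is
#' `unclassified`.
#'
#' @param fit a two-component `nupt_mixture`.
#' @param identities percent identities in \[0, 100\].
#' @param threshold posterior probability threshold in (0.5, 1\];
#'   default 0.95.
#' @param ids optional NUPT identifiers.
#' @return data.frame with `nupt_id`, `gamma_I`, `gamma_II`, `label`
#'   (one of `"I"`, `"II"`, `"unclassified"`) and `threshold`.
#' @export
assign_age_class <- function(fit, identities, threshold = 0.95, ids = NULL) {
  stopifnot(inherits(fit, "nupt_mixture"))
  if (fit$k != 2L) stop("age classification requires a k = 2 fit")
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  g <- mixture_posterior(fit, identities)
  if (is.null(ids)) ids <- sprintf("NUPT_%05d", seq_along(identities))
  lab <- rep("unclassified", length(identities))
  lab[g[, 1] >= threshold] <- "I"
  lab[g[, 2] >= threshold] <- "II"
  data.frame(nupt_id = ids, gamma_I = g[, 1], gamma_II = g[, 2],
             label = lab, threshold = threshold, stringsAsFactors = FALSE)
}
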