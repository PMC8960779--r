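#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Direct expectation-maximization for a two-component 1-D Gaussian mixture,
#' used to dichotomize a marker's bulk expression across samples. The best of
#' `n_init` initializations by final log-likelihood is returned: the first
#' initialization is deterministic (component means at the empirical 25th and
#' 75th percentiles, common standard deviation, equal weights), the remaining
#' ones draw two distinct observations as starting means. Component variances
#' are floored at `1e-6` times the sample variance to prevent collapse on
#' near-duplicate values. Components are ordered so component 2 has the
#' larger mean.
#'
#' @param values Numeric vector of per-sample expression (>= 4 finite values
#'   with positive variance).
#' @param n_init Number of initializations (default 5).
#' @param max_iter Maximum EM iterations per initialization (default 200).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-8).
#' @param seed Integer seed for the random restarts.
#'
#' @return An object of class `"gmm1d"`: `means`, `sds`, `weights` (component
#'   2 = high mean), `posterior` (per-sample probability of the high-mean
#'   component), `loglik`, `n_iter`, `converged`, `seed`.
#' @export
fit_gmm_1d <- function(values, n_init = 5L, max_iter = 200L, tol = 1e-8,
                       seed = 1L) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4L) stopf("need at least 4 finite values to fit a 2-component mixture")
  if (stats::var(x) == 0) stopf("degenerate input: all values are equal")
  var_floor <- 1e-6 * stats::var(x)

  em_run <- function(mu, sigma, w) {
    ll_old <- -Inf
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      d1 <- stats::dnorm(x, mu[1], sigma[1], log = TRUE) + log(w[1])
      d2 <- stats::dnorm(x, mu[2], sigma[2], log = TRUE) + log(w[2])
      m <- pmax(d1, d2)
      lse <- m + log(exp(d1 - m) + exp(d2 - m))
      r2 <- exp(d2 - lse)
      r1 <- 1 - r2
      ll <- sum(lse)
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
      ll_old <- ll
      n1 <- sum(r1); n2 <- sum(r2)
      w <- c(n1, n2) / n
      mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
      sigma <- sqrt(pmax(c(sum(r1 * (x - mu[1])^2) / n1,
                           sum(r2 * (x - mu[2])^2) / n2), var_floor))
    }
    list(mu = mu, sigma = sigma, w = w, ll = ll, r2 = r2,
         iter = iter, converged = converged)
  }

  fits <- with_seed(seed, {
    sd0 <- stats::sd(x)
    inits <- list(list(mu = stats::quantile(x, c(0.25, 0.75), names = FALSE),
                       sigma = c(sd0, sd0) / 2, w = c(0.5, 0.5)))
    if (n_init > 1L) {
      for (i in seq_len(n_init - 1L)) {
        mu0 <- sort(sample(x, 2L))
        while (mu0[1] == mu0[2]) mu0 <- sort(sample(x, 2L)) + c(0, 1e-8)
        inits[[i + 1L]] <- list(mu = mu0, sigma = c(sd0, sd0) / 2,
                                w = c(0.5, 0.5))
      }
    }
    lapply(inits, function(ini) em_run(ini$mu, ini$sigma, ini$w))
  })
  best <- fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]

  # normalize order: component 2 has the larger mean
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu); best$sigma <- rev(best$sigma)
    best$w <- rev(best$w); best$r2 <- 1 - best$r2
  }
  post <- rep(NA_real_, length(values))
  post[is.finite(values)] <- best$r2
  names(post) <- names(values)
  structure(list(means = best$mu, sds = best$sigma, weights = best$w,
                 posterior = post, loglik = best$ll, n_iter = best$iter,
                 converged = best$converged, seed = as.integer(seed)),
            class = "gmm1d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat(sprintf("gmm1d: means (%.3f, %.3f), sds (%.3f, %.3f), weights (%.3f, %.3f)\n",
              x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2]))
  cat(sprintf("  loglik %.4f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Dichotomize samples on a fitted marker mixture
#'
#' A sample is called positive for the marker iff its posterior probability
#' of the high-mean component exceeds 0.5; an exact 0.5 posterior resolves to
#' negative.
#'
#' @param fit A `"gmm1d"` object.
#' @return Logical vector of per-sample positive calls (NA where the input
#'   value was not finite).
#' @export
dichotomize_marker <- function(fit) {
  if (!inherits(fit, "gmm1d")) stopf("`fit` must be a gmm1d object")
  fit$posterior > 0.5
}

#' Four-way bulk cohort classification from two marker calls
#'
#' Combines the per-sample positive/negative calls of two markers into the
#' four classes A+B-, A-B+, A-B-, A+B+ and reports the concordant fraction:
#' the share of samples falling in the two mutually exclusive classes (A+B-
#' or A-B+).
#'
#' @param callsA,callsB Logical per-sample call vectors over the same
#'   samples, as from [dichotomize_marker()].
#' @param marker_names Length-2 character vector used in class labels.
#'
#' @return A list of class `"bulk_subtypes"`: `samples` (sample, posA, posB,
#'   class), `counts` (four-way class counts), `concordant_fraction`.
#' @export
classify_bulk_cohort <- function(callsA, callsB,
                                 marker_names = c("S100P", "SPP1")) {
  if (length(callsA) != length(callsB)) {
    stopf("the two call vectors cover different sample sets")
  }
  if (!is.null(names(callsA)) && !is.null(names(callsB)) &&
      !identical(names(callsA), names(callsB))) {
    stopf("the two call vectors cover different sample sets")
  }
  lv <- c(paste0(marker_names[1], "+", marker_names[2], "-"),
          paste0(marker_names[1], "-", marker_names[2], "+"),
          paste0(marker_names[1], "-", marker_names[2], "-"),
          paste0(marker_names[1], "+", marker_names[2], "+"))
  cls <- ifelse(callsA & !callsB, lv[1],
                ifelse(!callsA & callsB, lv[2],
                       ifelse(!callsA & !callsB, lv[3], lv[4])))
  cls <- factor(cls, levels = lv)
  ids <- names(callsA) %||% sprintf("S%03d", seq_along(callsA))
  counts <- table(cls)
  structure(list(
    samples = data.frame(sample = ids, posA = unname(callsA),
                         posB = unname(callsB), class = cls,
                         stringsAsFactors = FALSE),
    counts = counts,
    concordant_fraction = unname((counts[1L] + counts[2L]) / sum(counts))
  ), class = "bulk_subtypes")
}

#' @export
print.bulk_subtypes <- function(x, ...) {
  print(x$counts)
  cat(sprintf("concordant fraction: %.2f%%\n", 100 * x$concordant_fraction))
  invisible(x)
}

#' GMM-based two-marker subtyping of a bulk cohort
#'
#' Convenience wrapper: fits a two-component Gaussian mixture to each
#' marker's expression row, dichotomizes both, and classifies the cohort.
#'
#' @param expr Genes x samples matrix of (log-scale) expression.
#' @param markerA,markerB Marker row names.
#' @param seed Integer seed passed to both fits.
#' @param ... Further arguments to [fit_gmm_1d()].
#'
#' @return A `"bulk_subtypes"` object with the two fits attached as `fitA`,
#'   `fitB`.
#' @export
subtype_bulk_cohort <- function(expr, markerA = "S100P", markerB = "SPP1",
                                seed = 1L, ...) {
  for (g in c(markerA, markerB)) {
    if (!g %in% rownames(expr)) stopf("marker '%s' not in matrix", g)
  }
  fitA <- fit_gmm_1d(stats::setNames(expr[markerA, ], colnames(expr)),
                     seed = derive_seed(seed, 1L), ...)
  fitB <- fit_gmm_1d(stats::setNames(expr[markerB, ], colnames(expr)),
                     seed = derive_seed(seed, 2L), ...)
  out <- classify_bulk_cohort(dichotomize_marker(fitA), dichotomize_marker(fitB),
                              marker_names = c(markerA, markerB))
  out$fitA <- fitA
  out$fitB <- fitB
  out
}
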