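# Minimum covariance determinant (MCD) estimation.
#
# The FAST-MCD algorithm of Rousseeuw & Van Driessen: random
# (p+1)-element starting subsets are refined by concentration steps
# (recompute center/scatter from the current subset, keep the h
# observations with smallest Mahalanobis distance) until the subset is
# stable; the subset with the smallest covariance determinant wins. For
# small n the search is exhaustive over all h-subsets, which makes the
# estimator exactly the MCD. The returned scatter carries the usual
# consistency factor so that on clean Gaussian data it estimates the
# ordinary covariance.

# consistency factor for the h/n-trimmed Gaussian scatter
.mcd_consistency <- function(alpha, p) {
  alpha / stats::pchisq(stats::qchisq(alpha, df = p), df = p + 2)
}

.safe_mahalanobis <- function(x, center, cov) {
  p <- ncol(x)
  tryCatch(stats::mahalanobis(x, center, cov),
           error = function(e) {
             tr <- sum(diag(cov))
             ridge <- if (tr > 0) 1e-10 * tr / p else 1e-12
             stats::mahalanobis(x, center, cov + diag(ridge, p))
           })
}

#' Minimum covariance determinant location and scatter
#'
#' @param x numeric matrix (observations x variables).
#' @param h size of the support subset; default
#'   `floor((n + p + 1) / 2)` (the standard high-breakdown choice).
#' @param nstarts number of random starting subsets of the iterative
#'   search (used when exhaustive search is infeasible).
#' @param max_csteps concentration-step cap per start.
#' @param exhaustive_limit exhaustive search is used when the number of
#'   h-subsets is at most this.
#' @param seed integer seed for the random starts.
#' @return list with `center`, `cov` (consistency-corrected), `best`
#'   (sorted indices of the optimal subset), `crit` (log-determinant of
#'   the uncorrected subset covariance), `h`, `n`.
#' @export
mcd_cov <- function(x, h = NULL, nstarts = 20, max_csteps = 30,
                    exhaustive_limit = 10000, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < p + 2) stop("need at least p + 2 observations")
  h <- h %||% floor((n + p + 1) / 2)
  stopifnot(h > p, h <= n)

  subset_fit <- function(idx) {
    xs <- x[idx, , drop = FALSE]
    list(center = colMeans(xs), cov = stats::cov(xs))
  }
  log_det <- function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }

  if (choose(n, h) <= exhaustive_limit) {
    combs <- utils::combn(n, h)
    crits <- apply(combs, 2, function(idx) log_det(stats::cov(
      x[idx, , drop = FALSE])))
    best <- combs[, which.min(crits)]
    fit <- subset_fit(best)
    crit <- min(crits)
  } else {
    best <- NULL
    crit <- Inf
    with_seed(derive_seed(seed, "mcd"), {
      for (s in seq_len(nstarts)) {
        idx <- sample.int(n, p + 1)
        for (it in seq_len(max_csteps)) {
          f <- subset_fit(idx)
          d2 <- .safe_mahalanobis(x, f$center, f$cov)
          new_idx <- sort(order(d2)[seq_len(h)])
          if (identical(new_idx, idx)) break
          idx <- new_idx
        }
        f <- subset_fit(idx)
        cr <- log_det(f$cov)
        if (cr < crit) {
          crit <- cr
          best <- idx
        }
      }
    })
    fit <- subset_fit(best)
  }
  list(center = fit$center,
       cov = fit$cov * .mcd_consistency(h / n, p),
       best = sort(best), crit = crit, h = h, n = n)
}
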