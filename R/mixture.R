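## Adaptive correlation cutoff: fit 1-3 unequal-variance Gaussian
## components to a pooled set of correlation coefficients by EM, pick the
## component count by BIC, then derive a cutoff from the fitted model and
## clamp it to a permitted range (default 0.4-0.6).

#' Fit a 1-3 component univariate Gaussian mixture
#'
#' EM with unequal component variances is run for each component count
#' `k = 1..kmax`; the fit minimizing BIC is returned. Initialization
#' partitions the sorted values into `k` contiguous equal-size blocks, so
#' the fit is deterministic for a given input.
#'
#' @param values Numeric vector (correlation coefficients, in `[-1, 1]`
#'   in normal use, though any finite values are accepted).
#' @param kmax Maximum number of components (1-3). Default 3.
#' @param min_n Minimum number of values for a trustworthy fit; fewer
#'   raises a condition of class `clustann_too_few_values` so callers can
#'   fall back to [default_cutoff()]. Default 50.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `mixture_fit`: list with `k`, `weights`,
#'   `means`, `sds` (components sorted by ascending mean), `loglik`,
#'   `criterion` (BIC, smaller is better), `n`.
#' @export
fit_mixture <- function(values, kmax = 3, min_n = 50, max_iter = 200,
                        tol = 1e-8) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < min_n) {
    stop(structure(class = c("clustann_too_few_values", "error", "condition"),
                   list(message = sprintf(
                     "only %d value(s), need at least %d for a mixture fit",
                     n, min_n), call = NULL)))
  }
  stopifnot(kmax >= 1, kmax <= 3)
  fits <- lapply(seq_len(kmax), function(k) em_gaussian(values, k, max_iter, tol))
  bics <- vapply(fits, function(f) f$criterion, numeric(1))
  best <- fits[[which.min(bics)]]
  structure(best, class = "mixture_fit")
}

# EM for a k-component univariate Gaussian mixture, unequal variances.
# Deterministic init: k contiguous blocks of the sorted data.
em_gaussian <- function(x, k, max_iter = 200, tol = 1e-8) {
  n <- length(x)
  xs <- sort(x)
  block <- ceiling(seq_along(xs) / (n / k))
  block[block > k] <- k
  mu <- as.numeric(tapply(xs, block, mean))
  sd_floor <- max(stats::sd(x), .Machine$double.eps) * 1e-4
  sg <- as.numeric(tapply(xs, block, stats::sd))
  sg[!is.finite(sg) | sg < sd_floor] <- sd_floor
  w <- as.numeric(tabulate(block, k)) / n
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E step in log space for stability
    logd <- vapply(seq_len(k), function(j) {
      stats::dnorm(x, mu[j], sg[j], log = TRUE) + log(w[j])
    }, numeric(n))
    if (k == 1L) logd <- matrix(logd, ncol = 1L)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    r <- exp(logd - lse)
    # M step
    nk <- colSums(r)
    nk[nk < .Machine$double.eps] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(r * x) / nk
    sg <- sqrt(colSums(r * (outer(x, mu, "-")^2)) / nk)
    sg[sg < sd_floor] <- sd_floor
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  p <- 3 * k - 1  # k-1 weights + k means + k sds
  list(k = k, weights = w[ord], means = mu[ord], sds = sg[ord],
       loglik = ll, criterion = -2 * ll + p * log(n), n = n)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, n = %d, loglik = %.4f, BIC = %.4f\n",
              x$k, x$n, x$loglik, x$criterion))
  for (j in seq_len(x$k)) {
    cat(sprintf("  comp %d: weight %.3f, mean %.4f, sd %.4f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Derive the adaptive correlation cutoff from a mixture fit
#'
#' For one fitted component the cutoff is the component's 0.75 quantile
#' (the point where its cumulative probability exceeds 0.75) -- a single
#' component means all cluster pairs look like different cell types. For
#' two components (low = different cell types, high = same cell type) the
#' cutoff is the intersection of the weighted component densities between
#' the two means; if the densities do not cross there, the midpoint of the
#' means is used and flagged. For three components the cutoff is the 0.75
#' quantile of the middle component. The raw cutoff is finally clamped to
#' `[clamp_lo, clamp_hi]`.
#'
#' @param fit A [fit_mixture()] result.
#' @param clamp_lo,clamp_hi Permitted cutoff range; defaults 0.4 and 0.6.
#' @return An object of class `cutoff_result`: list with `raw_cutoff`,
#'   `cutoff`, `k_selected`, `clamp_lo`, `clamp_hi`, `fallback_used`,
#'   `intersection_found`.
#' @export
derive_cutoff <- function(fit, clamp_lo = 0.4, clamp_hi = 0.6) {
  stopifnot(inherits(fit, "mixture_fit"), clamp_lo <= clamp_hi)
  intersection_found <- NA
  if (fit$k == 1L) {
    raw <- stats::qnorm(0.75, fit$means[1], fit$sds[1])
  } else if (fit$k == 2L) {
    f <- function(x) {
      log(fit$weights[1]) + stats::dnorm(x, fit$means[1], fit$sds[1], log = TRUE) -
        log(fit$weights[2]) - stats::dnorm(x, fit$means[2], fit$sds[2], log = TRUE)
    }
    lo <- fit$means[1]; hi <- fit$means[2]
    if (hi - lo < .Machine$double.eps || f(lo) * f(hi) > 0) {
      raw <- (lo + hi) / 2
      intersection_found <- FALSE
    } else {
      raw <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
      intersection_found <- TRUE
    }
  } else {
    raw <- stats::qnorm(0.75, fit$means[2], fit$sds[2])
  }
  cutoff_result(raw, clamp_lo, clamp_hi, k_selected = fit$k,
                fallback_used = FALSE,
                intersection_found = intersection_found)
}

cutoff_result <- function(raw, clamp_lo, clamp_hi, k_selected,
                          fallback_used, intersection_found = NA) {
  structure(list(raw_cutoff = raw,
                 cutoff = min(max(raw, clamp_lo), clamp_hi),
                 k_selected = k_selected,
                 clamp_lo = clamp_lo, clamp_hi = clamp_hi,
                 fallback_used = fallback_used,
                 intersection_found = intersection_found),
            class = "cutoff_result")
}

#' Fallback cutoff for degenerate inputs
#'
#' Used when too few correlation coefficients are available for a mixture
#' fit: the cutoff is the midpoint of the permitted range and the result is
#' flagged with `fallback_used = TRUE`.
#'
#' @param clamp_lo,clamp_hi Permitted cutoff range.
#' @return A `cutoff_result`.
#' @export
default_cutoff <- function(clamp_lo = 0.4, clamp_hi = 0.6) {
  stopifnot(clamp_lo <= clamp_hi)
  cutoff_result((clamp_lo + clamp_hi) / 2, clamp_lo, clamp_hi,
                k_selected = NA_integer_, fallback_used = TRUE)
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "<cutoff_result> cutoff = %.4f (raw %.4f, clamp [%.2f, %.2f], k = %s%s)\n",
    x$cutoff, x$raw_cutoff, x$clamp_lo, x$clamp_hi,
    ifelse(is.na(x$k_selected), "-", as.character(x$k_selected)),
    if (isTRUE(x$fallback_used)) ", fallback" else ""))
  invisible(x)
}

# Fit + derive with the fallback path wired in; used by the annotation
# modules and the CLI diagnostics.
estimate_cutoff <- function(values, clamp_lo = 0.4, clamp_hi = 0.6,
                            min_n = 50) {
  fit <- tryCatch(fit_mixture(values, min_n = min_n),
                  clustann_too_few_values = function(e) NULL)
  if (is.null(fit)) {
    return(list(cutoff = default_cutoff(clamp_lo, clamp_hi), fit = NULL))
  }
  list(cutoff = derive_cutoff(fit, clamp_lo, clamp_hi), fit = fit)
}
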