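#' Robust (Huber) simple linear regression
#'
#' M-estimated straight-line fit of \code{y} on \code{x} with the Huber loss,
#' computed by iteratively reweighted least squares with the residual scale
#' re-estimated by the MAD at every iteration. Gross outliers are
#' down-weighted rather than deleted; in clean Gaussian data the fit agrees
#' with ordinary least squares.
#'
#' The reported \code{r_squared} is the squared Pearson correlation between
#' fitted and observed responses. Because fitted values of a straight-line
#' fit are an affine function of \code{x}, this equals \code{cor(x, y)^2}
#' whenever the slope is nonzero, regardless of the estimator used for the
#' coefficients.
#'
#' @param x,y Paired numeric vectors; at least 10 finite pairs, and \code{x}
#'   must have nonzero variance.
#' @param k Huber tuning constant in units of the residual scale
#'   (default 1.345, ~95% Gaussian efficiency).
#' @param max_iter,tol IRLS iteration cap and coefficient convergence
#'   tolerance.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{weights} (final Huber weights), \code{iterations},
#'   \code{converged}.
#' @examples
#' set.seed(1)
#' x <- runif(100); y <- 2 * x + 1 + rnorm(100, sd = 0.1)
#' robust_fit(x, y)$slope
#' @export
robust_fit <- function(x, y, k = 1.345, max_iter = 50L, tol = 1e-8) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 finite (x, y) pairs, got ", n)
  if (stats::sd(x) == 0)
    stop("`x` is constant: the predictor is degenerate")

  # OLS start
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar

  w <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- y - intercept - slope * x
    scale <- stats::mad(r, center = 0)
    if (scale <= .Machine$double.eps) { converged <- TRUE; break }  # exact fit
    u <- abs(r) / scale
    w <- ifelse(u <= k, 1, k / u)
    sw <- sum(w)
    xw <- sum(w * x) / sw; yw <- sum(w * y) / sw
    sxxw <- sum(w * (x - xw)^2)
    new_slope <- sum(w * (x - xw) * (y - yw)) / sxxw
    new_intercept <- yw - new_slope * xw
    if (abs(new_slope - slope) < tol && abs(new_intercept - intercept) < tol) {
      slope <- new_slope; intercept <- new_intercept
      converged <- TRUE
      break
    }
    slope <- new_slope; intercept <- new_intercept
  }
  r2 <- if (slope == 0) 0 else stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r_squared = r2,
       weights = w, iterations = iter, converged = converged)
}

#' DBM parameter search space
#'
#' The exhaustive grid over (alpha, m, s) scanned by [dbm_grid_fit()].
#' Defaults: alpha from 0.25 to 1.00 in steps of 0.01, prior mean m from
#' 0.01 to 0.99 in steps of 0.01, prior scale s in {2, 4, ..., 20}
#' (75,240 triples).
#'
#' @param alpha_values,m_values,s_values Ascending numeric vectors of
#'   candidate values.
#' @return Object of class \code{"dbm_search_space"}.
#' @export
dbm_search_space <- function(alpha_values = seq(0.25, 1.00, by = 0.01),
                             m_values = seq(0.01, 0.99, by = 0.01),
                             s_values = seq(2, 20, by = 2)) {
  stopifnot(!is.unsorted(alpha_values, strictly = TRUE),
            !is.unsorted(m_values, strictly = TRUE),
            !is.unsorted(s_values, strictly = TRUE),
            all(alpha_values >= 0 & alpha_values <= 1),
            all(m_values > 0 & m_values < 1),
            all(s_values > 0))
  structure(list(alpha_values = alpha_values, m_values = m_values,
                 s_values = s_values),
            class = "dbm_search_space")
}

#' Thinned search space for quick fits
#'
#' A coarser version of the default grid (alpha step 0.05, m step 0.05,
#' s in {2, 6, 10, 14, 18}; 1,520 triples) for simulation studies and tests
#' where the full 75,240-triple scan is unnecessary.
#' @return Object of class \code{"dbm_search_space"}.
#' @export
dbm_search_space_coarse <- function() {
  dbm_search_space(alpha_values = seq(0.25, 1.00, by = 0.05),
                   m_values = seq(0.05, 0.95, by = 0.05),
                   s_values = c(2, 6, 10, 14, 18))
}

# Candidate triples in tie-break order: sorted by alpha, then m, then s, so
# that the first index of a maximal fit realizes the smallest-alpha /
# smallest-m / smallest-s rule.
candidate_grid <- function(space) {
  g <- expand.grid(s = space$s_values, m = space$m_values,
                   alpha = space$alpha_values,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("alpha", "m", "s")]
}

# Squared Pearson correlation of each column of X with y; NA for
# zero-variance columns.
col_r2 <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  sxy <- colSums(X * yc)
  sxx <- colSums(X^2) - n * colMeans(X)^2
  r2 <- sxy^2 / (sxx * syy)
  r2[sxx <= 1e-18 * n] <- NA_real_
  r2
}

#' Fit DBM parameters to one condition block by exhaustive grid search
#'
#' For every (alpha, m, s) triple in the search space, computes the trial-wise
#' P(stop) sequence from the block's trial-type history (never from the RTs),
#' regresses the eligible Go RTs on P(stop), and returns the triple with the
#' maximal regression fit R-squared — the squared correlation between fitted
#' and observed RT, i.e. the fit criterion of a robust straight-line
#' regression of RT on P(stop). Eligible trials are go (non-stop) trials with
#' a registered response; RTs on stop trials are censored by the stop process
#' and excluded.
#'
#' Ties in R-squared (within 1e-12) are broken deterministically toward the
#' smallest alpha, then smallest m, then smallest s.
#'
#' @param trials Data frame for a single block with columns \code{is_stop}
#'   (0/1 or logical) and \code{rt} (ms; \code{NA} when no response was
#'   registered), in task order.
#' @param space A [dbm_search_space()]; default is the full grid.
#' @param n_grid Rate-grid resolution passed to the belief filter.
#' @param chunk_size Number of candidate triples evaluated per block of the
#'   scan (memory/speed trade-off only; the result is identical).
#' @return Object of class \code{"dbm_fit"}: list with \code{params}
#'   (best-fit [dbm_params()]), \code{r_squared}, \code{slope},
#'   \code{intercept}, \code{slope_sign} (+1/-1/0), \code{pstop} (one value
#'   per trial of the full block), \code{n_trials_used} (eligible RT count),
#'   \code{n_grid}.
#' @export
dbm_grid_fit <- function(trials, space = dbm_search_space(), n_grid = 200L,
                         chunk_size = 8192L) {
  stopifnot(is.data.frame(trials),
            all(c("is_stop", "rt") %in% names(trials)),
            inherits(space, "dbm_search_space"))
  outcomes <- as.integer(trials$is_stop)
  if (!all(outcomes %in% c(0L, 1L))) stop("`is_stop` must be binary")
  eligible <- !as.logical(trials$is_stop) & is.finite(trials$rt)
  n_used <- sum(eligible)
  if (n_used < 50L)
    stop("insufficient data: need at least 50 eligible Go RTs, got ", n_used)
  y <- trials$rt[eligible]

  cand <- candidate_grid(space)
  n_cand <- nrow(cand)
  best_r2 <- -Inf
  best_idx <- NA_integer_
  for (start in seq(1L, n_cand, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n_cand)
    P <- dbm_pstop_grid_cpp(outcomes, cand$alpha[idx], cand$m[idx],
                            cand$s[idx], as.integer(n_grid))
    r2 <- col_r2(P[eligible, , drop = FALSE], y)
    r2[is.na(r2)] <- -Inf
    # first index within 1e-12 of the chunk max, then compare to running best
    chunk_best <- max(r2)
    if (chunk_best > best_r2 + 1e-12) {
      best_r2 <- chunk_best
      best_idx <- idx[which(r2 >= chunk_best - 1e-12)[1L]]
    }
  }
  if (!is.finite(best_r2))
    stop("all candidate P(stop) sequences are degenerate (constant)")

  params <- dbm_params(cand$alpha[best_idx], cand$m[best_idx],
                       cand$s[best_idx])
  pstop <- dbm_pstop(outcomes, params, n_grid = n_grid)
  fit <- robust_fit(pstop[eligible], y)
  structure(
    list(params = params, r_squared = fit$r_squared, slope = fit$slope,
         intercept = fit$intercept, slope_sign = sign(fit$slope),
         pstop = pstop, n_trials_used = n_used, n_grid = as.integer(n_grid)),
    class = "dbm_fit"
  )
}

#' @export
print.dbm_fit <- function(x, ...) {
  cat(sprintf(
    "DBM grid fit: alpha = %.2f, m = %.2f, s = %g  (R^2 = %.4f, n = %d)\n",
    x$params$alpha, x$params$prior_mean, x$params$prior_scale,
    x$r_squared, x$n_trials_used))
  cat(sprintf("  RT ~ P(stop): slope %.1f ms/unit, intercept %.1f ms\n",
              x$slope, x$intercept))
  invisible(x)
}
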