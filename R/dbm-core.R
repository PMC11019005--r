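#' DBM parameter set
#'
#' Bundles the three parameters of the Dynamic Belief Model (DBM): the
#' belief-persistence probability \code{alpha}, and the mean and scale of the
#' fixed beta prior over the latent stop-signal rate. The model assumes that
#' on each trial the stop rate \eqn{r_k} stays equal to \eqn{r_{k-1}} with
#' probability \eqn{\alpha} and is re-drawn from \eqn{Beta(a, b)} with
#' probability \eqn{1 - \alpha}, where the prior is parameterized by its mean
#' \eqn{m = a/(a+b)} and scale \eqn{s = a + b}.
#'
#' @param alpha Probability in \[0, 1\] that the stop rate carries over from
#'   the previous trial (1 = fixed world, 0 = memoryless).
#' @param prior_mean Mean \eqn{m} of the beta prior, strictly inside (0, 1).
#' @param prior_scale Scale \eqn{s = a + b} of the beta prior; positive.
#'   Larger values make the prior more concentrated around \code{prior_mean}.
#'
#' @return An object of class \code{"dbm_params"}: a list with elements
#'   \code{alpha}, \code{prior_mean}, \code{prior_scale}, and the implied
#'   beta shapes \code{a}, \code{b}.
#' @examples
#' dbm_params(0.95, 0.30, 14)
#' @export
dbm_params <- function(alpha, prior_mean, prior_scale) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(prior_mean), length(prior_mean) == 1L,
            is.numeric(prior_scale), length(prior_scale) == 1L)
  if (alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1], got ", alpha)
  if (prior_mean <= 0 || prior_mean >= 1)
    stop("`prior_mean` must lie strictly inside (0, 1), got ", prior_mean)
  if (prior_scale <= 0)
    stop("`prior_scale` must be positive, got ", prior_scale)
  a <- prior_mean * prior_scale
  b <- (1 - prior_mean) * prior_scale
  structure(
    list(alpha = alpha, prior_mean = prior_mean, prior_scale = prior_scale,
         a = a, b = b),
    class = "dbm_params"
  )
}

#' @export
print.dbm_params <- function(x, ...) {
  cat(sprintf(
    "DBM parameters: alpha = %.3f, prior mean m = %.3f, prior scale s = %.2f\n",
    x$alpha, x$prior_mean, x$prior_scale))
  cat(sprintf("  implied beta prior: Beta(a = %.3f, b = %.3f)\n", x$a, x$b))
  invisible(x)
}

# Midpoints of n equal bins on (0, 1); keeps the beta density evaluation away
# from the endpoint singularities that occur when a < 1 or b < 1.
rate_grid <- function(n_grid) (seq_len(n_grid) - 0.5) / n_grid

new_belief <- function(grid, mass, trial_index) {
  structure(list(grid = grid, mass = mass, trial_index = trial_index),
            class = "dbm_belief")
}

#' Initial belief over the stop-signal rate
#'
#' Discretizes the beta prior \eqn{Beta(m s, (1-m) s)} on a grid of bin
#' midpoints over (0, 1) and normalizes it to a probability mass function.
#'
#' @param params A [dbm_params()] object.
#' @param n_grid Number of grid points (default 200; at least 50).
#' @return An object of class \code{"dbm_belief"}: list with \code{grid}
#'   (rate values), \code{mass} (probability weights summing to 1) and
#'   \code{trial_index} (number of outcomes absorbed so far, here 0).
#' @examples
#' b <- dbm_prior(dbm_params(1, 0.25, 4))
#' dbm_predict(b)  # ~0.25
#' @export
dbm_prior <- function(params, n_grid = 200L) {
  stopifnot(inherits(params, "dbm_params"))
  n_grid <- as.integer(n_grid)
  if (n_grid < 50L) stop("`n_grid` must be at least 50, got ", n_grid)
  grid <- rate_grid(n_grid)
  mass <- stats::dbeta(grid, params$a, params$b)
  new_belief(grid, mass / sum(mass), 0L)
}

#' One step of leaky belief propagation
#'
#' Mixes the current posterior with the fixed prior: with probability
#' \code{alpha} the rate is unchanged, with probability \code{1 - alpha} it is
#' re-drawn from the prior. The result is the predictive (prior) belief for
#' the upcoming trial.
#'
#' @param belief A \code{"dbm_belief"} object (normalized).
#' @param params The [dbm_params()] whose prior defines the reset component;
#'   must share the belief's grid size.
#' @return A \code{"dbm_belief"} with mass
#'   \code{alpha * mass + (1 - alpha) * prior_mass}, renormalized.
#' @export
dbm_propagate <- function(belief, params) {
  stopifnot(inherits(belief, "dbm_belief"), inherits(params, "dbm_params"))
  prior <- stats::dbeta(belief$grid, params$a, params$b)
  prior <- prior / sum(prior)
  mass <- params$alpha * belief$mass + (1 - params$alpha) * prior
  new_belief(belief$grid, mass / sum(mass), belief$trial_index)
}

#' Bayes update of the belief from one trial outcome
#'
#' Multiplies the belief pointwise by the Bernoulli likelihood of the observed
#' trial type — \eqn{r} for a stop trial, \eqn{1 - r} for a go trial — and
#' renormalizes. The posterior mean moves toward 1 after a stop outcome and
#' toward 0 after a go outcome.
#'
#' @param belief A \code{"dbm_belief"} object (normalized).
#' @param outcome 1 (stop trial) or 0 (go trial).
#' @return The posterior \code{"dbm_belief"}; \code{trial_index} incremented.
#' @export
dbm_update <- function(belief, outcome) {
  stopifnot(inherits(belief, "dbm_belief"))
  if (!(length(outcome) == 1L && outcome %in% c(0, 1)))
    stop("`outcome` must be a single 0 (go) or 1 (stop)")
  lik <- if (outcome == 1) belief$grid else 1 - belief$grid
  mass <- belief$mass * lik
  z <- sum(mass)
  if (!is.finite(z) || z <= 0)
    stop("belief mass degenerated to zero during the update")
  new_belief(belief$grid, mass / z, belief$trial_index + 1L)
}

#' Predictive stop probability of the current belief
#'
#' The mean of the belief distribution: the probability, before observing the
#' upcoming trial, that it carries a stop signal.
#'
#' @param belief A \code{"dbm_belief"} object that has already been
#'   propagated for the upcoming trial.
#' @return A single probability strictly inside (0, 1).
#' @export
dbm_predict <- function(belief) {
  stopifnot(inherits(belief, "dbm_belief"))
  sum(belief$grid * belief$mass)
}

#' Trial-wise P(stop) sequence for an outcome history
#'
#' Runs the DBM over a binary trial-type sequence and returns the predictive
#' stop probability P(stop) for every trial, each computed from the history
#' up to (but excluding) that trial. The first element therefore equals the
#' prior mean \code{m} (up to grid discretization).
#'
#' @param outcomes Integer/logical vector of trial types (1/TRUE = stop,
#'   0/FALSE = go), in task order.
#' @param params A [dbm_params()] object.
#' @param n_grid Number of rate-grid points (default 200).
#' @return Numeric vector of P(stop), one per trial.
#' @examples
#' # alpha = 1 with a flat Beta(1,1) prior reproduces Laplace's rule:
#' dbm_pstop(c(1, 0, 0, 1), dbm_params(1, 0.5, 2))
#' @export
dbm_pstop <- function(outcomes, params, n_grid = 200L) {
  outcomes <- as.integer(outcomes)
  if (length(outcomes) == 0L) stop("`outcomes` must contain at least one trial")
  if (!all(outcomes %in% c(0L, 1L)))
    stop("`outcomes` must be binary (1 = stop trial, 0 = go trial)")
  belief <- dbm_prior(params, n_grid)
  pstop <- numeric(length(outcomes))
  for (k in seq_along(outcomes)) {
    if (k > 1L) belief <- dbm_propagate(belief, params)
    pstop[k] <- dbm_predict(belief)
    belief <- dbm_update(belief, outcomes[k])
  }
  pstop
}
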