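# Trial-level hierarchical regressions: Go RT, standardized P1/N1
# amplitude, and stop error as functions of condition valence, stake and
# the trial-wise stop expectation P(stop), with subject random intercepts;
# per-condition simple slopes and tertile binning for visualization.

#' Effect-code the incentive factors
#'
#' Adds \code{valence_c} (punishment = +0.5, reward = -0.5) and
#' \code{stake_c} (high = +0.5, low = -0.5) so that interaction
#' coefficients live on the same scale as main effects.
#'
#' @param data Data frame with \code{valence} and \code{stake} columns.
#' @return \code{data} with the coded columns appended.
#' @export
code_conditions <- function(data) {
  stopifnot(all(c("valence", "stake") %in% names(data)))
  data$valence_c <- ifelse(data$valence == "punishment", 0.5, -0.5)
  data$stake_c <- ifelse(data$stake == "high", 0.5, -0.5)
  data
}

#' Fit a trial-level mixed-effects model
#'
#' Fits \code{outcome ~ valence_c * stake_c * pstop [* amplitude] +
#' (1 | subject)} by (restricted) maximum likelihood — a linear model for
#' continuous outcomes and a binomial logit model for binary ones. This is
#' the full-factorial fixed-effects structure over the incentive factors,
#' the continuous stop expectation, and (optionally) a trial-level ERP
#' amplitude, with a subject random intercept.
#'
#' @param data Trial-level data frame; must contain \code{subject},
#'   \code{valence}, \code{stake}, the \code{pstop} column and the outcome.
#' @param outcome Name of the outcome column. Binary (logical/0-1) outcomes
#'   get a logit link.
#' @param pstop Name of the P(stop) column (default \code{"pstop"}).
#' @param amplitude Optional name of an amplitude column to cross with the
#'   design (used for the stop-error models).
#' @param center_pstop If TRUE, grand-mean center P(stop) before fitting.
#' @param ... Passed to [lmerTest::lmer()] / [lme4::glmer()].
#' @return Object of class \code{"sst_model"}: list with the fitted
#'   \code{fit}, the \code{formula}, \code{binary} flag and the analysis
#'   data.
#' @export
fit_trial_model <- function(data, outcome, pstop = "pstop",
                            amplitude = NULL, center_pstop = FALSE, ...) {
  stopifnot(all(c("subject", outcome, pstop) %in% names(data)))
  data <- code_conditions(data)
  data <- data[is.finite(data[[pstop]]) & !is.na(data[[outcome]]), ]
  if (!is.null(amplitude)) data <- data[is.finite(data[[amplitude]]), ]
  if (center_pstop)
    data[[pstop]] <- data[[pstop]] - mean(data[[pstop]])
  if (length(unique(data$subject)) < 2L)
    stop("need at least 2 subjects for a random-intercept model")

  y <- data[[outcome]]
  binary <- is.logical(y) || all(y %in% c(0, 1))
  fixed <- paste(c("valence_c", "stake_c", pstop, amplitude), collapse = " * ")
  form <- stats::as.formula(
    paste0("`", outcome, "` ~ ", fixed, " + (1 | subject)"))
  fit <- if (binary) {
    data[[outcome]] <- as.numeric(y)
    lme4::glmer(form, data = data, family = stats::binomial(), ...)
  } else {
    lmerTest::lmer(form, data = data, ...)
  }
  structure(list(fit = fit, formula = form, binary = binary, data = data,
                 pstop = pstop, amplitude = amplitude),
            class = "sst_model")
}

#' @export
print.sst_model <- function(x, ...) {
  cat("Trial-level mixed model", if (x$binary) "(logit link)", "\n")
  print(x$formula)
  print(tidy_effects(x))
  invisible(x)
}

#' Tidy fixed-effect table with Wald intervals
#'
#' @param model An \code{"sst_model"} object.
#' @param conf_level Interval coverage (default 0.95).
#' @return Data frame with \code{term}, \code{estimate}, \code{se},
#'   \code{lo}, \code{hi}, \code{p_value}, and \code{odds_ratio} columns
#'   (the latter only for logit models).
#' @export
tidy_effects <- function(model, conf_level = 0.95) {
  stopifnot(inherits(model, "sst_model"))
  co <- stats::coef(summary(model$fit))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  pcol <- grep("^Pr\\(", colnames(co), value = TRUE)
  out <- data.frame(term = rownames(co), estimate = est, se = se,
                    lo = est - z * se, hi = est + z * se,
                    p_value = if (length(pcol)) co[, pcol[1]] else NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (model$binary) out$odds_ratio <- exp(out$estimate)
  out
}

#' Per-condition simple slopes of P(stop) (or an amplitude interaction)
#'
#' Decomposes the fitted interaction structure into the linear P(stop)
#' slope — or the slope of an \code{amplitude x P(stop)} product term —
#' within each of the four incentive conditions, as the corresponding
#' linear combination of fixed-effect coefficients with a propagated Wald
#' interval.
#'
#' @param model An \code{"sst_model"} object.
#' @param term Character vector of continuous variables whose joint slope
#'   is requested, e.g. \code{"pstop"} or \code{c("n1_z", "pstop")}.
#' @param conf_level Interval coverage.
#' @return Data frame with one row per condition: \code{condition},
#'   \code{estimate}, \code{se}, \code{lo}, \code{hi} (plus
#'   \code{odds_ratio} for logit models).
#' @export
simple_slopes <- function(model, term = NULL, conf_level = 0.95) {
  stopifnot(inherits(model, "sst_model"))
  if (is.null(term)) term <- model$pstop
  beta <- lme4::fixef(model$fit)
  V <- as.matrix(stats::vcov(model$fit))
  conds <- sst_conditions()
  codes <- list(valence_c = ifelse(conds$valence == "punishment", 0.5, -0.5),
                stake_c = ifelse(conds$stake == "high", 0.5, -0.5))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- lapply(seq_len(nrow(conds)), function(i) {
    L <- vapply(names(beta), function(nm) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      extra <- setdiff(parts, term)
      if (!all(term %in% parts) || !all(extra %in% names(codes)))
        return(0)
      prod(vapply(extra, function(e) codes[[e]][i], numeric(1)))
    }, numeric(1))
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    data.frame(condition = conds$condition[i], estimate = est, se = se,
               lo = est - z * se, hi = est + z * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (model$binary) out$odds_ratio <- exp(out$estimate)
  out
}

#' Tertile binning of P(stop) for visualization
#'
#' Cuts the pooled P(stop) distribution at its 1/3 and 2/3 empirical
#' quantiles, assigning labels with the lower-inclusive convention:
#' low \code{p < q1}, medium \code{q1 <= p < q2}, high \code{p >= q2}.
#'
#' @param pstop Numeric vector of probabilities.
#' @return List with \code{cutpoints} (the two quantiles) and \code{labels}
#'   (factor of "low"/"medium"/"high", one per input value).
#' @export
bin_tertiles <- function(pstop) {
  pstop_ok <- pstop[is.finite(pstop)]
  if (length(unique(pstop_ok)) < 3L)
    stop("need at least 3 distinct P(stop) values to form tertiles")
  q <- stats::quantile(pstop_ok, c(1 / 3, 2 / 3), names = FALSE)
  if (q[1] >= q[2])
    stop("degenerate P(stop) distribution: tertile cutpoints coincide")
  labels <- cut(pstop, breaks = c(-Inf, q[1], q[2], Inf),
                labels = c("low", "medium", "high"), right = FALSE)
  list(cutpoints = q, labels = labels)
}
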