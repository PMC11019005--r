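# Race-model behavioral summaries: SSRT by the integration method with
# omission replacement, and per-condition performance tables.

#' Stop-signal reaction time by the integration method
#'
#' Estimates SSRT for one condition block under the independent race model:
#' go-trial omissions are replaced by the maximum observed go RT, the go-RT
#' distribution is sorted ascending, the RT at rank
#' \code{ceiling(p * n_go)} — where \code{p} is the probability of
#' responding on a stop trial — is taken as the point where the stop process
#' finishes, and the mean SSD over stop trials is subtracted.
#'
#' Estimates with \code{p} outside \[0.1, 0.9\] are returned but flagged
#' unreliable (the staircase normally keeps \code{p} near 0.5).
#'
#' @param trials Trial table for one block with columns \code{is_stop},
#'   \code{rt}, \code{ssd}, \code{stop_error}.
#' @param min_stop Minimum number of stop trials required.
#' @return Object of class \code{"ssrt_estimate"}: list with \code{ssrt},
#'   \code{p_respond_stop}, \code{mean_ssd}, \code{nth_rt},
#'   \code{n_stop_trials}, \code{n_go_trials}, \code{reliable}.
#' @export
compute_ssrt <- function(trials, min_stop = 30L) {
  stopifnot(all(c("is_stop", "rt", "ssd", "stop_error") %in% names(trials)))
  stop_i <- as.logical(trials$is_stop)
  n_stop <- sum(stop_i)
  if (n_stop < min_stop)
    stop("need at least ", min_stop, " stop trials, got ", n_stop)
  p <- mean(trials$stop_error[stop_i], na.rm = TRUE)
  mean_ssd <- mean(trials$ssd[stop_i], na.rm = TRUE)

  go_rt <- trials$rt[!stop_i]
  n_go <- length(go_rt)
  max_rt <- max(go_rt, na.rm = TRUE)
  go_rt[!is.finite(go_rt)] <- max_rt  # omission replacement
  reliable <- p >= 0.1 && p <= 0.9
  if (!reliable)
    warning("P(respond | stop) = ", signif(p, 3),
            " outside [0.1, 0.9]: SSRT estimate flagged unreliable")
  nth <- min(max(ceiling(p * n_go), 1L), n_go)
  nth_rt <- sort(go_rt)[nth]
  structure(list(ssrt = nth_rt - mean_ssd, p_respond_stop = p,
                 mean_ssd = mean_ssd, nth_rt = nth_rt,
                 n_stop_trials = n_stop, n_go_trials = n_go,
                 reliable = reliable),
            class = "ssrt_estimate")
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf(
    "SSRT (integration method): %.1f ms  [p(respond|stop) = %.3f, mean SSD = %.1f ms, n_stop = %d%s]\n",
    x$ssrt, x$p_respond_stop, x$mean_ssd, x$n_stop_trials,
    if (x$reliable) "" else ", UNRELIABLE"))
  invisible(x)
}

#' Per-condition behavioral summary
#'
#' Mean non-omission go RT, go accuracy (correct arrow responses over go
#' trials), stop success (withheld responses over stop trials), and SSRT,
#' per subject and condition block.
#'
#' @param trials Trial table (one or more subjects/blocks) as produced by
#'   [simulate_block()] or conforming real data.
#' @param expected_conditions Conditions that should be present per subject;
#'   missing ones are listed in the \code{"missing_cells"} attribute.
#' @return Data frame with one row per subject x condition: \code{subject},
#'   \code{condition}, \code{n_trials}, \code{mean_go_rt},
#'   \code{go_success}, \code{stop_success} (percent), \code{ssrt},
#'   \code{ssrt_reliable}.
#' @export
summarize_conditions <- function(trials,
                                 expected_conditions =
                                   sst_conditions()$condition) {
  stopifnot(all(c("subject", "condition", "is_stop", "rt") %in%
                  names(trials)))
  cells <- unique(trials[, c("subject", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    b <- trials[trials$subject == cells$subject[i] &
                  trials$condition == cells$condition[i], ]
    stop_i <- as.logical(b$is_stop)
    go <- b[!stop_i, ]
    est <- tryCatch(suppressWarnings(compute_ssrt(b)), error = function(e) NULL)
    data.frame(
      subject = cells$subject[i], condition = cells$condition[i],
      n_trials = nrow(b),
      mean_go_rt = mean(go$rt, na.rm = TRUE),
      go_success = 100 * mean(go$go_correct %in% TRUE),
      stop_success = 100 * mean(!b$stop_error[stop_i], na.rm = TRUE),
      ssrt = if (is.null(est)) NA_real_ else est$ssrt,
      ssrt_reliable = if (is.null(est)) NA else est$reliable,
      stringsAsFactors = FALSE
    )
  }))
  missing <- do.call(rbind, lapply(unique(cells$subject), function(s) {
    miss <- setdiff(expected_conditions,
                    cells$condition[cells$subject == s])
    if (length(miss))
      data.frame(subject = s, condition = miss, stringsAsFactors = FALSE)
  }))
  attr(out, "missing_cells") <- missing
  out
}
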