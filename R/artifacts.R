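# Injection of realistic tracking artifacts into clean synthetic sessions.

#' Inject tracking artifacts into a clean session
#'
#' Adds, at the configured per-sample rates: confidence drops below the 0.99
#' QC threshold, isolated single-frame jump outliers, top-view x
#' perturbations that break cross-view consistency, and short gaps (runs of
#' zero-confidence frames). The clean values are retained in the attached
#' injection log so QC recovery can be scored exactly.
#'
#' @param session A clean `obs_session` (confidences identically 1).
#' @param config A [gait_config()] supplying `confidence_drop_rate`,
#'   `jump_rate`, `cross_view_rate`, `gap_rate`, `jump_size`, `max_gap`.
#' @param seed Integer seed.
#' @return The corrupted `obs_session`, with attribute `"artifact_log"`: a
#'   data frame `type`, `view`, `landmark`, `frame`, `clean_x`, `clean_y`.
#' @export
inject_tracking_artifacts <- function(session, config = gait_config(),
                                      seed = 1L) {
  stopifnot(inherits(session, "obs_session"))
  for (f in c("confidence_drop_rate", "jump_rate", "cross_view_rate", "gap_rate")) {
    r <- config[[f]]
    if (!is_scalar_num(r) || r < 0 || r > 1) stop_config(f, "must lie in [0, 1]")
  }
  if (any(session$tracking$confidence != 1))
    warning("session does not look clean (confidences != 1 present)")
  tk <- session$tracking
  n <- nrow(tk)
  log <- list()
  note <- function(type, idx) {
    if (length(idx) == 0) return()
    log[[length(log) + 1L]] <<- data.frame(
      type = type, view = tk$view[idx], landmark = tk$landmark[idx],
      frame = tk$frame[idx], clean_x = tk$x[idx], clean_y = tk$y[idx])
  }
  with_seed(seed, {
    ## confidence drops (position untouched)
    idx <- which(stats::runif(n) < config$confidence_drop_rate)
    note("confidence_drop", idx)
    tk$confidence[idx] <- stats::runif(length(idx), 0.5, 0.989)

    ## isolated single-frame jumps
    idx <- which(stats::runif(n) < config$jump_rate)
    note("jump", idx)
    mag <- stats::runif(length(idx), config$jump_size[1], config$jump_size[2]) *
      sample(c(-1, 1), length(idx), replace = TRUE)
    tk$x[idx] <- tk$x[idx] + mag
    tk$y[idx] <- tk$y[idx] + mag * stats::runif(length(idx), -0.5, 0.5)

    ## cross-view x mismatches (top view only)
    top <- which(tk$view == "top")
    idx <- top[stats::runif(length(top)) < config$cross_view_rate]
    note("cross_view", idx)
    tk$x[idx] <- tk$x[idx] + stats::runif(length(idx), 6, 15) *
      sample(c(-1, 1), length(idx), replace = TRUE)

    ## short gaps: runs of zero confidence
    idx <- which(stats::runif(n) < config$gap_rate)
    gaps <- integer(0)
    for (i in idx) {
      len <- sample.int(config$max_gap, 1L)
      run <- i:min(i + len - 1L, n)
      run <- run[tk$view[run] == tk$view[i] & tk$landmark[run] == tk$landmark[i]]
      gaps <- c(gaps, run)
    }
    note("gap", gaps)
    tk$confidence[gaps] <- 0
  })
  session$tracking <- tk
  attr(session, "artifact_log") <-
    if (length(log)) do.call(rbind, log) else
      data.frame(type = character(), view = character(), landmark = character(),
                 frame = integer(), clean_x = numeric(), clean_y = numeric())
  session
}
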