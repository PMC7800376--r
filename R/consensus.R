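# Sliding-window consensus detection of the first whisker-contact frame.

#' Simulate per-window first-contact probability streams
#'
#' Emulates the output of a per-window contact classifier: for every
#' stride-1 window of 10 consecutive frames, an 11-class probability vector
#' over the relative position (1-10) of the first-contact frame, with class
#' 11 meaning "first contact not present in this window". Windows containing
#' the true frame vote for it, corrupted by label noise that displaces the
#' vote by up to two frames; windows not containing it vote "not present".
#'
#' @param true_contact_frame True first-contact frame.
#' @param n_frames Number of frames in the trial.
#' @param noise Probability that a containing window's vote is displaced.
#' @param seed Integer seed.
#' @param window Window length (frames).
#' @param peak Probability mass placed on the chosen class.
#' @return Data frame `window_start`, `p1` ... `p11`.
#' @export
generate_window_probability_stream <- function(true_contact_frame, n_frames,
                                               noise = 0.25, seed = 1L,
                                               window = 10L, peak = 0.9) {
  if (true_contact_frame < 1 || true_contact_frame > n_frames)
    stop("true_contact_frame outside the stream")
  starts <- seq_len(n_frames - window + 1L)
  nc <- window + 1L
  probs <- matrix((1 - peak) / (nc - 1), length(starts), nc)
  rel <- true_contact_frame - starts + 1L
  cls <- ifelse(rel >= 1L & rel <= window, rel, nc)
  with_seed(seed, {
    for (i in seq_along(starts)) {
      cl <- cls[i]
      if (cl <= window && noise > 0 && stats::runif(1) < noise) {
        shift <- sample(c(-2L, -1L, 1L, 2L), 1L,
                        prob = c(0.15, 0.35, 0.35, 0.15))
        cl <- min(max(cl + shift, 1L), window)
      }
      probs[i, cl] <- peak
    }
  })
  out <- data.frame(window_start = starts, probs)
  names(out) <- c("window_start", paste0("p", seq_len(nc)))
  out
}

#' Consensus first-contact frame from sliding-window predictions
#'
#' Each window casts a hard vote: the argmax class, mapped to frame
#' `window_start + class - 1` when the class is a relative position (1-10);
#' the "not present" class casts no vote. A running total per frame is kept
#' and the frame with the most votes is chosen; ties resolve to the earliest
#' frame (a first-contact detector should not bias late). A soft-vote
#' variant accumulates the full probability vectors instead.
#'
#' @param stream Data frame from [generate_window_probability_stream()] or
#'   [read_window_stream_csv()]: `window_start` plus `p1` ... `p11`.
#' @param soft Use soft votes (summed probabilities) instead of hard votes.
#' @return Object of class `consensus_result`: `frame` (chosen first-contact
#'   frame or `NA` when no votes were cast), `votes` (named vector),
#'   `margin` (top vote minus runner-up).
#' @export
consensus_first_contact <- function(stream, soft = FALSE) {
  pm <- as.matrix(stream[, grep("^p", names(stream)), drop = FALSE])
  nc <- ncol(pm)
  window <- nc - 1L
  votes <- numeric(0)
  if (soft) {
    tal <- new.env()
    for (i in seq_len(nrow(pm))) {
      for (cl in seq_len(window)) {
        f <- as.character(stream$window_start[i] + cl - 1L)
        tal[[f]] <- (tal[[f]] %||% 0) + pm[i, cl]
      }
    }
    votes <- unlist(as.list(tal))
  } else {
    cls <- apply(pm, 1, which.max)
    keep <- cls <= window
    if (any(keep)) {
      frames <- stream$window_start[keep] + cls[keep] - 1L
      tab <- table(frames)
      votes <- stats::setNames(as.numeric(tab), names(tab))
    }
  }
  if (length(votes) == 0L) {
    return(structure(list(frame = NA_integer_, votes = votes, margin = NA_real_,
                          flag = "no votes cast"), class = "consensus_result"))
  }
  fr_num <- as.numeric(names(votes))
  ord <- order(-votes, fr_num)            # max votes, earliest frame first
  top <- votes[ord[1]]
  runner <- if (length(votes) > 1L) votes[ord[2]] else 0
  structure(list(frame = as.integer(fr_num[ord[1]]),
                 votes = votes[order(fr_num)],
                 margin = as.numeric(top - runner),
                 flag = NULL),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  if (is.na(x$frame)) cat("<consensus_result> no votes cast\n")
  else cat(sprintf("<consensus_result> frame %d (margin %g, %d candidate frames)\n",
                   x$frame, x$margin, length(x$votes)))
  invisible(x)
}

#' Contact-detection error statistics
#'
#' Error is `(predicted - true) * frame period`, in ms; negative errors are
#' early predictions.
#'
#' @param predicted,true Paired frame vectors.
#' @param frame_rate Hz.
#' @return List with `mean_ms`, `sd_ms`, `errors_ms`.
#' @export
evaluate_contact_error <- function(predicted, true, frame_rate = 250) {
  if (length(predicted) != length(true))
    stop("predicted and true frame lists differ in length")
  e <- (predicted - true) / frame_rate * 1000
  list(mean_ms = mean(e, na.rm = TRUE), sd_ms = stats::sd(e, na.rm = TRUE),
       errors_ms = e)
}
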