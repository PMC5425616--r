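## Synthetic single-dot stimuli emulating a location-discrimination task:
## two targets left/right of center, a white dot jumping around the true
## target every 93.2 ms, at most 25 frames (2.33 s timeout), four difficulty
## levels given by the target offset in pixels.

#' Generate synthetic single-dot stimuli
#'
#' Per trial a true target is assigned (balanced across trials) and the dot's
#' x-position in each frame is drawn Gaussian around the signed target offset
#' (`+offset` for target 1, `-offset` for target 2).
#'
#' The dot-position noise is not printed for the reference experiment; the
#' default of 35 px is fixed so that, with the canonical bound of 0.8 and a
#' matched internal model, accuracy in the hardest condition (offset 10) is
#' about 0.7.
#'
#' @param offset Target offset in pixels; one of 10, 25, 40, 55.
#' @param n_trials Number of trials (the reference task used 200 per
#'   condition).
#' @param dot_noise_sd Standard deviation of frame positions around the
#'   target (> 0), in pixels.
#' @param n_frames Frames per trial (max 25).
#' @param frame_duration Seconds per frame (default 0.0932).
#' @param seed Optional integer seed.
#' @return An object of class `dot_stimuli`: a list with `frames` (an
#'   `n_trials x n_frames` matrix of x-positions), `true_target`,
#'   `condition`, `target_offset`, `frame_duration`, `dot_noise_sd`.
#' @export
#' @examples
#' s <- generate_dot_stimuli(55, n_trials = 10, seed = 3)
#' dim(s$frames)
generate_dot_stimuli <- function(offset, n_trials = 200, dot_noise_sd = 35,
                                 n_frames = 25, frame_duration = 0.0932,
                                 seed = NULL) {
  if (!offset %in% c(10, 25, 40, 55))
    stop("offset must be one of 10, 25, 40, 55 pixels", call. = FALSE)
  .check_num(dot_noise_sd, "dot_noise_sd", lower = 0, strict_lower = TRUE)
  stopifnot(n_trials >= 1, n_frames >= 1, n_frames <= 25)
  if (!is.null(seed)) set.seed(seed)
  true_target <- rep_len(c(1L, 2L), n_trials)
  center <- ifelse(true_target == 1L, offset, -offset)
  frames <- matrix(stats::rnorm(n_trials * n_frames, mean = center,
                                sd = dot_noise_sd),
                   nrow = n_trials, ncol = n_frames)
  structure(list(frames = frames, true_target = true_target,
                 condition = paste0("offset", offset),
                 target_offset = offset, frame_duration = frame_duration,
                 dot_noise_sd = dot_noise_sd),
            class = "dot_stimuli")
}

#' @export
print.dot_stimuli <- function(x, ...) {
  cat("dot_stimuli:", nrow(x$frames), "trials x", ncol(x$frames),
      "frames, offset", x$target_offset, "px, frame",
      x$frame_duration, "s, noise sd", x$dot_noise_sd, "px\n")
  invisible(x)
}

#' Extract the exact input sequence of one stimulus trial
#'
#' Wires a stimulus trial into the exact-input models: the per-step feature
#' value is the frame's dot position, the time step is the frame duration,
#' and the generative means are the two target positions.
#'
#' @param stim A `dot_stimuli` object.
#' @param trial Trial index.
#' @return An [input_sequence()] with attribute `"gen_means"` set to
#'   `c(offset, -offset)`.
#' @export
exact_input_from_stimulus <- function(stim, trial = 1) {
  stopifnot(inherits(stim, "dot_stimuli"))
  if (trial < 1 || trial > nrow(stim$frames))
    stop("trial index out of range", call. = FALSE)
  if (ncol(stim$frames) < 1) stop("empty stimulus", call. = FALSE)
  out <- input_sequence(stim$frames[trial, ], stim$frame_duration,
                        stim$true_target[trial])
  attr(out, "gen_means") <- c(stim$target_offset, -stim$target_offset)
  out
}

#' Write stimuli to a delimited text file
#'
#' One row per trial: `trial_id`, `condition`, `true_target`, then the frame
#' positions `f1..fK`.
#'
#' @param stim A `dot_stimuli` object.
#' @param path Output file path.
#' @export
write_stimuli <- function(stim, path) {
  stopifnot(inherits(stim, "dot_stimuli"))
  k <- ncol(stim$frames)
  df <- data.frame(trial_id = seq_len(nrow(stim$frames)),
                   condition = stim$condition,
                   true_target = stim$true_target)
  fr <- as.data.frame(stim$frames)
  names(fr) <- paste0("f", seq_len(k))
  utils::write.csv(cbind(df, fr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read stimuli written by [write_stimuli()]
#'
#' Validates the frame count and recovers the target offset from the
#' condition label.
#'
#' @param path File path.
#' @param frame_duration Seconds per frame.
#' @return A `dot_stimuli` object.
#' @export
read_stimuli <- function(path, frame_duration = 0.0932) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df))
  if (length(fcols) < 1 || length(fcols) > 25)
    stop("expected 1..25 frame columns f1..fK", call. = FALSE)
  offset <- as.numeric(sub("^offset", "", df$condition[1]))
  if (!offset %in% c(10, 25, 40, 55))
    stop("condition label does not encode a valid offset", call. = FALSE)
  structure(list(frames = as.matrix(df[, fcols]),
                 true_target = as.integer(df$true_target),
                 condition = df$condition[1],
                 target_offset = offset,
                 frame_duration = frame_duration,
                 dot_noise_sd = NA_real_),
            class = "dot_stimuli")
}
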