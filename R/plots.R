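## Base-graphics helpers for the three standard figure types: quantile
## probability plot, sweep heatmap, correct-vs-error QQ plot.

#' Quantile-probability plot
#'
#' Plots the five RT quantiles of correct and error responses against their
#' response probabilities across conditions, connecting equal quantiles
#' with lines (the classic fan shape: the highest quantile spreads most as
#' difficulty increases).
#'
#' @param qp Data frame from [quantile_probability_data()].
#' @param ... Passed to [plot()].
#' @export
plot_qp <- function(qp, ...) {
  plot(range(qp$response_prob), range(qp$rt), type = "n",
       xlab = "response probability", ylab = "RT (s)", ...)
  for (q in unique(qp$quantile)) {
    sub <- qp[qp$quantile == q, ]
    sub <- sub[order(sub$response_prob), ]
    graphics::lines(sub$response_prob, sub$rt, col = "grey60")
  }
  cor_ <- qp$type == "correct"
  graphics::points(qp$response_prob[cor_], qp$rt[cor_], col = "blue",
                   pch = 1)
  graphics::points(qp$response_prob[!cor_], qp$rt[!cor_], col = "red",
                   pch = 1)
  invisible(qp)
}

#' Heatmap of a sweep result
#'
#' @param sweep A `sweep_result` data frame.
#' @param value Column to map to color (e.g. `"proportion_correct"`,
#'   `"median_rt"`, `"rt_diff"`).
#' @param x,y Grid columns (default the sweep's two varied parameters).
#' @param ... Passed to [graphics::image()].
#' @export
plot_sweep_heatmap <- function(sweep, value = "proportion_correct",
                               x = NULL, y = NULL, ...) {
  stopifnot(inherits(sweep, "sweep_result"))
  varied <- c("mean_noise", "noise_var", "prior_spread")
  varied <- varied[vapply(varied, function(v)
    length(unique(sweep[[v]])) > 1, logical(1))]
  if (is.null(x)) x <- varied[1]
  if (is.null(y)) y <- varied[2]
  xs <- sort(unique(sweep[[x]]))
  ys <- sort(unique(sweep[[y]]))
  z <- matrix(NA_real_, length(xs), length(ys))
  for (i in seq_len(nrow(sweep)))
    z[match(sweep[[x]][i], xs), match(sweep[[y]][i], ys)] <-
      sweep[[value]][i]
  graphics::image(log10(xs), log10(ys), z, xlab = paste0("log10 ", x),
                  ylab = paste0("log10 ", y), main = value, ...)
  invisible(z)
}

#' Correct-vs-error RT QQ plot
#'
#' @param qq Data frame from [qq_percentiles()], or a list of them.
#' @param ... Passed to [plot()].
#' @export
plot_qq <- function(qq, ...) {
  if (is.data.frame(qq)) qq <- list(qq)
  rng <- range(unlist(lapply(qq, function(d) c(d$rt_correct, d$rt_error))))
  plot(rng, rng, type = "n", xlab = "correct RT percentile (s)",
       ylab = "error RT percentile (s)", ...)
  graphics::abline(0, 1, lty = 2)
  cols <- grDevices::hcl.colors(length(qq), "Dark 3")
  for (i in seq_along(qq))
    graphics::points(qq[[i]]$rt_correct, qq[[i]]$rt_error, col = cols[i],
                     pch = 16, cex = 0.5)
  invisible(qq)
}
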