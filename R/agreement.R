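# Bland-Altman agreement between ALCV-predicted and ultrasound gestational
# age: bias, SD of differences, 95% limits of agreement, correlation, and
# the within +/- 1 / +/- 2 week coverage used to summarize clinical accuracy.

#' Bland-Altman agreement statistics
#'
#' Differences are `predicted - reference`; the 95% limits of agreement are
#' `bias +/- 1.96 * sd(differences)`.
#'
#' @param predicted,reference numeric vectors of equal length `>= 2`, weeks.
#' @return An `agreement_stats`: `n`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `pearson_r`, `pct_within_1wk`, `pct_within_2wk`,
#'   `n_outside_loa`.
#' @export
bland_altman <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("bland_altman: predicted and reference lengths differ")
  }
  n <- length(predicted)
  if (n < 2 || anyNA(predicted) || anyNA(reference) ||
    any(!is.finite(c(predicted, reference)))) {
    stop("bland_altman: need >= 2 finite paired values")
  }
  d <- predicted - reference
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  r <- if (stats::sd(predicted) == 0 || stats::sd(reference) == 0) {
    NA_real_
  } else {
    stats::cor(predicted, reference)
  }
  structure(
    list(
      n = n, bias = bias, sd_diff = sd_diff,
      loa_low = loa_low, loa_high = loa_high,
      pearson_r = r,
      pct_within_1wk = 100 * mean(abs(d) <= 1),
      pct_within_2wk = 100 * mean(abs(d) <= 2),
      n_outside_loa = sum(d < loa_low | d > loa_high)
    ),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<agreement_stats n=%d>\n  bias %.2f weeks (95%% LOA: %.2f, %.2f)\n",
      "  r = %.3f | within 1 wk: %.0f%% | within 2 wk: %.0f%% | outside LOA: %d\n"
    ),
    x$n, x$bias, x$loa_low, x$loa_high, x$pearson_r,
    x$pct_within_1wk, x$pct_within_2wk, x$n_outside_loa
  ))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param stats an `agreement_stats`.
#' @param predicted,reference the paired values the stats came from.
#' @param path optional PNG output path; plots to the active device if `NULL`.
#' @return `stats`, invisibly.
#' @export
plot_bland_altman <- function(stats, predicted, reference, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 560)
    on.exit(grDevices::dev.off())
  }
  m <- (predicted + reference) / 2
  d <- predicted - reference
  graphics::plot(m, d,
    pch = 19, col = "grey30",
    xlab = "Mean of methods (weeks)",
    ylab = "Predicted - reference (weeks)",
    main = "Bland-Altman agreement"
  )
  graphics::abline(h = stats$bias, lty = 1)
  graphics::abline(h = c(stats$loa_low, stats$loa_high), lty = 2)
  invisible(stats)
}

#' Identity plot of predicted vs reference gestational age
#'
#' @param predicted,reference paired values, weeks.
#' @param path optional PNG output path.
#' @return `NULL`, invisibly.
#' @export
plot_identity <- function(predicted, reference, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  rng <- range(c(predicted, reference))
  graphics::plot(reference, predicted,
    pch = 19, col = "grey30", xlim = rng, ylim = rng,
    xlab = "Ultrasound GA (weeks)", ylab = "ALCV-predicted GA (weeks)",
    main = "Identity plot"
  )
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}
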