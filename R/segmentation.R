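# Vessel enhancement and segmentation inside the pupil: percentile contrast
# stretching of the red and green channels (the blue channel carries little
# vessel signal under retroillumination and is ignored), inversion to a
# vesselness map, then hysteresis thresholding.

#' Contrast-stretch vesselness map
#'
#' Linearly stretches the red and green channels between their `p_low`/`p_high`
#' percentiles computed inside the pupil mask only (global percentiles would be
#' corrupted by the dark surround), averages them, and inverts so that dark
#' vessels on the bright reflex score high. Values outside the pupil are 0.
#'
#' @param image an [rgb_image].
#' @param pupil a `pupil_region` from [refine_pupil_mask()].
#' @param p_low,p_high stretch percentiles, `0 <= p_low < p_high <= 100`.
#' @param invert if `FALSE`, bright-on-dark structures are enhanced instead.
#' @param boundary_erosion_px shrink the pupil mask by this many pixels first,
#'   keeping the blurred dark rim at the pupil boundary out of the vesselness
#'   map (it would otherwise segment as a ring of false vessels).
#' @return A `vesselness_map`: list with `values` (matrix in `[0, 1]`),
#'   `pupil`, and `flat` flag (constant pupil interior, all-zero output).
#' @export
enhance_contrast <- function(image, pupil, p_low = 2, p_high = 98,
                             invert = TRUE, boundary_erosion_px = 3) {
  stopifnot(p_low >= 0, p_high <= 100, p_low < p_high)
  mask <- pupil$mask
  if (boundary_erosion_px > 0) {
    shrunk <- binary_erode(mask, boundary_erosion_px)
    if (any(shrunk)) mask <- shrunk
  }
  if (!any(mask)) {
    stop("enhance_contrast: empty pupil mask")
  }
  stretch <- function(ch) {
    q <- stats::quantile(ch[mask], c(p_low, p_high) / 100, names = FALSE)
    if (q[2] <= q[1]) {
      return(NULL)
    }
    clamp((ch - q[1]) / (q[2] - q[1]), 0, 1)
  }
  r <- stretch(image[, , 1])
  g <- stretch(image[, , 2])
  flat <- is.null(r) && is.null(g)
  if (flat) {
    v <- matrix(0, nrow(mask), ncol(mask))
  } else {
    parts <- Filter(Negate(is.null), list(r, g))
    v <- Reduce(`+`, parts) / length(parts)
    v <- if (invert) 1 - v else v
  }
  v[!mask] <- 0
  structure(list(values = v, pupil = pupil, flat = flat),
    class = "vesselness_map"
  )
}

#' Hysteresis segmentation of the vasculature
#'
#' Seeds are pixels with vesselness `>= high`; all pixels `>= low` that are
#' 8-connected to a seed are kept. Connected components smaller than
#' `min_object_px` are removed and the result is intersected with the pupil
#' mask.
#'
#' @param vness a `vesselness_map`.
#' @param low,high thresholds with `0 <= low < high <= 1`.
#' @param min_object_px minimum component size, pixels.
#' @return A `vessel_map`: list with `mask` (logical), `pupil`, `params_used`.
#' @export
hysteresis_segment <- function(vness, low = 0.25, high = 0.55,
                               min_object_px = 20) {
  if (!(low >= 0 && high <= 1 && low < high)) {
    stop("hysteresis_segment: need 0 <= low < high <= 1")
  }
  v <- vness$values
  cand <- v >= low
  seeds <- v >= high
  if (any(seeds)) {
    lab <- label_components(cand, connectivity = 8)
    keep <- unique(lab[seeds])
    mask <- lab > 0 & lab %in% keep
  } else {
    mask <- cand & FALSE
  }
  mask <- remove_small_components(mask, min_object_px)
  mask <- mask & vness$pupil$mask
  structure(
    list(
      mask = mask, pupil = vness$pupil,
      params_used = list(
        low = low, high = high,
        min_object_px = min_object_px
      )
    ),
    class = "vessel_map"
  )
}

#' Re-segment with manual parameter overrides
#'
#' The manual-tuning hook of the semiautomated workflow: re-runs
#' [hysteresis_segment()] with any of `low`, `high`, `min_object_px`
#' overridden; everything else keeps its default. `params_used` in the result
#' makes every mask reproducible from (image, pupil, params).
#'
#' @param vness a `vesselness_map`.
#' @param overrides named list, subset of `low`, `high`, `min_object_px`.
#' @return A `vessel_map`.
#' @export
tune_segmentation <- function(vness, overrides = list()) {
  allowed <- c("low", "high", "min_object_px")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad) > 0) {
    stop(
      "tune_segmentation: unknown parameter(s): ",
      paste(bad, collapse = ", ")
    )
  }
  params <- utils::modifyList(
    list(low = 0.25, high = 0.55, min_object_px = 20),
    overrides
  )
  hysteresis_segment(vness,
    low = params$low, high = params$high,
    min_object_px = params$min_object_px
  )
}

#' @export
print.vessel_map <- function(x, ...) {
  p <- x$params_used
  cat(sprintf(
    "<vessel_map %d vessel px | low=%.2f high=%.2f min_object=%d>\n",
    sum(x$mask), p$low, p$high, p$min_object_px
  ))
  invisible(x)
}
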