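# Automatic pupil extraction: circular Hough candidate generation, weighted
# candidate voting (contrast, circularity, color), and RGB/HSV boundary
# refinement. Mildly elliptical pupils are handled by the refinement step
# rather than an explicit ellipse transform.

#' Circular Hough transform pupil candidates
#'
#' Detects circular objects by correlating a Sobel edge map with ring
#' templates over a radius range. The accumulator response for a candidate is
#' the fraction of its ring lying on strong edges; candidates below
#' `accumulator_floor` are dropped. Non-maximum suppression keeps distinct
#' circles.
#'
#' @param image an [rgb_image]; at least 64 x 64.
#' @param radius_range c(min, max) radii in pixels. Default 10--45% of the
#'   short image side (the pupil occupies only a fraction of the frame).
#' @param max_candidates maximum number of candidates returned.
#' @param radius_step spacing of the radius grid, pixels.
#' @param accumulator_floor minimum fraction (0--1) of ring support required.
#' @return A data.frame of candidates ordered by accumulator response:
#'   `row`, `col`, `radius`, `response`. Empty (zero rows) when nothing
#'   exceeds the floor.
#' @export
hough_circle_candidates <- function(image,
                                    radius_range = NULL,
                                    max_candidates = 5,
                                    radius_step = 2,
                                    accumulator_floor = 0.3) {
  d <- dim(image)
  if (d[1] < 64 || d[2] < 64) {
    stop("hough_circle_candidates: image must be at least 64 x 64")
  }
  if (is.null(radius_range)) {
    radius_range <- c(0.10, 0.45) * min(d[1:2])
  }
  rmin <- radius_range[1]
  rmax <- radius_range[2]
  if (!(rmin > 0 && rmin < rmax && rmax < min(d[1:2]) / 2)) {
    stop("hough_circle_candidates: need 0 < min radius < max radius < min(rows, cols)/2")
  }
  gray <- to_gray(image)
  mag <- sobel(gray)$mag
  # robust edge threshold: a single specular highlight must not drown the
  # pupil rim, so key off a high percentile rather than the maximum
  thr <- stats::quantile(mag, 0.99, names = FALSE) * 0.25
  empty <- data.frame(
    row = numeric(0), col = numeric(0),
    radius = numeric(0), response = numeric(0)
  )
  if (max(mag) == 0) {
    return(empty)
  }
  edges <- (mag >= thr) * 1

  radii <- seq(rmin, rmax, by = radius_step)
  nr <- d[1]
  nc <- d[2]
  best_resp <- matrix(-Inf, nr, nc)
  best_rad <- matrix(0, nr, nc)
  for (r in radii) {
    offs <- disk_offsets(r + 1)
    dist <- sqrt(offs[, 1]^2 + offs[, 2]^2)
    ring <- abs(dist - r) <= 1.2
    ro <- offs[ring, , drop = FALSE]
    acc <- xcorr_offsets(edges, ro, rep(1 / nrow(ro), nrow(ro)))
    upd <- acc > best_resp
    best_resp[upd] <- acc[upd]
    best_rad[upd] <- r
  }
  # candidate disks must lie within the image
  rows <- outer(seq_len(nr), rep(1, nc))
  cols <- outer(rep(1, nr), seq_len(nc))
  inside <- rows - best_rad >= 1 & rows + best_rad <= nr &
    cols - best_rad >= 1 & cols + best_rad <= nc
  best_resp[!inside] <- -Inf

  cands <- empty
  resp <- best_resp
  while (nrow(cands) < max_candidates) {
    i <- which.max(resp)
    if (length(i) == 0 || resp[i] < accumulator_floor) break
    pr <- ((i - 1) %% nr) + 1
    pc <- ((i - 1) %/% nr) + 1
    r <- best_rad[i]
    cands <- rbind(cands, data.frame(
      row = pr, col = pc, radius = r, response = resp[i]
    ))
    # suppress a neighborhood of half the detected radius
    sup <- disk_mask(c(nr, nc), c(pr, pc), max(3, r / 2))
    resp[sup] <- -Inf
  }
  cands
}

# Hue-free HSV pieces used by refinement: value = max/255, saturation =
# (max - min)/max (0 where max = 0).
hsv_sat_val <- function(image) {
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  list(sat = s, val = mx / 255)
}

minmax_norm <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) {
    return(rep(1, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

#' Score pupil candidates by weighted voting
#'
#' Each candidate gets three per-frame min-max normalized scores in `[0, 1]`:
#' contrast (absolute gray-level difference between the disk interior and a
#' surrounding annulus), circularity (fraction of boundary samples on strong
#' gradient ridges), and color (mean redness `(R - max(G, B))/255` of the
#' interior, targeting the red reflex). The total is their weighted sum.
#'
#' @param image an [rgb_image].
#' @param candidates data.frame from [hough_circle_candidates()]; non-empty.
#' @param weights length-3 numeric (contrast, circularity, color) summing
#'   to 1.
#' @return The candidates with `contrast_score`, `circularity_score`,
#'   `color_score`, `total_score` columns, sorted by decreasing total score
#'   with deterministic ties (row, col, radius).
#' @export
score_candidates <- function(image, candidates, weights = rep(1 / 3, 3)) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("score_candidates: candidate list is empty")
  }
  stopifnot(length(weights) == 3, abs(sum(weights) - 1) < 1e-8)
  gray <- to_gray(image)
  mag <- sobel(gray)$mag
  ridge_thr <- if (any(mag > 0)) {
    stats::quantile(mag[mag > 0], 0.9, names = FALSE)
  } else {
    Inf
  }
  redness <- (image[, , 1] - pmax(image[, , 2], image[, , 3])) / 255
  d <- dim(gray)

  raw <- t(vapply(seq_len(nrow(candidates)), function(i) {
    ctr <- c(candidates$row[i], candidates$col[i])
    r <- candidates$radius[i]
    disk <- disk_mask(d, ctr, r)
    annul <- disk_mask(d, ctr, 1.5 * r) & !disk_mask(d, ctr, 1.1 * r)
    contrast <- if (any(annul)) {
      abs(mean(gray[disk]) - mean(gray[annul])) / 255
    } else {
      0 # disk touches the border everywhere; annulus clipped away
    }
    ang <- seq(0, 2 * pi, length.out = 73)[-73]
    br <- clamp(round(ctr[1] + r * sin(ang)), 1, d[1])
    bc <- clamp(round(ctr[2] + r * cos(ang)), 1, d[2])
    circ <- mean(mag[cbind(br, bc)] >= ridge_thr)
    color <- clamp(mean(redness[disk]), 0, 1)
    c(contrast, circ, color)
  }, numeric(3)))

  candidates$contrast_score <- minmax_norm(raw[, 1])
  candidates$circularity_score <- minmax_norm(raw[, 2])
  candidates$color_score <- minmax_norm(raw[, 3])
  candidates$total_score <- as.vector(
    cbind(
      candidates$contrast_score, candidates$circularity_score,
      candidates$color_score
    ) %*% weights
  )
  ord <- order(-candidates$total_score, candidates$row, candidates$col,
    candidates$radius)
  candidates[ord, , drop = FALSE]
}

#' Refine the pupil boundary using RGB and HSV information
#'
#' Thresholds redness (RGB) and saturation/value (HSV) inside the candidate
#' disk dilated by a margin, keeps the largest 8-connected component, then
#' applies morphological closing and hole filling. If the refined component
#' covers less than half the candidate disk the raw disk is used instead and
#' the result is flagged.
#'
#' @param image an [rgb_image].
#' @param best one scored candidate (a single-row data.frame or list with
#'   `row`, `col`, `radius`).
#' @param margin_frac dilation margin as a fraction of the radius.
#' @param redness_min absolute floor on `R - max(G, B)` (intensity units).
#'   The working threshold is the larger of this floor and half the median
#'   redness of the disk interior, so a dimly reddish iris surround does not
#'   pass.
#' @param sat_min,val_min HSV saturation/value floors.
#' @return A `pupil_region`: list with `candidate`, `mask` (logical), `area`,
#'   `fallback` flag.
#' @export
refine_pupil_mask <- function(image, best, margin_frac = 0.15,
                              redness_min = 10, sat_min = 0.15,
                              val_min = 0.2) {
  ctr <- c(best$row[1], best$col[1])
  r <- best$radius[1]
  d <- dim(image)[1:2]
  roi <- disk_mask(d, ctr, r * (1 + margin_frac))
  redness <- image[, , 1] - pmax(image[, , 2], image[, , 3])
  red_thr <- max(redness_min, 0.5 * stats::median(redness[disk_mask(d, ctr, r)]))
  sv <- hsv_sat_val(image)
  sel <- roi & redness >= red_thr & sv$sat >= sat_min & sv$val >= val_min
  disk_area <- sum(disk_mask(d, ctr, r))
  fallback <- FALSE
  if (any(sel)) {
    comp <- largest_component(sel)
    comp <- fill_holes(binary_close(comp, 3)) & roi
    if (sum(comp) >= 0.5 * disk_area) {
      mask <- comp
    } else {
      fallback <- TRUE
      mask <- disk_mask(d, ctr, r)
    }
  } else {
    fallback <- TRUE
    mask <- disk_mask(d, ctr, r)
  }
  structure(
    list(
      candidate = best, mask = mask, area = sum(mask),
      fallback = fallback
    ),
    class = "pupil_region"
  )
}

#' @export
print.pupil_region <- function(x, ...) {
  cat(sprintf(
    "<pupil_region center=(%.1f, %.1f) radius=%.1f area=%d px%s>\n",
    x$candidate$row[1], x$candidate$col[1], x$candidate$radius[1],
    x$area, if (x$fallback) " [fallback disk]" else ""
  ))
  invisible(x)
}

#' One-call pupil detection
#'
#' Runs candidate generation, scoring and refinement; returns `NULL` when no
#' candidate exceeds the accumulator floor.
#'
#' @param image an [rgb_image].
#' @param ... passed to [hough_circle_candidates()].
#' @param weights passed to [score_candidates()].
#' @return A `pupil_region` or `NULL`.
#' @export
detect_pupil <- function(image, ..., weights = rep(1 / 3, 3)) {
  cands <- hough_circle_candidates(image, ...)
  if (nrow(cands) == 0) {
    return(NULL)
  }
  scored <- score_candidates(image, cands, weights = weights)
  refine_pupil_mask(image, scored[1, , drop = FALSE])
}
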