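# Synthetic retroillumination scenes with analytic ground truth.
#
# The generator emulates the appearance this pipeline is built for: a bright
# reddish pupil reflex on a darker iris background, with the persistent fetal
# lens vasculature showing as dark branches inside the reflex, degraded by
# defocus blur, sensor noise and bright specular/mucus-like artifacts.

#' Branch specification for synthetic vessel trees
#'
#' @param path numeric matrix `n x 2` of sub-pixel (row, col) points, `n >= 2`,
#'   consecutive points distinct.
#' @param width stroke width in pixels (> 0); a scalar or one value per point.
#' @param nominal_tortuosity_amplitude amplitude (pixels) recorded for
#'   bookkeeping when the branch was built as a sinusoid; 0 for straight.
#' @return A `branch_spec` with the analytic polyline `length` precomputed.
#' @export
branch_spec <- function(path, width = 3, nominal_tortuosity_amplitude = 0) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2)
  steps <- sqrt(rowSums((path[-1, , drop = FALSE] -
    path[-nrow(path), , drop = FALSE])^2))
  if (any(steps == 0)) {
    stop("branch_spec: consecutive path points must be distinct")
  }
  if (any(width <= 0) || !(length(width) %in% c(1L, nrow(path)))) {
    stop("branch_spec: width must be > 0, scalar or one value per point")
  }
  structure(
    list(
      path = path, width = width,
      nominal_tortuosity_amplitude = nominal_tortuosity_amplitude,
      length = sum(steps)
    ),
    class = "branch_spec"
  )
}

#' Sinusoidal branch between two points
#'
#' Builds a branch whose centerline is a sinusoid about the start--end chord,
#' sampled at most 0.5 px apart. Amplitude 0 degenerates to the straight
#' segment. This gives direct control over tortuosity for testing the fractal
#' dimension measure.
#'
#' @param start,end (row, col) endpoints; must differ.
#' @param amplitude peak deviation from the chord, pixels, `>= 0`.
#' @param cycles number of full sine periods along the chord, `>= 1`.
#' @param width stroke width in pixels.
#' @return A [branch_spec()].
#' @export
make_branch_sinusoid <- function(start, end, amplitude, cycles = 1, width = 3) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (all(start == end)) {
    stop("make_branch_sinusoid: start and end coincide")
  }
  stopifnot(amplitude >= 0, cycles >= 1)
  chord <- sqrt(sum((end - start)^2))
  u <- (end - start) / chord
  nvec <- c(-u[2], u[1])
  # upper bound on arc length gives a sample count with spacing <= 0.5 px
  arc_bound <- chord + 2 * pi * cycles * amplitude
  n <- max(2L, ceiling(arc_bound / 0.25) + 1L)
  t <- seq(0, 1, length.out = n)
  offset <- amplitude * sin(2 * pi * cycles * t)
  path <- cbind(
    start[1] + t * chord * u[1] + offset * nvec[1],
    start[2] + t * chord * u[2] + offset * nvec[2]
  )
  branch_spec(path, width = width, nominal_tortuosity_amplitude = amplitude)
}

#' Synthetic scene specification
#'
#' Declares a retroillumination scene: pupil geometry, vessel tree, and
#' degradations. The seed fully determines the rendered image.
#'
#' @param image_size c(rows, cols).
#' @param pupil_center (row, col) of the pupil disk.
#' @param pupil_radius pupil radius, pixels.
#' @param pupil_reflex_color,background_color,vessel_color RGB triples in
#'   `[0, 255]`. Vessels are dark on the bright reflex, as under
#'   retroillumination.
#' @param vessel_tree list of [branch_spec()] drawn inside the pupil.
#' @param blur_sigma Gaussian defocus blur sigma, pixels, `>= 0`.
#' @param noise_sigma additive Gaussian sensor noise SD, intensity units.
#' @param artifact_count number of bright specular/mucus-like artifacts.
#' @param seed integer; fully determines the rendering.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = c(160, 160),
                       pupil_center = round(image_size / 2),
                       pupil_radius = round(0.28 * min(image_size)),
                       pupil_reflex_color = c(200, 70, 60),
                       background_color = c(70, 45, 45),
                       vessel_color = c(60, 18, 18),
                       vessel_tree = list(),
                       blur_sigma = 0,
                       noise_sigma = 0,
                       artifact_count = 0,
                       seed = 1L) {
  stopifnot(
    length(image_size) == 2, all(image_size >= 16),
    pupil_radius > 0, blur_sigma >= 0, noise_sigma >= 0, artifact_count >= 0
  )
  structure(
    list(
      image_size = as.integer(image_size),
      pupil_center = as.numeric(pupil_center),
      pupil_radius = as.numeric(pupil_radius),
      pupil_reflex_color = pupil_reflex_color,
      background_color = background_color,
      vessel_color = vessel_color,
      vessel_tree = vessel_tree,
      blur_sigma = blur_sigma,
      noise_sigma = noise_sigma,
      artifact_count = as.integer(artifact_count),
      seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

# Pixels covered by a branch stroke: disks of diameter `width` drawn along the
# path resampled to <= 0.5 px spacing. Returns linear indices into an
# nr x nc raster.
rasterize_branch <- function(branch, nr, nc) {
  path <- branch$path
  steps <- sqrt(rowSums((path[-1, , drop = FALSE] -
    path[-nrow(path), , drop = FALSE])^2))
  s <- c(0, cumsum(steps))
  total <- s[length(s)]
  ns <- max(2L, ceiling(total / 0.4) + 1L)
  sq <- seq(0, total, length.out = ns)
  pr <- stats::approx(s, path[, 1], xout = sq)$y
  pc <- stats::approx(s, path[, 2], xout = sq)$y
  w <- if (length(branch$width) == 1) {
    rep(branch$width, ns)
  } else {
    stats::approx(s, branch$width, xout = sq)$y
  }
  rad <- w / 2
  maxr <- ceiling(max(rad)) + 1L
  offs <- disk_offsets(maxr + 0.5)
  base_r <- round(pr)
  base_c <- round(pc)
  # expand samples x offsets, keep pixel centers within rad of the sample
  px_r <- rep(base_r, each = nrow(offs)) + rep(offs[, 1], times = ns)
  px_c <- rep(base_c, each = nrow(offs)) + rep(offs[, 2], times = ns)
  sr <- rep(pr, each = nrow(offs))
  sc <- rep(pc, each = nrow(offs))
  rr <- rep(rad, each = nrow(offs))
  keep <- (px_r - sr)^2 + (px_c - sc)^2 <= rr^2 &
    px_r >= 1 & px_r <= nr & px_c >= 1 & px_c <= nc
  unique((px_c[keep] - 1L) * nr + px_r[keep])
}

#' Render a synthetic scene
#'
#' Rendering order: background, pupil reflex disk, dark vessels, bright
#' artifacts, Gaussian blur, additive Gaussian noise, clip to `[0, 255]`.
#' Ground truth is computed analytically before any degradation.
#'
#' @param spec a [scene_spec()].
#' @return A list with `image` ([rgb_image]) and `truth`: pupil mask, vessel
#'   mask, per-branch analytic length/width, branch count, and density
#'   (percent of pupil pixels covered by vessels).
#' @export
render_scene <- function(spec) {
  nr <- spec$image_size[1]
  nc <- spec$image_size[2]
  ctr <- spec$pupil_center
  rad <- spec$pupil_radius
  if (ctr[1] - rad < 1 || ctr[1] + rad > nr ||
    ctr[2] - rad < 1 || ctr[2] + rad > nc) {
    stop(sprintf(
      "render_scene: pupil disk (center %.1f,%.1f radius %.1f) exceeds image bounds %dx%d",
      ctr[1], ctr[2], rad, nr, nc
    ))
  }
  pupil <- disk_mask(c(nr, nc), ctr, rad)
  for (i in seq_along(spec$vessel_tree)) {
    p <- spec$vessel_tree[[i]]$path
    d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    if (any(d > rad)) {
      stop(sprintf(
        "render_scene: vessel branch %d leaves the pupil disk (max offset %.1f > radius %.1f)",
        i, max(d), rad
      ))
    }
  }

  chans <- lapply(1:3, function(ch) {
    matrix(spec$background_color[ch], nr, nc)
  })
  for (ch in 1:3) chans[[ch]][pupil] <- spec$pupil_reflex_color[ch]

  vessel <- matrix(FALSE, nr, nc)
  lengths <- numeric(0)
  widths <- numeric(0)
  for (b in spec$vessel_tree) {
    idx <- rasterize_branch(b, nr, nc)
    vessel[idx] <- TRUE
    lengths <- c(lengths, b$length)
    widths <- c(widths, mean(b$width))
  }
  vessel <- vessel & pupil
  for (ch in 1:3) chans[[ch]][vessel] <- spec$vessel_color[ch]

  img <- with_seed(spec$seed, {
    if (spec$artifact_count > 0) {
      for (a in seq_len(spec$artifact_count)) {
        ar <- stats::runif(1, 1, nr)
        ac <- stats::runif(1, 1, nc)
        if (a %% 2 == 1) {
          # bright elliptical specular blob
          sa <- stats::runif(1, 2.5, 7)
          sb <- stats::runif(1, 1.5, sa)
          th <- stats::runif(1, 0, pi)
          dr <- outer(seq_len(nr) - ar, rep(1, nc))
          dc <- outer(rep(1, nr), seq_len(nc) - ac)
          xr <- dr * cos(th) + dc * sin(th)
          yr <- -dr * sin(th) + dc * cos(th)
          blob <- (xr / sa)^2 + (yr / sb)^2 <= 1
          for (ch in 1:3) chans[[ch]][blob] <- c(245, 240, 225)[ch]
        } else {
          # thin bright streak (mucus mimic)
          len <- stats::runif(1, 8, 25)
          th <- stats::runif(1, 0, pi)
          ends <- c(ar, ac) + len * c(cos(th), sin(th))
          ends <- clamp(ends, 2, c(nr, nc) - 1)
          if (any(abs(ends - c(ar, ac)) > 0.5)) {
            streak <- branch_spec(rbind(c(ar, ac), ends), width = 1.6)
            idx <- rasterize_branch(streak, nr, nc)
            for (ch in 1:3) {
              m <- chans[[ch]]
              m[idx] <- c(240, 235, 220)[ch]
              chans[[ch]] <- m
            }
          }
        }
      }
    }
    if (spec$blur_sigma > 0) {
      chans <- lapply(chans, gaussian_blur, sigma = spec$blur_sigma)
    }
    if (spec$noise_sigma > 0) {
      chans <- lapply(chans, function(m) {
        m + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
      })
    }
    arr <- array(0, dim = c(nr, nc, 3))
    for (ch in 1:3) arr[, , ch] <- clamp(chans[[ch]], 0, 255)
    arr
  })

  truth <- list(
    pupil_center = ctr,
    pupil_radius = rad,
    pupil_mask = pupil,
    vessel_mask = vessel,
    branch_lengths = lengths,
    branch_widths = widths,
    n_branches = length(spec$vessel_tree),
    density = if (sum(pupil) > 0) 100 * sum(vessel & pupil) / sum(pupil) else 0
  )
  list(image = rgb_image(img, source_id = "synthetic"), truth = truth)
}

#' Save a rendered scene with its ground-truth sidecar
#'
#' Writes the image as PNG and a JSON sidecar with the analytic ground truth
#' (geometry and per-branch metrics; masks are reconstructable from the spec).
#'
#' @param scene result of [render_scene()].
#' @param path output PNG path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_scene <- function(scene, path) {
  write_image(scene$image, path)
  tr <- scene$truth
  side <- list(
    pupil_center = tr$pupil_center, pupil_radius = tr$pupil_radius,
    n_branches = tr$n_branches, branch_lengths = tr$branch_lengths,
    branch_widths = tr$branch_widths, density = tr$density
  )
  jsonlite::write_json(side, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Documented feature distributions for simulated cohorts: rough pixel/percent
# scales of the biomarkers on a ~160 px pupil. Mean/SD pairs.
cohort_feature_params <- function() {
  list(
    n_branches = c(12, 4),
    branch_length_max = c(60, 15),
    branch_length_min = c(18, 5),
    branch_width_max = c(7, 1.5),
    branch_width_min = c(2.5, 0.6),
    branch_thickness_max = c(6, 1.2),
    branch_thickness_min = c(1.8, 0.4),
    tortuosity_max = c(1.25, 0.08),
    tortuosity_min = c(1.02, 0.02),
    density = c(8, 3)
  )
}

#' Simulate a longitudinal cohort of ALCV sessions
#'
#' Draws per-session imaging features from documented distributions and
#' generates the reference gestational age as a linear predictor plus a
#' subject-level random intercept and residual noise:
#' `ga = beta0 + sum(beta_j x_j) + b_subject + e`, with
#' `b ~ N(0, sigma_subject^2)` and `e ~ N(0, sigma_resid^2)`.
#'
#' @param n_subjects number of subjects, `>= 2`.
#' @param sessions_per_subject sessions per subject, `>= 1`.
#' @param beta named coefficient vector; must include `"(Intercept)"`. The
#'   default is the shipped fixed-coefficient model (see [default_ga_model()]).
#' @param sigma_subject SD of the subject random intercept, weeks.
#' @param sigma_resid residual SD, weeks.
#' @param seed integer seed; fully determines the table.
#' @return data.frame with `subject_id`, `session_id`, one column per feature
#'   named in `beta`, and `ultrasound_ga`.
#' @export
simulate_cohort <- function(n_subjects, sessions_per_subject,
                            beta = NULL,
                            sigma_subject = 1.5, sigma_resid = 0.7,
                            seed = 1L) {
  stopifnot(n_subjects >= 2, sessions_per_subject >= 1,
    sigma_subject >= 0, sigma_resid >= 0)
  if (is.null(beta)) {
    m <- default_ga_model()
    beta <- c("(Intercept)" = m$intercept, m$coefficients)
  }
  if (any(!is.finite(beta))) {
    stop("simulate_cohort: beta must be finite")
  }
  if (!"(Intercept)" %in% names(beta)) {
    stop("simulate_cohort: beta must contain an \"(Intercept)\" term")
  }
  terms <- setdiff(names(beta), "(Intercept)")
  params <- cohort_feature_params()
  n <- n_subjects * sessions_per_subject
  with_seed(seed, {
    feats <- matrix(numeric(0), nrow = n, ncol = 0)
    for (tm in terms) {
      p <- params[[tm]]
      if (is.null(p)) p <- c(0, 1)
      x <- stats::rnorm(n, p[1], p[2])
      if (p[1] > 0) x <- pmax(x, 0.05) # physical features are positive
      feats <- cbind(feats, x)
    }
    colnames(feats) <- terms
    eta <- beta[["(Intercept)"]] +
      if (length(terms) > 0) as.vector(feats %*% beta[terms]) else 0
    b <- rep(stats::rnorm(n_subjects, 0, sigma_subject),
      each = sessions_per_subject
    )
    e <- stats::rnorm(n, 0, sigma_resid)
    out <- data.frame(
      subject_id = rep(sprintf("S%03d", seq_len(n_subjects)),
        each = sessions_per_subject
      ),
      session_id = rep(sprintf("V%02d", seq_len(sessions_per_subject)),
        times = n_subjects
      ),
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(feats))
    out$ultrasound_ga <- eta + b + e
    out
  })
}
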