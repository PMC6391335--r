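# End-to-end orchestration: frames -> pupil -> vessels -> biomarkers -> GA.
#
# Videos are handled as directories of extracted still frames (PNG/PPM/JPEG,
# ordered by filename); no video codec is bundled, so MP4/MOV containers must
# be exploded to frames upstream. Frame indices are 0-based, following video
# convention.

#' Pipeline configuration
#'
#' Collects every tunable stage parameter. Unknown keys are rejected both
#' here and when reading a config file; the pipeline never silently
#' substitutes defaults for malformed keys.
#'
#' @param ... overrides of the defaults listed in the source.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    radius_range = NULL, # auto: 10-45% of short side
    max_candidates = 5,
    radius_step = 2,
    accumulator_floor = 0.3,
    voting_weights = c(1 / 3, 1 / 3, 1 / 3),
    margin_frac = 0.15,
    redness_min = 15,
    sat_min = 0.15,
    val_min = 0.2,
    p_low = 2,
    p_high = 98,
    boundary_erosion_px = 3,
    low = 0.25,
    high = 0.55,
    min_object_px = 20,
    prune_len = 5,
    normalize_by_pupil = FALSE,
    coefficients_file = NULL, # NULL = shipped model
    frame_stride = 1,
    top_k = 3,
    seed = 1L,
    log_level = "info"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop(
      "pipeline_config: unknown parameter(s): ",
      paste(bad, collapse = ", ")
    )
  }
  structure(utils::modifyList(defaults, over, keep.null = TRUE),
    class = "pipeline_config"
  )
}

#' Read/write a pipeline config file (JSON)
#'
#' @param path config file path.
#' @return [read_config()]: a `pipeline_config`; [write_config()]: `path`.
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "info") ||
    identical(config$log_level, "debug")) {
    message(sprintf(...))
  }
}

resolve_model <- function(config) {
  if (is.null(config$coefficients_file)) {
    default_ga_model()
  } else {
    load_ga_model(config$coefficients_file)
  }
}

#' Extract frames from a video directory
#'
#' @param video_path directory of still frames, ordered by filename. MP4/MOV
#'   files are rejected with a message (no codec support is bundled).
#' @param stride keep every `stride`-th frame, starting at frame 0.
#' @return List of [rgb_image] tagged with 0-based `frame_index` and
#'   `source_id`.
#' @export
extract_frames <- function(video_path, stride = 1) {
  stopifnot(stride >= 1)
  if (file.exists(video_path) && !dir.exists(video_path)) {
    ext <- tolower(tools::file_ext(video_path))
    if (ext %in% c("mp4", "mov", "avi")) {
      stop(
        "extract_frames: no video codec support available for '.", ext,
        "'; extract frames to a directory of stills first"
      )
    }
    stop("extract_frames: '", video_path, "' is not a frame directory")
  }
  if (!dir.exists(video_path)) {
    stop("extract_frames: no such video directory: ", video_path)
  }
  files <- sort(list.files(video_path,
    pattern = "\\.(png|ppm|jpg|jpeg|tif|tiff)$",
    ignore.case = TRUE, full.names = TRUE
  ))
  if (length(files) == 0) {
    stop("extract_frames: no readable frames in ", video_path)
  }
  pick <- seq(1, length(files), by = stride)
  lapply(pick, function(i) {
    read_image(files[i],
      frame_index = i - 1L,
      source_id = basename(video_path)
    )
  })
}

# Divide pixel-scaled biomarkers by the pupil radius for cross-image
# comparability; density and counts are already scale-free.
normalize_features <- function(features, pupil_radius) {
  scaled <- c(
    "branch_length_max", "branch_length_min",
    "branch_width_max", "branch_width_min",
    "branch_extent_max", "branch_extent_min"
  )
  for (fn in scaled) features[[fn]] <- features[[fn]] / pupil_radius
  features
}

#' Quantify one frame
#'
#' Full single-frame pipeline: pupil detection, contrast enhancement,
#' hysteresis segmentation, skeleton morphometry.
#'
#' @param image an [rgb_image].
#' @param config a [pipeline_config()].
#' @return List with `features` (`NULL` if no pupil found), `pupil`, `vmap`,
#'   `qc_flags`.
#' @export
quantify_frame <- function(image, config = pipeline_config()) {
  qc <- character(0)
  pupil <- tryCatch(
    detect_pupil(image,
      radius_range = config$radius_range,
      max_candidates = config$max_candidates,
      radius_step = config$radius_step,
      accumulator_floor = config$accumulator_floor,
      weights = config$voting_weights
    ),
    error = function(e) NULL
  )
  if (is.null(pupil)) {
    return(list(
      features = NULL, pupil = NULL, vmap = NULL,
      qc_flags = "no pupil detected"
    ))
  }
  if (pupil$fallback) qc <- c(qc, "pupil refinement fell back to raw disk")
  vness <- enhance_contrast(image, pupil,
    p_low = config$p_low,
    p_high = config$p_high,
    boundary_erosion_px = config$boundary_erosion_px
  )
  if (vness$flat) qc <- c(qc, "flat pupil interior; empty vesselness")
  vmap <- hysteresis_segment(vness,
    low = config$low, high = config$high,
    min_object_px = config$min_object_px
  )
  bset <- skeletonize_map(vmap, prune_len = config$prune_len)
  bset <- measure_branches(bset, vmap)
  features <- compute_features(bset, vmap)
  if (isTRUE(config$normalize_by_pupil)) {
    features <- normalize_features(features, pupil$candidate$radius[1])
  }
  list(features = features, pupil = pupil, vmap = vmap, qc_flags = qc)
}

#' Rank frames by pupil quality and vessel focus
#'
#' An automated stand-in for manual best-frame selection: each frame is
#' scored as (pupil voting score) x (focus), where focus is the variance of
#' the gradient magnitude inside the detected pupil, min-max normalized
#' across the frames of the video. Frames without a detectable pupil score 0.
#'
#' @param frames list of [rgb_image].
#' @param config a [pipeline_config()].
#' @return data.frame sorted by decreasing score (ties broken by
#'   `frame_index`): `position` (index into `frames`), `frame_index`,
#'   `pupil_score`, `focus`, `score`.
#' @export
rank_frames <- function(frames, config = pipeline_config()) {
  stopifnot(length(frames) > 0)
  rows <- lapply(seq_along(frames), function(i) {
    img <- frames[[i]]
    fi <- attr(img, "frame_index")
    if (is.null(fi)) fi <- i - 1L
    cands <- tryCatch(
      hough_circle_candidates(img,
        radius_range = config$radius_range,
        max_candidates = config$max_candidates,
        radius_step = config$radius_step,
        accumulator_floor = config$accumulator_floor
      ),
      error = function(e) NULL
    )
    if (is.null(cands) || nrow(cands) == 0) {
      return(data.frame(
        position = i, frame_index = fi,
        pupil_score = 0, focus = NA_real_
      ))
    }
    scored <- score_candidates(img, cands, weights = config$voting_weights)
    best <- scored[1, , drop = FALSE]
    mask <- disk_mask(dim(img)[1:2], c(best$row, best$col), best$radius)
    mag <- sobel(to_gray(img))$mag
    data.frame(
      position = i, frame_index = fi,
      pupil_score = best$total_score, focus = stats::var(mag[mask])
    )
  })
  df <- do.call(rbind, rows)
  det <- !is.na(df$focus)
  fnorm <- rep(0, nrow(df))
  if (any(det)) fnorm[det] <- minmax_norm(df$focus[det])
  df$score <- ifelse(det, df$pupil_score * fnorm, 0)
  df[order(-df$score, df$frame_index), , drop = FALSE]
}

#' Run the full pipeline for one imaging session
#'
#' Per video, the `top_k` best-ranked frames with a detected pupil are
#' quantified and averaged; per-video biomarkers are then averaged across
#' videos ([aggregate_session()]) and gestational age is predicted from the
#' configured coefficients. Sessions in which no frame shows a usable pupil
#' are flagged `"insufficient retroillumination"` and carry no features.
#'
#' @param config a [pipeline_config()].
#' @param video_paths one or more frame directories.
#' @param subject_id,session_id identifiers recorded in the result.
#' @param ultrasound_ga optional reference GA, weeks.
#' @param frames optional explicit selection: a list (one element per video)
#'   of integer vectors of 0-based frame indices, overriding the automatic
#'   ranking (mirrors the manual-selection workflow).
#' @return A `session_record`.
#' @export
run_session <- function(config, video_paths,
                        subject_id = "S000", session_id = "V01",
                        ultrasound_ga = NA_real_, frames = NULL) {
  stopifnot(length(video_paths) >= 1)
  model <- resolve_model(config)
  per_video <- list()
  selected <- list()
  qc <- character(0)
  for (vi in seq_along(video_paths)) {
    vp <- video_paths[[vi]]
    imgs <- extract_frames(vp, stride = config$frame_stride)
    if (!is.null(frames)) {
      want <- frames[[vi]]
      have <- vapply(imgs, function(im) attr(im, "frame_index"), numeric(1))
      missing <- setdiff(want, have)
      if (length(missing) > 0) {
        stop(
          "run_session: frame index(es) ", paste(missing, collapse = ", "),
          " not present in ", vp
        )
      }
      take <- match(want, have)
    } else {
      rk <- rank_frames(imgs, config)
      rk <- rk[rk$score > 0 | (rk$pupil_score > 0 & !is.na(rk$focus)), ,
        drop = FALSE
      ]
      take <- utils::head(rk$position, config$top_k)
    }
    frame_feats <- list()
    for (ti in take) {
      qf <- quantify_frame(imgs[[ti]], config)
      qc <- c(qc, qf$qc_flags)
      if (!is.null(qf$features)) {
        frame_feats[[length(frame_feats) + 1]] <- qf$features
        selected[[length(selected) + 1]] <- list(
          video = vp,
          frame_index = attr(imgs[[ti]], "frame_index")
        )
      }
    }
    if (length(frame_feats) > 0) {
      per_video[[length(per_video) + 1]] <- aggregate_session(frame_feats)
    }
    pipeline_log(
      config, "video %s: %d/%d frames quantified",
      vp, length(frame_feats), length(imgs)
    )
  }
  if (length(per_video) == 0) {
    return(structure(
      list(
        subject_id = subject_id, session_id = session_id,
        video_paths = video_paths, selected_frames = list(),
        features = NULL, predicted_ga = NA_real_,
        ultrasound_ga = ultrasound_ga,
        qc_flags = unique(c(qc, "insufficient retroillumination"))
      ),
      class = "session_record"
    ))
  }
  features <- aggregate_session(per_video)
  predicted <- predict_ga(model, features)
  structure(
    list(
      subject_id = subject_id, session_id = session_id,
      video_paths = video_paths, selected_frames = selected,
      features = features, predicted_ga = predicted,
      ultrasound_ga = ultrasound_ga, qc_flags = unique(qc)
    ),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record %s/%s: %s%s>\n", x$subject_id, x$session_id,
    if (is.null(x$features)) {
      "QC FAILED"
    } else {
      sprintf("predicted GA %.2f weeks", x$predicted_ga)
    },
    if (length(x$qc_flags)) {
      paste0(" [", paste(x$qc_flags, collapse = "; "), "]")
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Agreement analysis over session records
#'
#' Keeps records carrying both a predicted and an ultrasound GA, delegates to
#' [bland_altman()], and optionally writes a JSON report plus Bland-Altman
#' and identity plots.
#'
#' @param records list of `session_record` (or a data.frame with
#'   `predicted_ga` and `ultrasound_ga` columns).
#' @param out_dir optional output directory for `agreement.json` and plots.
#' @return An `agreement_stats`.
#' @export
run_agreement <- function(records, out_dir = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    df <- do.call(rbind, lapply(records, function(r) {
      data.frame(
        predicted_ga = if (is.null(r$predicted_ga)) NA else r$predicted_ga,
        ultrasound_ga = if (is.null(r$ultrasound_ga)) NA else r$ultrasound_ga
      )
    }))
  }
  ok <- stats::complete.cases(df[, c("predicted_ga", "ultrasound_ga")])
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < 2) {
    stop("run_agreement: need >= 2 records with both predicted and reference GA")
  }
  stats <- bland_altman(df$predicted_ga, df$ultrasound_ga)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(stats),
      file.path(out_dir, "agreement.json"),
      auto_unbox = TRUE, digits = NA
    )
    plot_bland_altman(stats, df$predicted_ga, df$ultrasound_ga,
      path = file.path(out_dir, "bland_altman.png")
    )
    plot_identity(df$predicted_ga, df$ultrasound_ga,
      path = file.path(out_dir, "identity.png")
    )
  }
  stats
}
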