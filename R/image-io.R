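#' RGB image container
#'
#' A thin wrapper around a `rows x cols x 3` numeric array with intensities in
#' `[0, 255]`, channels ordered red, green, blue. Optional `frame_index` and
#' `source_id` attributes identify the frame within a video.
#'
#' @param pixels numeric array `rows x cols x 3` in `[0, 255]`, or a matrix
#'   (replicated to three channels).
#' @param frame_index optional integer frame index within the source video.
#' @param source_id optional character identifier of the source video/file.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, frame_index = NULL, source_id = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("rgb_image: pixel intensities must be finite and in [0, 255]")
  }
  structure(pixels,
    frame_index = frame_index, source_id = source_id,
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<rgb_image %d x %d%s%s>\n", d[1], d[2],
    if (!is.null(attr(x, "source_id"))) {
      paste0(" source=", attr(x, "source_id"))
    } else {
      ""
    },
    if (!is.null(attr(x, "frame_index"))) {
      paste0(" frame=", attr(x, "frame_index"))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Read a still image
#'
#' Reads PNG, JPEG or plain-text PPM (P3) into an [rgb_image]. Gray images are
#' replicated across channels; alpha channels are dropped.
#'
#' @param path file path; format inferred from the extension.
#' @param frame_index,source_id passed to [rgb_image()].
#' @return An [rgb_image].
#' @export
read_image <- function(path, frame_index = NULL, source_id = NULL) {
  if (!file.exists(path)) {
    stop("read_image: no such file: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path) * 255
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("read_image: the 'jpeg' package is required for JPEG input")
    }
    a <- jpeg::readJPEG(path) * 255
  } else if (ext == "ppm") {
    a <- read_ppm(path)
  } else {
    stop("read_image: unsupported image format '.", ext, "'")
  }
  if (is.matrix(a)) {
    a <- array(rep(a, 3), dim = c(dim(a), 3))
  }
  if (dim(a)[3] > 3) {
    a <- a[, , 1:3, drop = FALSE]
  }
  rgb_image(a, frame_index = frame_index, source_id = source_id)
}

#' Write a still image
#'
#' Writes an [rgb_image] (or plain array/matrix in `[0, 255]`) as PNG or
#' plain-text PPM (P3).
#'
#' @param img image to write.
#' @param path destination; `.png` or `.ppm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  a <- unclass(img)
  if (is.matrix(a)) {
    a <- array(rep(a, 3), dim = c(dim(a), 3))
  }
  a <- clamp(a, 0, 255)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(a / 255, path)
  } else if (ext == "ppm") {
    write_ppm(a, path)
  } else {
    stop("write_image: unsupported output format '.", ext, "'")
  }
  invisible(path)
}

# Plain-text (P3) PPM: a text-only interchange format used for fixtures.
read_ppm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P3") {
    stop("read_ppm: only ASCII 'P3' PPM is supported")
  }
  nc <- as.integer(toks[2])
  nr <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc * 3) {
    stop("read_ppm: truncated pixel data in ", path)
  }
  # PPM stores row-major RGB triples
  a <- array(0, dim = c(nr, nc, 3))
  m <- matrix(vals, nrow = 3) # 3 x (nr*nc), pixels row-major
  for (ch in 1:3) {
    a[, , ch] <- matrix(m[ch, ], nrow = nr, ncol = nc, byrow = TRUE)
  }
  a * (255 / maxv)
}

write_ppm <- function(a, path) {
  nr <- dim(a)[1]
  nc <- dim(a)[2]
  v <- as.integer(round(clamp(a, 0, 255)))
  a <- array(v, dim = dim(a))
  m <- rbind(
    as.vector(t(a[, , 1])),
    as.vector(t(a[, , 2])),
    as.vector(t(a[, , 3]))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(nc, nr), "255"), con)
  writeLines(paste(as.vector(m), collapse = " "), con)
  invisible(path)
}
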