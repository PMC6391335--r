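# Low-level raster operations shared by the pipeline stages.
#
# Images are numeric matrices (gray) or rows x cols x 3 arrays (RGB) with
# intensities in [0, 255]; masks are logical matrices. All coordinates are
# 1-based (row, col), matching R matrix indexing.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Shift matrix content by (dr, dc): result[r, c] = m[r - dr, c - dc], `pad`
# where the source index falls outside the matrix.
mat_shift <- function(m, dr, dc, pad = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) > 0 && length(cs) > 0) {
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

# Separable Gaussian blur with edge replication. sigma = 0 is the identity.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) {
    return(m)
  }
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(m)
  nc <- ncol(m)
  # rows pass (vertical), then cols pass, replicating edges via index clamping
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    idx <- clamp(seq_len(nr) + (i - rad - 1L), 1L, nr)
    out <- out + k[i] * m[idx, , drop = FALSE]
  }
  out2 <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    idx <- clamp(seq_len(nc) + (i - rad - 1L), 1L, nc)
    out2 <- out2 + k[i] * out[, idx, drop = FALSE]
  }
  out2
}

# Sobel gradients; returns list(gx, gy, mag). gy increases down rows.
sobel <- function(m) {
  sh <- function(dr, dc) mat_shift(m, dr, dc, pad = 0)
  gx <- (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1)) -
    (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1))
  gy <- (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
    (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Logical disk raster: pixels whose centers lie within `radius` of `center`.
disk_mask <- function(dim, center, radius) {
  dr <- outer(seq_len(dim[1]) - center[1], rep(1, dim[2]))
  dc <- outer(rep(1, dim[1]), seq_len(dim[2]) - center[2])
  dr * dr + dc * dc <= radius * radius
}

neighbor_offsets <- function(connectivity = 8) {
  if (connectivity == 4) {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else {
    cbind(
      dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
      dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
    )
  }
}

# Connected-component labels (0 = background) via the pixel adjacency graph.
# Labels are renumbered so that component 1 has the smallest linear index,
# making labeling deterministic.
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) {
    return(lab)
  }
  pos <- match(seq_len(nr * nc), idx) # linear index -> vertex id
  offs <- neighbor_offsets(connectivity)
  edges <- NULL
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (k in seq_len(nrow(offs))) {
    r2 <- r + offs[k, 1]
    c2 <- cc + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    v2 <- pos[nb]
    keep <- !is.na(v2)
    if (any(keep)) {
      edges <- rbind(edges, cbind(which(ok)[keep], v2[keep]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  # renumber by first appearance in linear-index order
  comp <- match(comp, unique(comp))
  lab[idx] <- comp
  lab
}

largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (!any(lab > 0)) {
    return(mask & FALSE)
  }
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

remove_small_components <- function(mask, min_px, connectivity = 8) {
  if (min_px <= 1 || !any(mask)) {
    return(mask)
  }
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  lab > 0 & lab %in% keep
}

# Fill holes: background (4-connected) components not touching the border.
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 4)
  if (!any(lab > 0)) {
    return(mask)
  }
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr * dr + dc * dc <= radius * radius
  cbind(dr = dr[keep], dc = dc[keep])
}

binary_dilate <- function(mask, radius) {
  offs <- disk_offsets(radius)
  out <- mask & FALSE
  m <- mask * 1
  for (k in seq_len(nrow(offs))) {
    out <- out | (mat_shift(m, offs[k, 1], offs[k, 2], pad = 0) > 0)
  }
  out
}

binary_erode <- function(mask, radius) {
  offs <- disk_offsets(radius)
  out <- mask | TRUE
  m <- mask * 1
  for (k in seq_len(nrow(offs))) {
    out <- out & (mat_shift(m, offs[k, 1], offs[k, 2], pad = 0) > 0)
  }
  out
}

binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

# Exact Euclidean distance transform (Felzenszwalb & Huttenlocher): distance
# from each TRUE pixel to the nearest FALSE pixel; 0 on FALSE pixels. A mask
# with no FALSE pixel returns Inf everywhere.
edt <- function(mask) {
  big <- 1e12
  f <- ifelse(mask, big, 0)
  nr <- nrow(f)
  nc <- ncol(f)
  d1 <- function(fv) {
    n <- length(fv)
    if (n == 1) {
      return(fv)
    }
    d <- numeric(n)
    v <- integer(n)
    z <- numeric(n + 1)
    k <- 1L
    v[1] <- 1L
    z[1] <- -Inf
    z[2] <- Inf
    for (q in 2:n) {
      repeat {
        s <- ((fv[q] + q * q) - (fv[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
        if (k > 1 && s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1] <- Inf
    }
    k <- 1L
    for (q in 1:n) {
      while (z[k + 1] < q) k <- k + 1L
      d[q] <- (q - v[k])^2 + fv[v[k]]
    }
    d
  }
  g <- apply(f, 2, d1) # along rows (per column)
  g <- t(apply(g, 1, d1)) # along cols (per row)
  out <- sqrt(g)
  out[out >= sqrt(big)] <- Inf
  out
}

# Circular cross-correlation of `img` with a kernel given as offset rows
# (dr, dc, w): out[r, c] = sum w * img[r + dr, c + dc] (wrapping).
xcorr_offsets <- function(img, offs, w) {
  nr <- nrow(img)
  nc <- ncol(img)
  kern <- matrix(0, nr, nc)
  kr <- ((offs[, 1]) %% nr) + 1L
  kc <- ((offs[, 2]) %% nc) + 1L
  for (i in seq_along(kr)) {
    kern[kr[i], kc[i]] <- kern[kr[i], kc[i]] + w[i]
  }
  acc <- stats::fft(stats::fft(img) * Conj(stats::fft(kern)), inverse = TRUE)
  Re(acc) / (nr * nc)
}

# Convert RGB array to gray [0,255] (unweighted channel mean, matching the
# pipeline's use of raw channel intensities elsewhere).
to_gray <- function(img) {
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}
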