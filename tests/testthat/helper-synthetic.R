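# Shared fixtures built in code: synthetic vessel trees with analytic truth,
# and small brute-force oracles kept independent of the package internals.

# Wrap a ground-truth mask pair as a vessel_map, bypassing segmentation.
gt_vessel_map <- function(scene) {
  structure(
    list(
      mask = scene$truth$vessel_mask,
      pupil = list(mask = scene$truth$pupil_mask),
      params_used = list(low = NA, high = NA, min_object_px = 0)
    ),
    class = "vessel_map"
  )
}

# Seeded synthetic vessel tree inside a pupil disk. Odd seeds: a star tree
# (one junction, 3-5 arms); even seeds: 3-5 disjoint gently sinuous branches.
# Widths follow vessel allometry (long trunks thick, short twigs thin) within
# the 2-8 px range; lengths 20-80 px.
make_test_tree <- function(seed, image_size = c(160, 160), rad = 62) {
  set.seed(seed)
  ctr <- c(80, 80)
  star <- seed %% 2 == 1
  nb <- sample(3:5, 1)
  tree <- vector("list", nb)
  if (star) {
    base <- runif(1, 0, 2 * pi)
    angs <- base + (seq_len(nb) - 1) * 2 * pi / nb + runif(nb, -0.15, 0.15)
    lens <- runif(nb, 25, rad - 6)
    wids <- pmin(pmax(2 + (lens - 15) / 65 * 5 + runif(nb, -0.5, 0.5), 2), 8)
    for (i in seq_len(nb)) {
      u <- c(sin(angs[i]), cos(angs[i]))
      tree[[i]] <- branch_spec(rbind(ctr, ctr + lens[i] * u),
        width = wids[i]
      )
    }
  } else {
    phi <- runif(1, 0, pi)
    u <- c(sin(phi), cos(phi))
    nv <- c(-u[2], u[1])
    offs <- seq(-0.6 * rad, 0.6 * rad, length.out = nb)
    for (i in seq_len(nb)) {
      half_span <- sqrt(rad^2 - offs[i]^2) - 6
      len <- min(runif(1, 20, 80), 2 * half_span)
      wid <- pmin(pmax(2 + (len - 15) / 65 * 5 + runif(1, -0.5, 0.5), 2), 8)
      amp <- runif(1, 0, 2)
      start <- ctr + offs[i] * nv - (len / 2) * u
      end <- ctr + offs[i] * nv + (len / 2) * u
      tree[[i]] <- make_branch_sinusoid(start, end,
        amplitude = amp,
        cycles = sample(1:2, 1), width = wid
      )
    }
  }
  scene_spec(
    image_size = image_size, pupil_center = ctr, pupil_radius = rad,
    vessel_tree = tree, blur_sigma = 0, noise_sigma = 0,
    artifact_count = 0, seed = seed
  )
}

# Independent hysteresis oracle: plain threshold-then-BFS flood fill from
# seed pixels, no package helpers.
oracle_hysteresis <- function(v, low, high, min_object_px = 1) {
  nr <- nrow(v)
  nc <- ncol(v)
  cand <- v >= low
  keep <- matrix(FALSE, nr, nc)
  queue <- which(v >= high & cand)
  keep[queue] <- TRUE
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    r <- ((i - 1) %% nr) + 1
    cc <- ((i - 1) %/% nr) + 1
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr
        c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        j <- (c2 - 1) * nr + r2
        if (cand[j] && !keep[j]) {
          keep[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  if (min_object_px > 1 && any(keep)) {
    # BFS component sizes, same neighborhood
    lab <- matrix(0L, nr, nc)
    cur <- 0L
    for (i in which(keep)) {
      if (lab[i] > 0) next
      cur <- cur + 1L
      q <- i
      lab[i] <- cur
      while (length(q) > 0) {
        p <- q[1]
        q <- q[-1]
        r <- ((p - 1) %% nr) + 1
        cc <- ((p - 1) %/% nr) + 1
        for (dr in -1:1) {
          for (dc in -1:1) {
            r2 <- r + dr
            c2 <- cc + dc
            if ((dr == 0 && dc == 0) || r2 < 1 || r2 > nr ||
              c2 < 1 || c2 > nc) {
              next
            }
            j <- (c2 - 1) * nr + r2
            if (keep[j] && lab[j] == 0) {
              lab[j] <- cur
              q <- c(q, j)
            }
          }
        }
      }
    }
    sizes <- tabulate(lab[lab > 0])
    keep <- keep & matrix(sizes[ifelse(lab > 0, lab, 1)] >= min_object_px &
      lab > 0, nr, nc)
  }
  keep
}

# Brute-force circle detector: exhaustive template search over a center
# window and radius list, scoring each circle by the image-gradient support
# along its circumference (sharp maximum at the true rim). The gradient is
# computed by plain finite differences, independent of package internals.
oracle_best_circle <- function(gray, radii, rows, cols) {
  nr <- nrow(gray)
  nc <- ncol(gray)
  gr <- gray * 0
  gc <- gray * 0
  gr[2:(nr - 1), ] <- gray[3:nr, ] - gray[1:(nr - 2), ]
  gc[, 2:(nc - 1)] <- gray[, 3:nc] - gray[, 1:(nc - 2)]
  mag <- sqrt(gr^2 + gc^2)
  ang <- seq(0, 2 * pi, length.out = 97)[-97]
  best <- c(score = -Inf, row = 0, col = 0, radius = 0)
  for (r in radii) {
    for (cr in rows) {
      for (cc in cols) {
        pr <- pmin(pmax(round(cr + r * sin(ang)), 1), nr)
        pc <- pmin(pmax(round(cc + r * cos(ang)), 1), nc)
        s <- mean(mag[cbind(pr, pc)])
        if (s > best[["score"]]) {
          best <- c(score = s, row = cr, col = cc, radius = r)
        }
      }
    }
  }
  best
}
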