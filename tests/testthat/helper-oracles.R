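# Independent oracles and fixture builders used across the suite.

# Flood-fill connected-component labelling, written independently of the
# package's implementation (plain R, explicit queue).
flood_fill_oracle <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    nb <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    nb <- rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c)); lab[r, c] <- nxt
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Brute-force caliper sweep: projection width over angles 0..180 degrees in
# `step`-degree increments, on the convex hull of the boundary pixel centres.
sweep_feret_oracle <- function(region, step = 0.01) {
  pts <- unique(region$boundary)
  x <- pts[, 2]; y <- -pts[, 1]
  hi <- grDevices::chull(x, y)
  hx <- x[hi]; hy <- y[hi]
  ang <- seq(0, 180, by = step) * pi / 180
  wmin <- Inf; wmax <- -Inf
  for (a in split(ang, ceiling(seq_along(ang) / 3000))) {
    proj <- outer(cos(a), hx) + outer(sin(a), hy)
    w <- apply(proj, 1, max) - apply(proj, 1, min)
    wmin <- min(wmin, min(w)); wmax <- max(wmax, max(w))
  }
  c(min_feret = wmin, feret = wmax)
}

# Brute-force chain walk: Euclidean step lengths along the closed chain.
chain_walk_oracle <- function(boundary) {
  n <- nrow(boundary)
  tot <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    tot <- tot + sqrt(sum((boundary[i, ] - boundary[j, ])^2))
  }
  tot
}

# Rasterise a rotated ellipse (pixel-centre test) into a logical matrix.
rasterize_ellipse <- function(a, b, theta_deg = 0, pad = 3) {
  ext <- ceiling(max(a, b)) + pad
  th <- theta_deg * pi / 180
  g <- expand.grid(r_ = -ext:ext, c_ = -ext:ext)
  u <- g$c_ * cos(th) + (-g$r_) * sin(th)
  v <- -g$c_ * sin(th) + (-g$r_) * cos(th)
  matrix((u / a)^2 + (v / b)^2 <= 1, 2 * ext + 1, 2 * ext + 1)
}

# Random sparse logical mask with a reproducible seed.
random_mask <- function(h, w, p = 0.35, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(h * w) < p, h, w))
}

# One grain_region from a single-object mask.
region_from_mask <- function(mask) {
  label_components(mask, connectivity = 8)[[1]]
}

# A flat raster image holding a mask at the given intensities.
image_from_mask <- function(mask, fg = 60, bg = 245) {
  px <- matrix(bg, nrow(mask), ncol(mask))
  px[mask] <- fg
  raster_image(px)
}

# Ramanujan approximation of an ellipse perimeter (semi-axes a, b).
ellipse_perimeter_true <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}
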