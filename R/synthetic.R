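#' Specification of a synthetic grain scene
#'
#' Defaults emulate the field study the package targets: > 400 grains per
#' image on a 960 x 720 px canvas, grain length ~ 6.1 mm (CV 8.58 %),
#' width ~ 2.9 mm (CV 12.36 %), length-width correlation 0.608, and a
#' width-driven per-grain weight law `w = 26.22 * width - 37.43 + N(0, 1.1)`
#' mg — the metric Minor-model coefficients — so that the generated data
#' have a known "right answer" for index ranking. Grains are rendered as
#' rotated superellipses (exponent 2.5: rounder than a rectangle, more
#' angular than an ellipse; set `squareness = 2` for exact ellipses in
#' descriptor accuracy tests) on a bright background, with no two grains
#' closer than `min_gap_px`.
#'
#' @param n_grains grains per scene.
#' @param length_mean,length_cv grain length mean (mm) and CV (%).
#' @param width_mean,width_cv grain width mean (mm) and CV (%).
#' @param length_width_corr correlation between length and width.
#' @param weight_slope,weight_intercept,weight_noise_sd per-grain weight
#'   law applied to width (mg/mm, mg, mg).
#' @param scale mm per pixel of the rendered image.
#' @param image_width,image_height canvas size in pixels.
#' @param background,foreground 8-bit intensities of panel and grains.
#' @param noise_sd optional Gaussian intensity noise (0 = flat shading).
#' @param edge_aa render edges anti-aliased (pixel intensity proportional
#'   to sub-pixel coverage), emulating the optical blur of a real camera;
#'   the default, since it is this sub-pixel information that resolution
#'   enhancement recovers. `FALSE` renders hard binary edges, which
#'   segment exactly to the ground-truth rasterisation but quantise every
#'   boundary to whole pixels.
#' @param squareness superellipse exponent (2 = ellipse).
#' @param min_gap_px minimum boundary-to-boundary separation in px.
#' @param orientation_range half-range J of grain orientations in degrees
#'   (orientations drawn uniformly from `[-J, J]` around horizontal, as on
#'   a seed-counter plate). `NULL` (default) picks the widest range — up to
#'   fully random `[0, 180)` — for which the scene still packs at the
#'   required separation.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(n_grains = 450,
                       length_mean = 6.1, length_cv = 8.58,
                       width_mean = 2.9, width_cv = 12.36,
                       length_width_corr = 0.608,
                       weight_slope = 26.22, weight_intercept = -37.43,
                       weight_noise_sd = 1.1,
                       scale = 0.15,
                       image_width = 960, image_height = 720,
                       background = 245, foreground = 60,
                       noise_sd = 0, edge_aa = TRUE, squareness = 2.5,
                       min_gap_px = 2, orientation_range = NULL) {
  stopifnot(n_grains >= 1, length_mean > 0, width_mean > 0,
            length_cv >= 0, width_cv >= 0,
            abs(length_width_corr) < 1, scale > 0,
            image_width >= 1, image_height >= 1,
            background >= 0, background <= 255,
            foreground >= 0, foreground <= 255,
            weight_noise_sd >= 0, squareness > 0, min_gap_px >= 0)
  if (!is.null(orientation_range)) {
    stopifnot(orientation_range >= 0, orientation_range <= 90)
  }
  structure(as.list(environment()), class = "scene_spec")
}

# Sample (length, width) pairs from a correlated bivariate normal,
# truncated to positive values by rejection.
sample_dimensions <- function(n, spec) {
  sdl <- spec$length_mean * spec$length_cv / 100
  sdw <- spec$width_mean * spec$width_cv / 100
  rho <- spec$length_width_corr
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- n - nrow(out)
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    len <- spec$length_mean + sdl * z1
    wid <- spec$width_mean + sdw * z2
    ok <- len > 0 & wid > 0
    out <- rbind(out, cbind(len[ok], wid[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

# Pixel coordinates (row, col) inside a rotated superellipse centred at
# (cr, cc) with semi-axes a, b (px), orientation theta (deg, ccw from +x)
# and exponent p, evaluated at pixel centres.
superellipse_pixels <- function(cr, cc, a, b, theta_deg, p, h, w) {
  ext <- ceiling(max(a, b)) + 1
  r0 <- max(1, floor(cr - ext)); r1 <- min(h, ceiling(cr + ext))
  c0 <- max(1, floor(cc - ext)); c1 <- min(w, ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(matrix(integer(0), 0, 2))
  rows <- r0:r1; cols <- c0:c1
  th <- theta_deg * pi / 180
  # x right (columns), y up: y = -(row - cr)
  x <- rep(cols - cc, each = length(rows))
  y <- rep(-(rows - cr), times = length(cols))
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  inside <- (abs(u) / a)^p + (abs(v) / b)^p <= 1
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

# Sub-pixel coverage of a rotated superellipse over its bounding box,
# by ss x ss supersampling. Returns (row, col, coverage) for pixels with
# any coverage.
superellipse_coverage <- function(cr, cc, a, b, theta_deg, p, h, w, ss = 4) {
  ext <- ceiling(max(a, b)) + 2
  r0 <- max(1, floor(cr - ext)); r1 <- min(h, ceiling(cr + ext))
  c0 <- max(1, floor(cc - ext)); c1 <- min(w, ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0), coverage = numeric(0)))
  rows <- r0:r1; cols <- c0:c1
  th <- theta_deg * pi / 180
  base_x <- rep(cols - cc, each = length(rows))
  base_y <- rep(-(rows - cr), times = length(cols))
  offs <- (seq_len(ss) - 0.5) / ss - 0.5
  cover <- numeric(length(base_x))
  for (dx in offs) for (dy in offs) {
    x <- base_x + dx; y <- base_y + dy
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    cover <- cover + ((abs(u) / a)^p + (abs(v) / b)^p <= 1)
  }
  cover <- cover / ss^2
  keep <- cover > 0
  cbind(row = rep(rows, times = length(cols))[keep],
        col = rep(cols, each = length(rows))[keep],
        coverage = cover[keep])
}

# Half-extents of the axis-aligned bounding box of a rotated 2a x 2b
# rectangle (a superset of the superellipse for any exponent).
bbox_half_extents <- function(a, b, theta_deg) {
  th <- theta_deg * pi / 180
  cbind(hw = a * abs(cos(th)) + b * abs(sin(th)),
        hh = a * abs(sin(th)) + b * abs(cos(th)))
}

# Worst-case half-extents over orientations in [-J, J] degrees.
bbox_bounds_for_range <- function(a, b, J) {
  th_w <- pmin(J, atan2(b, a) * 180 / pi)   # hw maximised at tan(theta) = b/a
  th_h <- pmin(J, atan2(a, b) * 180 / pi)   # hh maximised at tan(theta) = a/b
  cbind(hw = a * cos(th_w * pi / 180) + b * sin(th_w * pi / 180),
        hh = a * sin(th_h * pi / 180) + b * cos(th_h * pi / 180))
}

# Shelf layout of grains with half-extents (hw, hh): grains are packed in
# rows, tallest first. Returns NULL when the canvas cannot hold them at the
# given pitch, otherwise row assignment and deterministic base positions.
shelf_layout <- function(hw, hh, w, h, pitch, margin) {
  ord <- order(-hh)
  avail_w <- w - 2 * margin
  rows <- list(); cur <- integer(0); cur_w <- 0
  for (i in ord) {
    need <- 2 * hw[i] + pitch
    if (cur_w + need > avail_w && length(cur) > 0) {
      rows[[length(rows) + 1]] <- cur
      cur <- integer(0); cur_w <- 0
    }
    if (need > avail_w) return(NULL)
    cur <- c(cur, i); cur_w <- cur_w + need
  }
  if (length(cur) > 0) rows[[length(rows) + 1]] <- cur
  heights <- vapply(rows, function(r) 2 * max(hh[r]) + pitch, numeric(1))
  if (sum(heights) > h - 2 * margin) return(NULL)
  list(rows = rows, heights = heights)
}

#' Generate a synthetic grain scene with ground truth
#'
#' Samples grain dimensions, renders each grain as a rotated superellipse
#' at a randomised non-overlapping position, applies the weight law to
#' each grain's width, and returns the image together with full ground
#' truth. Grains are laid out in randomly jittered rows, the way a vacuum
#' seed counter arrays them on the imaging panel; on sparse canvases the
#' orientations are fully random, while at the study's density (450 grains
#' on 960 x 720 px) the orientation range narrows automatically so the
#' required minimum separation can always be honoured. Deterministic for a
#' given seed.
#'
#' @param spec a [scene_spec()].
#' @param seed integer RNG seed.
#' @return list with `image` (a [raster_image()], grayscale), `truth`
#'   (list with per-grain data.frame `grains` (`length_mm`, `width_mm`,
#'   `orientation_deg`, `center_row`, `center_col`, `weight_mg`),
#'   `total_weight`, `mgw`, and the logical ground-truth `mask`), and the
#'   `spec`.
#' @export
generate_scene <- function(spec = scene_spec(), seed = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(as.integer(seed), {
    h <- spec$image_height; w <- spec$image_width
    n <- spec$n_grains
    dims <- sample_dimensions(n, spec)
    a <- dims[, 1] / 2 / spec$scale
    b <- dims[, 2] / 2 / spec$scale
    pitch <- spec$min_gap_px + 1  # +1 px rasterisation slack
    margin <- spec$min_gap_px + 1

    # Widest orientation range that is guaranteed to pack.
    cand <- if (is.null(spec$orientation_range))
      c(90, 60, 45, 30, 20, 15, 10, 7, 5, 3, 2, 1, 0) else spec$orientation_range
    J <- NA_real_; layout <- NULL
    for (Jc in cand) {
      bb <- bbox_bounds_for_range(a, b, Jc)
      layout <- shelf_layout(bb[, "hw"] + 1, bb[, "hh"] + 1, w, h, pitch, margin)
      if (!is.null(layout)) { J <- Jc; break }
    }
    if (is.null(layout)) {
      stop("cannot place ", n, " grains on a ", w, " x ", h,
           " px canvas at the required separation; ",
           "use a larger image or fewer grains")
    }

    theta <- stats::runif(n, -J, J) %% 180  # J = 90 covers all orientations
    he <- bbox_half_extents(a, b, theta)
    hw <- he[, "hw"] + 1; hh <- he[, "hh"] + 1

    # Randomised placement inside the shelf layout: shuffle each row,
    # spread the horizontal and vertical slack as random gaps, and jitter
    # each grain vertically within its row.
    cr <- numeric(n); cc <- numeric(n)
    v_slack <- (h - 2 * margin) - sum(layout$heights)
    v_extra <- diff(sort(c(0, stats::runif(length(layout$rows), 0, v_slack),
                           v_slack)))[seq_along(layout$rows)]
    y <- margin
    for (r in seq_along(layout$rows)) {
      row_idx <- layout$rows[[r]]
      idx <- row_idx[sample.int(length(row_idx))]
      y <- y + v_extra[r]
      row_h <- layout$heights[r]
      h_slack <- (w - 2 * margin) - sum(2 * hw[idx] + pitch)
      h_extra <- diff(sort(c(0, stats::runif(length(idx), 0, h_slack),
                             h_slack)))[seq_along(idx)]
      x <- margin
      for (k in seq_along(idx)) {
        i <- idx[k]
        x <- x + h_extra[k] + pitch / 2
        cc[i] <- x + hw[i]
        cr[i] <- y + pitch / 2 + hh[i] +
          stats::runif(1, 0, max(0, row_h - pitch - 2 * hh[i]))
        x <- x + 2 * hw[i] + pitch / 2
      }
      y <- y + row_h
    }

    occupancy <- matrix(FALSE, h, w)
    shade <- if (spec$edge_aa) matrix(0, h, w) else NULL
    pixels <- vector("list", n)
    for (i in seq_len(n)) {
      if (spec$edge_aa) {
        cov <- superellipse_coverage(cr[i], cc[i], a[i], b[i], theta[i],
                                     spec$squareness, h, w)
        px <- cov[cov[, "coverage"] >= 0.5, c("row", "col"), drop = FALSE]
        shade[cov[, c("row", "col"), drop = FALSE]] <- cov[, "coverage"]
      } else {
        px <- superellipse_pixels(cr[i], cc[i], a[i], b[i], theta[i],
                                  spec$squareness, h, w)
      }
      if (nrow(px) == 0) stop("grain ", i, " rasterised to zero pixels; ",
                              "increase the image resolution")
      occupancy[px] <- TRUE
      pixels[[i]] <- px
    }
    truth_df <- data.frame(
      grain = seq_len(n), length_mm = dims[, 1], width_mm = dims[, 2],
      orientation_deg = theta, center_row = cr, center_col = cc
    )
    truth_df$weight_mg <- spec$weight_slope * truth_df$width_mm +
      spec$weight_intercept +
      stats::rnorm(spec$n_grains, 0, spec$weight_noise_sd)
    img <- matrix(spec$background, h, w)
    if (spec$edge_aa) {
      img <- img + shade * (spec$foreground - spec$background)
    } else {
      img[occupancy] <- spec$foreground
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      img[img < 0] <- 0; img[img > 255] <- 255
    }
    list(
      image = raster_image(img, scale = spec$scale),
      truth = list(grains = truth_df,
                   total_weight = sum(truth_df$weight_mg),
                   mgw = mean(truth_df$weight_mg),
                   mask = occupancy,
                   grain_pixels = pixels),
      spec = spec,
      seed = as.integer(seed)
    )
  })
}

# Default 2x2 design effects: percent reductions applied to the length and
# width means for the second year and for deficit irrigation.
design_effects_default <- function() {
  c(year_length = 2.480, year_width = 1.566,
    irr_length = 1.377, irr_width = 5.127)
}

# Per-group multiplicative (length, width) mean shifts for a 2x2
# year x irrigation design.
group_multipliers <- function(year, irrigation, effects) {
  lm_ <- 1; wm_ <- 1
  if (year == 2) {
    lm_ <- lm_ * (1 - effects[["year_length"]] / 100)
    wm_ <- wm_ * (1 - effects[["year_width"]] / 100)
  }
  if (irrigation == "DI") {
    lm_ <- lm_ * (1 - effects[["irr_length"]] / 100)
    wm_ <- wm_ * (1 - effects[["irr_width"]] / 100)
  }
  c(length = lm_, width = wm_)
}

#' Generate a multi-sample synthetic dataset
#'
#' Generates `n_samples` scenes, optionally under a balanced 2 x 2
#' year x irrigation design whose group mean shifts (percent reductions of
#' grain length and width) default to the field-study effect sizes. Scene
#' seeds are derived from the master seed, so the dataset is reproducible.
#'
#' @param n_samples number of scenes.
#' @param base_spec base [scene_spec()].
#' @param design apply the 2 x 2 design (TRUE) or share the base spec
#'   across all samples (FALSE).
#' @param effects named percent reductions `year_length`, `year_width`,
#'   `irr_length`, `irr_width`.
#' @param seed master seed.
#' @return list of per-sample lists: `image`, `truth`, `spec`,
#'   `sample_id`, `year` (1/2), `irrigation` ("WI"/"DI").
#' @export
generate_dataset <- function(n_samples, base_spec = scene_spec(),
                             design = TRUE,
                             effects = design_effects_default(),
                             seed = 1) {
  stopifnot(n_samples >= 1)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1, n_samples))
  groups <- expand.grid(year = c(1, 2), irrigation = c("WI", "DI"),
                        stringsAsFactors = FALSE)
  out <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    g <- groups[(i - 1) %% nrow(groups) + 1, ]
    spec_i <- base_spec
    if (design) {
      mult <- group_multipliers(g$year, g$irrigation, effects)
      spec_i$length_mean <- base_spec$length_mean * mult[["length"]]
      spec_i$width_mean <- base_spec$width_mean * mult[["width"]]
    }
    sc <- generate_scene(spec_i, seed = seeds[i])
    sc$sample_id <- sprintf("S%03d", i)
    sc$year <- g$year
    sc$irrigation <- g$irrigation
    out[[i]] <- sc
  }
  out
}

#' Match measured grains to ground-truth grains by centroid
#'
#' Orders a measurement table so its rows correspond to the rows of the
#' scene's ground-truth grain table, by nearest centroid. When the image
#' was measured after bicubic enhancement, pass the factor so ground-truth
#' centres are mapped into enhanced coordinates.
#'
#' @param measurements per-grain data.frame from [measure_image()] (with
#'   `X`/`Y` centroid columns).
#' @param truth the `truth` element of a [generate_scene()] result.
#' @param factor enhancement factor used during measurement.
#' @return `measurements` reordered to match `truth$grains` rows.
#' @export
match_to_truth <- function(measurements, truth, factor = 1) {
  stopifnot(all(c("X", "Y") %in% names(measurements)))
  tx <- factor * (truth$grains$center_col - 0.5) + 0.5
  ty <- factor * (truth$grains$center_row - 0.5) + 0.5
  idx <- vapply(seq_along(tx), function(i) {
    which.min((measurements$X - tx[i])^2 + (measurements$Y - ty[i])^2)
  }, integer(1))
  if (anyDuplicated(idx)) {
    stop("ambiguous centroid matching between measurements and ground truth")
  }
  measurements[idx, , drop = FALSE]
}

#' Simulate a per-sample table without rendering images
#'
#' Statistical counterpart of [generate_dataset()] at the sample level:
#' each sample's mean grain width (`Minor`, mm) is drawn from its group
#' mean (2 x 2 design shifts as in [generate_dataset()]) plus the
#' within-sample averaging noise `width_sd / sqrt(n_grains)`, and MGW
#' follows the width law with sample-level residual noise — the form used
#' for parameter-recovery and cross-validation studies.
#'
#' @inheritParams generate_dataset
#' @param spec a [scene_spec()] supplying the width distribution, grain
#'   count and weight law.
#' @return data.frame with `sample_id`, `year`, `irrigation`, `Minor`
#'   (mm), `MGW` (mg).
#' @export
simulate_sample_table <- function(n_samples = 180, spec = scene_spec(),
                                  design = TRUE,
                                  effects = design_effects_default(),
                                  seed = 1) {
  stopifnot(n_samples >= 1)
  groups <- expand.grid(year = c(1, 2), irrigation = c("WI", "DI"),
                        stringsAsFactors = FALSE)
  withr::with_seed(as.integer(seed), {
    idx <- (seq_len(n_samples) - 1) %% nrow(groups) + 1
    wmu <- vapply(idx, function(j) {
      m <- if (design)
        group_multipliers(groups$year[j], groups$irrigation[j], effects)[["width"]]
      else 1
      spec$width_mean * m
    }, numeric(1))
    sdw <- spec$width_mean * spec$width_cv / 100
    minor <- stats::rnorm(n_samples, wmu, sdw / sqrt(spec$n_grains))
    mgw <- spec$weight_slope * minor + spec$weight_intercept +
      stats::rnorm(n_samples, 0, spec$weight_noise_sd)
    data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
               year = groups$year[idx], irrigation = groups$irrigation[idx],
               Minor = minor, MGW = mgw, stringsAsFactors = FALSE)
  })
}
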