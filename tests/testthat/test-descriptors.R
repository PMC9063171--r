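test_that("chain perimeter follows the stated step convention", {
  # 10 x 5 filled rectangle: boundary ring of axis steps, 2 * (9 + 4) = 26
  m <- matrix(FALSE, 7, 12)
  m[2:6, 2:11] <- TRUE
  b <- label_components(m)[[1]]$boundary
  expect_equal(boundary_perimeter(b, method = "chain"), 26)

  # matches a brute-force chain walk on an irregular region
  m2 <- random_mask(18, 18, p = 0.6, seed = 4)
  regs <- label_components(m2)
  big <- regs[[which.max(vapply(regs, function(r) nrow(r$pixel_coords), 1))]]
  expect_equal(boundary_perimeter(big$boundary, method = "chain"),
               chain_walk_oracle(big$boundary), tolerance = 1e-12)

  # degenerate single-point chain
  expect_warning(p0 <- boundary_perimeter(matrix(c(3, 3), 1, 2)), "degenerate")
  expect_equal(p0, 0)
})

test_that("perimeter estimators bracket a digital disk's true perimeter", {
  reg <- region_from_mask(rasterize_ellipse(50, 50))
  p_chain <- boundary_perimeter(reg$boundary, method = "chain")
  p_corr <- boundary_perimeter(reg$boundary)
  expect_lt(abs(p_chain - 2 * pi * 50) / (2 * pi * 50), 0.05)
  expect_lt(abs(p_corr - 2 * pi * 50) / (2 * pi * 50), 0.01)
})

test_that("moment ellipse fit preserves area exactly and recovers axes", {
  disk <- region_from_mask(rasterize_ellipse(50, 50))
  e <- fit_ellipse(disk)
  A <- nrow(disk$pixel_coords)
  expect_equal(e$major, 2 * sqrt(A / pi), tolerance = 1e-9)
  expect_equal(e$minor, 2 * sqrt(A / pi), tolerance = 1e-9)

  ell <- region_from_mask(rasterize_ellipse(60, 30))
  e2 <- fit_ellipse(ell)
  expect_equal(e2$major, 120, tolerance = 0.01)
  expect_equal(e2$minor, 60, tolerance = 0.01)
  expect_true(e2$angle < 1 || e2$angle > 179)

  rot <- region_from_mask(rasterize_ellipse(60, 30, 37))
  e3 <- fit_ellipse(rot)
  expect_equal(e3$angle, 37, tolerance = 1)
  expect_equal(e3$major, 120, tolerance = 0.012)

  # area preservation to floating tolerance on every fit
  for (r in list(disk, ell, rot)) {
    e <- fit_ellipse(r)
    A <- nrow(r$pixel_coords)
    expect_lt(abs(A - pi * (e$major / 2) * (e$minor / 2)) / A, 2.3e-10)
  }

  # collinear pixels degenerate to a zero minor axis
  line <- matrix(FALSE, 5, 9); line[3, 2:8] <- TRUE
  lr <- label_components(line)[[1]]
  el <- fit_ellipse(lr)
  expect_true(el$degenerate)
  expect_equal(el$minor, 0)
})

test_that("Feret diameters agree with hull geometry and the sweep oracle", {
  sq <- region_from_mask(matrix(TRUE, 101, 101))
  f <- feret_diameters(sq)
  expect_equal(f$min_feret, 100, tolerance = 1e-9)
  expect_equal(f$feret, 100 * sqrt(2), tolerance = 1e-9)

  rot <- region_from_mask(rasterize_ellipse(60, 30, 37))
  fr <- feret_diameters(rot)
  expect_equal(fr$min_feret, 60, tolerance = 0.01 * 60)
  expect_equal(fr$feret, 120, tolerance = 0.01 * 120)

  # single-pixel degeneracy
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  f1 <- feret_diameters(label_components(m1)[[1]])
  expect_true(f1$degenerate)
  expect_equal(c(f1$feret, f1$min_feret), c(0, 0))

  # calipers vs the 0.01-degree brute-force sweep: the max diameter agrees
  # to the sweep's accuracy; the exact min width can only be below the
  # sweep's grid minimum, within the sweep's angular resolution.
  for (seed in c(2, 6)) {
    m <- rasterize_ellipse(35, 16, seed * 17)
    reg <- region_from_mask(m)
    fd <- feret_diameters(reg)
    sw <- sweep_feret_oracle(reg)
    expect_equal(fd$feret, sw[["feret"]], tolerance = 1e-6)
    expect_lte(fd$min_feret, sw[["min_feret"]] + 1e-9)
    expect_gt(fd$min_feret, sw[["min_feret"]] * (1 - 1e-3))
  }
})

test_that("shape ratios evaluate their defining formulas", {
  r <- shape_ratios(area = 100, perimeter = 40, major = 14, minor = 10,
                    hull_area = 104)
  expect_equal(r$circularity, 4 * pi * 100 / 1600, tolerance = 1e-12)
  expect_equal(r$solidity, 100 / 104)
  expect_equal(r$aspect_ratio, 1.4)
  expect_equal(r$roundness, 4 * 100 / (pi * 196))

  # a large digital disk caps circularity at 1 under the corrected perimeter
  disk <- region_from_mask(rasterize_ellipse(60, 60))
  d <- measure_region(disk, image_from_mask(rasterize_ellipse(60, 60)))
  expect_lte(d$circularity, 1)
  expect_gt(d$circularity, 0.99)

  expect_error(shape_ratios(10, 0, 4, 2, 5, label = 7), "region 7")
  expect_error(shape_ratios(10, 12, 4, 2, 0), "hull")
  expect_error(shape_ratios(10, 12, 4, 0, 5), "minor")
})

test_that("intensity moments match direct computation and flag degeneracy", {
  m <- matrix(FALSE, 6, 6); m[2:5, 2:5] <- TRUE
  reg <- label_components(m)[[1]]

  flat <- image_from_mask(m, fg = 80)
  s0 <- intensity_stats(reg, flat)
  expect_true(s0$degenerate)
  expect_equal(c(s0$skewness, s0$kurtosis), c(0, 0))

  # symmetric two-level intensities: zero skewness, kurtosis -2
  px <- matrix(245, 6, 6)
  px[m] <- rep(c(10, 90), 8)
  s1 <- intensity_stats(reg, raster_image(px))
  expect_equal(s1$skewness, 0, tolerance = 1e-12)
  expect_equal(s1$kurtosis, -2, tolerance = 1e-12)

  # arbitrary intensities: brute-force standardized moments
  vals <- c(3, 7, 11, 200, 40, 40, 41, 90, 12, 55, 63, 5, 18, 77, 130, 22)
  px2 <- matrix(245, 6, 6)
  px2[reg$pixel_coords] <- vals
  s2 <- intensity_stats(reg, raster_image(px2))
  mu <- mean(vals); sdev <- sqrt(mean((vals - mu)^2))
  expect_equal(s2$skewness, mean((vals - mu)^3) / sdev^3, tolerance = 1e-12)
  expect_equal(s2$kurtosis, mean((vals - mu)^4) / sdev^4 - 3, tolerance = 1e-12)
})

test_that("measure_region assembles a coherent descriptor bundle", {
  sc <- generate_scene(scene_spec(n_grains = 8, image_width = 480,
                                  image_height = 360), seed = 17)
  regs <- segment_grains(sc$image)
  for (reg in regs[c(1, 4, 8)]) {
    d <- measure_region(reg, sc$image)
    expect_gte(d$major, d$minor)
    expect_gt(d$minor, 0)
    expect_gte(d$feret, d$min_feret)
    expect_gt(d$min_feret, 0)
    expect_equal(d$aspect_ratio, d$major / d$minor, tolerance = 1e-12)
    expect_lt(abs(d$area - pi * (d$major / 2) * (d$minor / 2)) / d$area, 1e-9)
    expect_lte(d$circularity, 1)
    expect_gt(d$solidity, 0.95)  # superellipses are convex
    expect_lte(d$solidity, 1)
  }
  # on ellipse fixtures the convexity and width relations are tight:
  # solidity within discretisation of 1, min caliper within 5 % of minor
  for (th in c(0, 52)) {
    m <- rasterize_ellipse(60, 30, th)
    d <- measure_region(region_from_mask(m), image_from_mask(m))
    expect_gte(d$solidity, 0.98)
    expect_gte(d$min_feret, d$minor * 0.95)
    expect_gte(d$feret, d$major * 0.98)
  }
  # metric conversion is plain unit arithmetic
  d <- measure_region(regs[[2]], sc$image, scale = 0.15)
  expect_equal(d$minor_mm, d$minor * 0.15)
  expect_equal(d$area_mm2, d$area * 0.15^2)
  expect_equal(measure_region(regs[[2]], sc$image, scale = 0.15)$minor_mm,
               d$minor * 0.15)
  expect_equal(19.3 * 0.15, 2.895)
})

test_that("descriptors scale correctly with rasterisation size", {
  sizes <- c(15, 60)
  rel_len <- rel_area <- numeric(2)
  for (i in seq_along(sizes)) {
    r <- sizes[i]
    reg <- region_from_mask(rasterize_ellipse(2 * r, r, 20))
    d <- measure_region(reg, image_from_mask(rasterize_ellipse(2 * r, r, 20)))
    rel_len[i] <- abs(d$minor - 2 * r) / (2 * r)
    rel_area[i] <- abs(d$area - pi * 2 * r * r) / (pi * 2 * r * r)
  }
  expect_lt(rel_len[2], rel_len[1])
  expect_lt(rel_area[2], rel_area[1])
  expect_lt(rel_len[2], 0.01)
  expect_lt(rel_area[2], 0.01)
})

test_that("shape descriptors are rotation-robust at fine resolution", {
  angles <- seq(0, 170, by = 34)
  vals <- t(vapply(angles, function(th) {
    m <- rasterize_ellipse(150, 75, th)
    d <- measure_region(region_from_mask(m), image_from_mask(m))
    c(circ = d$circularity, sol = d$solidity, ar = d$aspect_ratio)
  }, numeric(3)))
  spread <- apply(vals, 2, function(v) (max(v) - min(v)) / mean(v))
  expect_true(all(spread < 0.02))
})

test_that("per-grain tables carry the particle-analysis schema", {
  sc <- generate_scene(scene_spec(n_grains = 5, image_width = 320,
                                  image_height = 240), seed = 23)
  tab <- measure_image(sc$image)  # scale travels with the image
  expect_true(all(c("Label", "Area", "Perim.", "Major", "Minor", "Angle",
                    "Feret", "MinFeret", "Circ.", "Solidity", "AR", "Round",
                    "Skew", "Kurt", "X", "Y", "Area_mm2", "Minor_mm")
                  %in% names(tab)))
  expect_equal(tab$Label, 1:5)
  expect_equal(tab$Minor_mm, tab$Minor * 0.15)

  tab2 <- measure_image(sc$image, scale = NULL)
  expect_false("Minor_mm" %in% names(tab2))

  empty <- measure_image(raster_image(matrix(255, 20, 20), scale = 0.1))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("Area", "Minor_mm") %in% names(empty)))
})
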