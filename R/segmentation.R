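#' Automatic thresholds on a 256-bin intensity histogram
#'
#' `isodata_threshold()` is the iterative intermeans (IsoData variant)
#' method: starting from the overall mean, the threshold is repeatedly
#' replaced by the midpoint of the means of the two classes it induces,
#' until it stabilises. `otsu_threshold()` maximises the between-class
#' variance. Both operate on a length-256 vector of counts for levels
#' 0..255 and return a (possibly fractional) threshold level; pixels at or
#' below it form the dark class.
#'
#' @param counts integer vector of length 256, histogram of levels 0..255.
#' @return a single numeric threshold in `[0, 255]`.
#' @export
isodata_threshold <- function(counts) {
  stopifnot(length(counts) == 256, all(counts >= 0))
  counts <- as.numeric(counts)
  lev <- 0:255
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  nz <- lev[counts > 0]
  if (length(nz) == 1) return(nz - 0.5)  # uniform image: no darker class
  t_cur <- sum(lev * counts) / n
  for (i in 1:1000) {
    low <- lev <= t_cur
    n1 <- sum(counts[low]); n2 <- n - n1
    if (n1 == 0 || n2 == 0) break
    m1 <- sum(lev[low] * counts[low]) / n1
    m2 <- sum(lev[!low] * counts[!low]) / n2
    t_new <- (m1 + m2) / 2
    if (abs(t_new - t_cur) < 1e-7) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur
}

#' @rdname isodata_threshold
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256, all(counts >= 0))
  counts <- as.numeric(counts)
  lev <- 0:255
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  nz <- lev[counts > 0]
  if (length(nz) == 1) return(nz - 0.5)  # uniform image: no darker class
  w0 <- cumsum(counts) / n
  mu <- cumsum(lev * counts) / n
  mu_t <- mu[256]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  lev[which.max(between)]
}

#' Segment grains from a bright background by HSB brightness thresholding
#'
#' Converts the image to HSB and thresholds the Brightness channel
#' (`max(R, G, B)`). The foreground is the dark side of the threshold:
#' grains are imaged on a lit white panel, so they are darker than the
#' background. `invert = TRUE` flips this for dark-background setups.
#'
#' @param image a [raster_image()].
#' @param method `"default-isodata"` (iterative intermeans, the default
#'   automatic method), `"otsu"`, or `"fixed:<level>"` with a level in
#'   0..255.
#' @param invert take the bright side as foreground instead.
#' @return a logical `height x width` matrix of class `binary_mask` with
#'   attribute `threshold`.
#' @export
hsb_threshold <- function(image, method = "default-isodata", invert = FALSE) {
  stopifnot(inherits(image, "raster_image"))
  b <- round(brightness_channel(image))
  if (identical(method, "default-isodata") || identical(method, "otsu")) {
    counts <- tabulate(as.integer(b) + 1L, nbins = 256)
    thr <- if (identical(method, "otsu")) otsu_threshold(counts) else isodata_threshold(counts)
  } else if (grepl("^fixed:", method)) {
    thr <- suppressWarnings(as.numeric(sub("^fixed:", "", method)))
    if (!is.finite(thr) || thr < 0 || thr > 255) {
      stop("fixed threshold must be a level in [0, 255], got: ", method)
    }
  } else {
    stop("unknown threshold method: '", method,
         "' (expected 'default-isodata', 'otsu' or 'fixed:<0..255>')")
  }
  mask <- if (invert) b > thr else b <= thr
  structure(mask, class = c("binary_mask", class(mask)), threshold = thr)
}

#' Fill holes inside foreground regions
#'
#' Specular highlights can punch holes into a grain's mask; a hole corrupts
#' the area and solidity, so holes are filled before measurement.
#'
#' @param mask a logical mask.
#' @return the mask with interior holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  num <- array(as.numeric(mask), dim(mask))
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(num))) > 0.5
  dim(filled) <- dim(mask)
  structure(filled, class = class(mask), threshold = attr(mask, "threshold"))
}

#' Extract labelled grain regions from a binary mask
#'
#' Each maximal connected foreground component becomes one region, labelled
#' `1..N` in raster-scan order of its first pixel. No size or circularity
#' filtering is applied.
#'
#' @param mask logical mask (e.g. from [hsb_threshold()]).
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @param exclude_edges drop regions touching the image border.
#' @param trace also run [trace_boundary()] on each region (default TRUE).
#' @return a list of `grain_region` objects with fields `label`,
#'   `pixel_coords` (n x 2 matrix of 1-based (row, col)), `boundary`
#'   (k x 2 matrix of boundary pixel centres, clockwise), `bbox`
#'   `(row_min, col_min, row_max, col_max)`.
#' @export
label_components <- function(mask, connectivity = 8, exclude_edges = FALSE,
                             trace = TRUE) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- label_components_cpp(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) return(list())
  fg <- which(lab > 0)
  h <- nrow(mask)
  coords <- cbind(row = (fg - 1L) %% h + 1L, col = (fg - 1L) %/% h + 1L)
  by_label <- split(seq_len(nrow(coords)), lab[fg])
  regions <- vector("list", n)
  for (k in seq_len(n)) {
    pc <- coords[by_label[[as.character(k)]], , drop = FALSE]
    bbox <- c(row_min = min(pc[, 1]), col_min = min(pc[, 2]),
              row_max = max(pc[, 1]), col_max = max(pc[, 2]))
    if (exclude_edges &&
        (bbox[1] == 1 || bbox[2] == 1 || bbox[3] == h || bbox[4] == ncol(mask))) {
      regions[[k]] <- NULL
      next
    }
    reg <- structure(
      list(label = k, pixel_coords = pc, boundary = NULL, bbox = bbox),
      class = "grain_region"
    )
    if (trace) reg$boundary <- trace_boundary(reg)
    regions[[k]] <- reg
  }
  regions <- Filter(Negate(is.null), regions)
  if (exclude_edges) {
    for (i in seq_along(regions)) regions[[i]]$label <- i
  }
  regions
}

#' Trace the outer boundary of a region
#'
#' Moore-neighbour tracing through pixel centres, clockwise in image
#' coordinates, starting at the top-left boundary pixel (first foreground
#' pixel in raster-scan order). A single-pixel region yields a degenerate
#' one-point polygon.
#'
#' @param region a `grain_region`.
#' @return a k x 2 matrix of (row, col) boundary pixel coordinates forming
#'   a closed chain (last vertex connects back to the first).
#' @export
trace_boundary <- function(region) {
  stopifnot(inherits(region, "grain_region"))
  pc <- region$pixel_coords
  if (nrow(pc) == 0) stop("empty region")
  bb <- region$bbox
  sub <- matrix(FALSE, bb[3] - bb[1] + 1, bb[4] - bb[2] + 1)
  sub[cbind(pc[, 1] - bb[1] + 1L, pc[, 2] - bb[2] + 1L)] <- TRUE
  b <- moore_trace_cpp(sub)
  b[, 1] <- b[, 1] + bb[1] - 1L
  b[, 2] <- b[, 2] + bb[2] - 1L
  colnames(b) <- c("row", "col")
  b
}

#' Segment an image into grain regions
#'
#' Convenience wrapper: threshold ([hsb_threshold()]), fill interior holes
#' ([fill_holes()]), and extract labelled regions ([label_components()]).
#'
#' @inheritParams hsb_threshold
#' @inheritParams label_components
#' @param fill fill interior holes before labelling (default TRUE).
#' @return list of `grain_region`, with the mask in attribute `mask`.
#' @export
segment_grains <- function(image, method = "default-isodata", invert = FALSE,
                           connectivity = 8, fill = TRUE, exclude_edges = FALSE) {
  mask <- hsb_threshold(image, method = method, invert = invert)
  if (fill) mask <- fill_holes(mask)
  regions <- label_components(mask, connectivity = connectivity,
                              exclude_edges = exclude_edges)
  attr(regions, "mask") <- mask
  regions
}

#' Write a binary mask as an 8-bit PNG (0 background, 255 foreground)
#'
#' @param mask logical mask.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  img <- raster_image(matrix(ifelse(mask, 255, 0), nrow(mask), ncol(mask)))
  write_image(img, path)
}
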