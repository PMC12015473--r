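#' Calibrated scanner image
#'
#' Container for an 8-bit RGB raster with its acquisition resolution.
#' The only calibration used anywhere in the package is the scan dpi:
#' one pixel is `2.54/dpi` cm on a side (flatbed scanners have no
#' perspective distortion, so a single scalar scale suffices).
#'
#' @param pixels integer array `H x W x 3`, values 0-255.
#' @param dpi dots per inch of the scan (must be > 0).
#' @param source_id identifier of the source file or scene.
#' @param accession_id germplasm accession the buds belong to.
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(pixels, dpi, source_id = "", accession_id = "") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0)
    stop("`dpi` must be a single positive number")
  structure(list(pixels = pixels, dpi = dpi,
                 source_id = as.character(source_id),
                 accession_id = as.character(accession_id)),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scan_image> %d x %d px, %g dpi (%.6f cm/px), accession '%s'\n",
              d[1], d[2], x$dpi, px_scale(x), x$accession_id))
  invisible(x)
}

#' Pixel scale of a scan in cm per pixel
#'
#' @param img a [scan_image], or a dpi value.
#' @return `2.54 / dpi` in cm/px.
#' @export
px_scale <- function(img) {
  dpi <- if (inherits(img, "scan_image")) img$dpi else img
  2.54 / dpi
}

#' Read a scanner PNG as a calibrated image
#'
#' Greyscale images are promoted to RGB (R = G = B); an alpha channel, if
#' present, is dropped. No resampling is performed: the stated dpi is
#' attached as-is.
#'
#' @param path path to an 8-bit PNG.
#' @param dpi acquisition resolution (default 600, the usual flatbed
#'   photo-scan setting).
#' @param accession_id accession the scan belongs to.
#' @return A [scan_image].
#' @export
read_scan <- function(path, dpi = 600, accession_id = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(dpi) || dpi <= 0) stop("`dpi` must be positive")
  raw <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot decode PNG '", path,
                                           "': ", conditionMessage(e)))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  nch <- dim(raw)[3]
  if (nch == 2L)      raw <- array(rep(raw[, , 1L], 3L), c(dim(raw)[1:2], 3L))
  else if (nch >= 4L) raw <- raw[, , 1:3, drop = FALSE]
  px <- array(as.integer(round(raw * 255)), dim(raw))
  scan_image(px, dpi, source_id = basename(path), accession_id = accession_id)
}

#' Segmentation settings
#'
#' @param threshold_mode `"otsu"` (default) or `"fixed"`. Buds lie on a
#'   black light-absorbing background, so Otsu on the brightness channel
#'   separates them cleanly; the fixed mode is a fallback for pathological
#'   histograms.
#' @param fixed_threshold brightness cut on the 0-255 scale when
#'   `threshold_mode = "fixed"`.
#' @param opening_radius_px disc radius for morphological opening
#'   (removes speckle noise); 0 disables.
#' @param closing_radius_px disc radius for morphological closing
#'   (bridges small gaps); 0 disables.
#' @param min_area_cm2 components smaller than this are discarded
#'   (default 0.02 cm^2, far below any real apical bud).
#' @param exclude_border drop components touching the image border
#'   (default `TRUE`: such buds are likely truncated by the scan window).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_mode = c("otsu", "fixed"),
                                fixed_threshold = 40,
                                opening_radius_px = 2L,
                                closing_radius_px = 2L,
                                min_area_cm2 = 0.02,
                                exclude_border = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(fixed_threshold >= 0, fixed_threshold <= 255,
            opening_radius_px >= 0, closing_radius_px >= 0,
            min_area_cm2 > 0)
  structure(list(threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 opening_radius_px = as.integer(opening_radius_px),
                 closing_radius_px = as.integer(closing_radius_px),
                 min_area_cm2 = min_area_cm2,
                 exclude_border = isTRUE(exclude_border)),
            class = "segmentation_config")
}

#' Segment buds from a dark-background scan
#'
#' Thresholds the brightness channel V = max(R, G, B) (Otsu by default),
#' applies morphological opening then closing, fills holes, labels
#' 8-connected components, discards components below the minimum area and
#' (by default) components touching the image border. Masks are returned
#' in reading order: row-major by bounding-box top-left corner.
#'
#' @param img a [scan_image].
#' @param cfg a [segmentation_config].
#' @return A list of `bud_mask` objects, each with elements `label`,
#'   `mask` (cropped logical matrix), `bbox` (half-open
#'   `(row0, col0, row1, col1)` in parent-image pixels, 1-based start),
#'   `touches_border`, and `parent_dim`. An empty list is a valid result.
#' @export
segment_buds <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(img, "scan_image"), inherits(cfg, "segmentation_config"))
  v <- pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3]) / 255
  dim(v) <- dim(img$pixels)[1:2]
  if (diff(range(v)) < 1 / 255) {
    if (cfg$threshold_mode == "otsu") {
      warning("flat brightness histogram: Otsu threshold is degenerate; ",
              "no buds segmented")
      return(list())
    }
  }
  thr <- if (cfg$threshold_mode == "otsu")
    EBImage::otsu(EBImage::Image(v)) else cfg$fixed_threshold / 255
  fg <- v > thr
  if (all(fg) || !any(fg)) {
    warning("thresholding produced an all-", if (all(fg)) "foreground"
            else "background", " image; no buds segmented")
    return(list())
  }
  m <- fg + 0
  if (cfg$opening_radius_px > 0)
    m <- EBImage::opening(m, EBImage::makeBrush(2L * cfg$opening_radius_px + 1L,
                                                "disc"))
  if (cfg$closing_radius_px > 0)
    m <- EBImage::closing(m, EBImage::makeBrush(2L * cfg$closing_radius_px + 1L,
                                                "disc"))
  m <- EBImage::fillHull(m)
  lab <- label8(m > 0.5)
  n <- max(lab)
  if (n == 0L) return(list())
  min_px <- cfg$min_area_cm2 / px_scale(img)^2
  out <- list()
  for (k in seq_len(n)) {
    sel <- lab == k
    if (sum(sel) < min_px) next
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    touches <- rows[1] == 1L || cols[1] == 1L ||
      rows[2] == nrow(sel) || cols[2] == ncol(sel)
    if (touches && cfg$exclude_border) next
    out[[length(out) + 1L]] <- structure(
      list(label = k,
           mask = sel[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
           bbox = c(rows[1], cols[1], rows[2] + 1L, cols[2] + 1L),
           touches_border = touches,
           parent_dim = dim(sel)),
      class = "bud_mask")
  }
  ord <- order(vapply(out, function(b) b$bbox[1], 1),
               vapply(out, function(b) b$bbox[2], 1))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$label <- i
  out
}

# 8-connected component labelling. EBImage::bwlabel is edge-connected
# (4-connectivity); labels that touch only diagonally are merged here with
# a small union-find over the label graph.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  a <- lab[-nrow(lab), -ncol(lab)]; b <- lab[-1, -1]
  c_ <- lab[-1, -ncol(lab)];        d <- lab[-nrow(lab), -1]
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Measure one bud mask
#'
#' Computes the four calibrated size features of a segmented bud:
#' * area `A`: foreground pixel count times `s^2`;
#' * perimeter `P`: arc length of the sub-pixel 0.5-level contour of the
#'   (lightly smoothed) mask, times `s`;
#' * length `L` and width `W`: long and short side of the minimum-area
#'   rotated bounding rectangle of the contour's convex hull (rotating
#'   calipers), times `s`.
#'
#' The contour is taken on a Gaussian-smoothed copy of the mask
#' (`sigma` = 1 px) so that oblique straight edges are tracked at sub-pixel
#' accuracy rather than as a pixel staircase; the small inward drift that
#' smoothing induces on curved boundary segments is compensated by the
#' first-order convex correction `pi * sigma^2` px added to the perimeter.
#'
#' @param mask a `bud_mask` from [segment_buds()] (or any object with a
#'   logical `mask` matrix element).
#' @param s pixel scale in cm/px (see [px_scale()]).
#' @param sigma smoothing bandwidth in px for the sub-pixel contour.
#' @return A one-row `data.frame` with `length_cm`, `width_cm`,
#'   `perimeter_cm`, `area_cm2`.
#' @export
measure_bud <- function(mask, s, sigma = 1) {
  m <- if (is.list(mask)) mask$mask else mask
  stopifnot(is.matrix(m), s > 0)
  npx <- sum(m)
  if (npx == 0L) stop("empty mask")
  if (npx == 1L) {
    message("single-pixel mask: degenerate features by convention")
    return(data.frame(length_cm = s, width_cm = s,
                      perimeter_cm = 4 * s, area_cm2 = s^2))
  }
  area <- npx * s^2
  ct <- subpixel_contour(m, sigma = sigma)
  if (is.null(ct)) {          # mask too small to survive smoothing
    ct <- subpixel_contour(m, sigma = 0)
    perim_px <- ct$length
  } else {
    perim_px <- ct$length + pi * sigma^2
  }
  lw <- min_area_rect(ct$points)
  data.frame(length_cm = lw[1] * s, width_cm = max(lw[2], 1e-9) * s,
             perimeter_cm = perim_px * s, area_cm2 = area)
}

# Sub-pixel 0.5-level contour of a binary mask, optionally Gaussian
# smoothed. Returns the longest closed polyline (points, arc length in px),
# or NULL if no contour exists at level 0.5.
subpixel_contour <- function(m, sigma = 1) {
  r <- if (sigma > 0) max(2L, ceiling(3 * sigma)) else 1L
  pad <- matrix(0, nrow(m) + 2L * r, ncol(m) + 2L * r)
  pad[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m))] <- m + 0
  if (sigma > 0) {
    k <- stats::dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
    pad <- stats::filter(pad, k, sides = 2)          # along columns
    pad <- t(stats::filter(t(pad), k, sides = 2))    # along rows
    pad[is.na(pad)] <- 0
  }
  cl <- grDevices::contourLines(seq_len(nrow(pad)), seq_len(ncol(pad)),
                                pad, levels = 0.5)
  if (!length(cl)) return(NULL)
  best <- NULL; best_len <- -1
  for (cc in cl) {
    p <- cbind(cc$x, cc$y)
    if (p[1, 1] != p[nrow(p), 1] || p[1, 2] != p[nrow(p), 2])
      p <- rbind(p, p[1, ])
    len <- sum(sqrt(rowSums(diff(p)^2)))
    if (len > best_len) { best_len <- len; best <- p }
  }
  list(points = best, length = best_len)
}

# Minimum-area rotated bounding rectangle via rotating calipers on the
# convex hull. Returns c(long side, short side) in the units of `points`.
min_area_rect <- function(points) {
  hi <- grDevices::chull(points)
  hp <- points[hi, , drop = FALSE]
  nh <- nrow(hp)
  if (nh == 1L) return(c(0, 0))
  if (nh == 2L) {
    d <- sqrt(sum((hp[2, ] - hp[1, ])^2))
    return(c(d, 0))
  }
  best <- c(Inf, 0, 0)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    th <- atan2(e[2], e[1])
    co <- cos(th); si <- sin(th)
    rx <- hp[, 1] * co + hp[, 2] * si
    ry <- -hp[, 1] * si + hp[, 2] * co
    w1 <- diff(range(rx)); w2 <- diff(range(ry))
    if (w1 * w2 < best[1]) best <- c(w1 * w2, w1, w2)
  }
  sort(best[2:3], decreasing = TRUE)
}

#' Extract bud features from a batch of scans
#'
#' Runs [segment_buds()] and [measure_bud()] over a list of images and
#' concatenates per-bud rows. A failure on one image is logged as a warning
#' and the batch continues.
#'
#' @param images list of [scan_image] objects.
#' @param cfg a [segmentation_config].
#' @param sigma contour smoothing bandwidth, see [measure_bud()].
#' @return A `data.frame` with columns `accession_id`, `source_id`,
#'   `bud_index`, `length_cm`, `width_cm`, `perimeter_cm`, `area_cm2`.
#'   Bud index numbers buds in reading order within each image.
#' @export
extract_features <- function(images, cfg = segmentation_config(), sigma = 1) {
  empty <- data.frame(accession_id = character(), source_id = character(),
                      bud_index = integer(), length_cm = numeric(),
                      width_cm = numeric(), perimeter_cm = numeric(),
                      area_cm2 = numeric())
  rows <- list(empty)
  for (img in images) {
    res <- tryCatch({
      masks <- segment_buds(img, cfg)
      if (!length(masks)) empty
      else {
        s <- px_scale(img)
        feats <- do.call(rbind, lapply(masks, measure_bud, s = s,
                                       sigma = sigma))
        cbind(data.frame(accession_id = img$accession_id,
                         source_id = img$source_id,
                         bud_index = seq_along(masks)), feats)
      }
    }, error = function(e) {
      warning("skipping image '", img$source_id, "': ", conditionMessage(e))
      empty
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate digital measurements against reference values
#'
#' Ordinary least-squares regression of estimated on reference values, as
#' used to benchmark digital bud measurements against manual calliper
#' measurements.
#'
#' @param est numeric vector of digital estimates.
#' @param truth numeric vector of paired reference measurements.
#' @return A list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation) and `rmse` (root-mean-square difference `est - truth`,
#'   in the trait's units).
#' @export
validate_against_reference <- function(est, truth) {
  stopifnot(length(est) == length(truth), length(est) >= 3,
            all(is.finite(est)), all(is.finite(truth)))
  if (stats::sd(truth) == 0) stop("reference values have zero variance")
  fit <- stats::lm(est ~ truth)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(est, truth)^2,
       rmse = sqrt(mean((est - truth)^2)))
}
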