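#' Construct a single-channel image
#'
#' A 2-D intensity grid with its physical pixel size. Pixel coordinates are
#' 0-based `(row, col)` throughout.
#'
#' @param pixels Numeric matrix of nonnegative, finite intensities.
#' @param pixel_size_um Physical edge length of one pixel (um), > 0.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels))) stop("intensities must be finite")
  if (any(pixels < 0)) stop("intensities must be >= 0")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be positive")
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "channel_image")
}

#' Construct a two-channel image
#'
#' Aligned receptor and arrestin channels with identical geometry.
#'
#' @param receptor,arrestin [channel_image()] objects of identical
#'   dimensions and pixel size.
#' @return An object of class `two_channel_image`.
#' @export
two_channel_image <- function(receptor, arrestin) {
  stopifnot(inherits(receptor, "channel_image"),
            inherits(arrestin, "channel_image"))
  if (!identical(dim(receptor$pixels), dim(arrestin$pixels)))
    stop("channel dimensions differ")
  if (receptor$pixel_size_um != arrestin$pixel_size_um)
    stop("channel pixel sizes differ")
  structure(list(receptor = receptor, arrestin = arrestin),
            class = "two_channel_image")
}

#' Construct a square region of interest
#'
#' @param row,col 0-based pixel coordinates of the ROI's top-left corner.
#' @param side Side length in pixels, >= 1.
#' @return An object of class `roi`.
#' @export
roi <- function(row, col, side) {
  stopifnot(row >= 0, col >= 0, side >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 side = as.integer(side)),
            class = "roi")
}

#' Physical area of an ROI
#'
#' @param r A [roi()].
#' @param pixel_size_um Pixel edge length (um).
#' @return Area in um^2: `(side * pixel_size_um)^2`.
#' @export
roi_area_um2 <- function(r, pixel_size_um) {
  stopifnot(inherits(r, "roi"))
  (r$side * pixel_size_um)^2
}

.crop <- function(mat, r) {
  if (is.null(r)) return(mat)
  stopifnot(inherits(r, "roi"))
  if (r$row + r$side > nrow(mat) || r$col + r$side > ncol(mat))
    stop("ROI exceeds image bounds")
  mat[(r$row + 1):(r$row + r$side), (r$col + 1):(r$col + r$side),
      drop = FALSE]
}

#' Mander's colocalization coefficients
#'
#' Thresholded Mander's overlap coefficients between the two channels,
#' optionally restricted to a square ROI:
#' M1 is the fraction of above-threshold receptor intensity lying in pixels
#' where the arrestin channel exceeds its threshold, and M2 the symmetric
#' quantity for the arrestin channel. Both lie in `[0, 1]`; 1 means complete
#' colocalization of that channel's signal.
#'
#' @param img A [two_channel_image()].
#' @param roi Optional [roi()]; `NULL` uses the whole image.
#' @param thr_receptor,thr_arrestin Intensity thresholds (AU), >= 0; pixels
#'   strictly above threshold count as signal.
#' @return A list of class `coloc_result`: `m1`, `m2`, `thresholds`.
#' @export
manders <- function(img, roi = NULL, thr_receptor, thr_arrestin) {
  stopifnot(inherits(img, "two_channel_image"),
            thr_receptor >= 0, thr_arrestin >= 0)
  r <- .crop(img$receptor$pixels, roi)
  a <- .crop(img$arrestin$pixels, roi)
  r_mask <- r > thr_receptor
  a_mask <- a > thr_arrestin
  denom_r <- sum(r[r_mask])
  denom_a <- sum(a[a_mask])
  if (denom_r == 0 || denom_a == 0)
    stop("undefined coefficient: a channel has no above-threshold signal")
  # numerators take the *other* channel's mask; clamp guards the rare case
  # where off-mask background pushes the ratio marginally above 1
  structure(list(m1 = min(sum(r[a_mask]) / denom_r, 1),
                 m2 = min(sum(a[r_mask]) / denom_a, 1),
                 thresholds = c(receptor = thr_receptor,
                                arrestin = thr_arrestin)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Mander's M1 = %.3f, M2 = %.3f (thresholds %g / %g AU)\n",
              x$m1, x$m2, x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' Automatic intensity threshold for one channel
#'
#' Either Otsu's histogram method (default, via \pkg{EBImage}) or a
#' background-statistics rule `mean + k * sd`.
#'
#' @param channel A [channel_image()].
#' @param method `"otsu"` or `"mean_plus_k_sd"`.
#' @param k Multiplier for `"mean_plus_k_sd"` (default 2).
#' @return Threshold in intensity units (AU).
#' @export
auto_threshold <- function(channel, method = c("otsu", "mean_plus_k_sd"),
                           k = 2) {
  stopifnot(inherits(channel, "channel_image"))
  method <- match.arg(method)
  x <- channel$pixels
  rg <- range(x)
  if (rg[1] == rg[2])
    stop("degenerate threshold: the image is constant")
  if (method == "otsu") {
    as.numeric(EBImage::otsu(EBImage::Image(x), range = rg, levels = 256L))
  } else {
    mean(x) + k * stats::sd(as.vector(x))
  }
}

# 8-connected component labels: EBImage::bwlabel is 4-connected, so labels
# touching only diagonally are merged with a small union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n <= 1L) return(lab)
  pairs <- NULL
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    r1 <- seq_len(nr - 1L); c1 <- if (off[2] > 0) seq_len(nc - 1L) else 2:nc
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + 1L, c1 + off[2], drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Detect puncta in a channel
#'
#' Thresholds the channel and extracts connected components
#' (8-connectivity: diagonal contact joins a component) with at least
#' `min_area_um2` of physical area. Returns centroids in 0-based pixel
#' coordinates and areas in um^2.
#'
#' @param channel A [channel_image()].
#' @param threshold Intensity threshold (AU), >= 0; pixels strictly above
#'   are foreground.
#' @param min_area_um2 Minimum punctum area (um^2), >= 0.
#' @return An object of class `puncta_set`: a data frame with columns
#'   `centroid_row`, `centroid_col` (0-based), `area_um2`,
#'   `mean_intensity`; attributes `labels` (the filtered label matrix, rows
#'   of the data frame numbered 1..n) and `pixel_size_um`.
#' @export
detect_puncta <- function(channel, threshold, min_area_um2 = 0) {
  stopifnot(inherits(channel, "channel_image"),
            threshold >= 0, min_area_um2 >= 0)
  px <- channel$pixels
  mask <- px > threshold
  empty <- data.frame(centroid_row = numeric(), centroid_col = numeric(),
                      area_um2 = numeric(), mean_intensity = numeric())
  if (!any(mask))
    return(structure(empty, class = c("puncta_set", "data.frame"),
                     labels = matrix(0L, nrow(px), ncol(px)),
                     pixel_size_um = channel$pixel_size_um))
  lab <- .label8(mask)
  ids <- seq_len(max(lab))
  npx <- tabulate(lab[lab > 0], nbins = max(lab))
  area <- npx * channel$pixel_size_um^2
  keep <- area >= min_area_um2
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[lab > 0]
  cr <- tapply(idx[, 1] - 1, labv, mean)  # 0-based centroids
  cc <- tapply(idx[, 2] - 1, labv, mean)
  mi <- tapply(px[lab > 0], labv, mean)
  out <- data.frame(centroid_row = as.numeric(cr[as.character(ids)]),
                    centroid_col = as.numeric(cc[as.character(ids)]),
                    area_um2 = area, mean_intensity = as.numeric(mi[as.character(ids)]))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  newlab <- matrix(0L, nrow(px), ncol(px))
  kept_ids <- ids[keep]
  if (length(kept_ids)) {
    remap <- integer(max(lab))
    remap[kept_ids] <- seq_along(kept_ids)
    newlab[lab > 0] <- remap[lab[lab > 0]]
  }
  structure(out, class = c("puncta_set", "data.frame"),
            labels = newlab, pixel_size_um = channel$pixel_size_um)
}

#' Classify receptor puncta by arrestin co-occupancy
#'
#' A receptor punctum counts as double-positive when at least
#' `overlap_fraction` of its pixels exceed the arrestin threshold; the
#' partial-overlap tolerance absorbs PSF-induced misregistration. Counts
#' partition the punctum set.
#'
#' @param receptor_puncta A [puncta_set()] from the receptor channel.
#' @param arrestin The arrestin [channel_image()] (same geometry).
#' @param thr_arrestin Arrestin intensity threshold (AU).
#' @param overlap_fraction Required fraction of punctum pixels above the
#'   arrestin threshold, in `[0, 1]` (default 0.3).
#' @return A list with `n_receptor_only`, `n_double_positive`, and
#'   `double_positive` (logical per punctum).
#' @export
classify_puncta <- function(receptor_puncta, arrestin, thr_arrestin,
                            overlap_fraction = 0.3) {
  stopifnot(inherits(receptor_puncta, "puncta_set"),
            inherits(arrestin, "channel_image"),
            overlap_fraction >= 0, overlap_fraction <= 1)
  lab <- attr(receptor_puncta, "labels")
  if (!identical(dim(lab), dim(arrestin$pixels)))
    stop("geometry mismatch between puncta labels and arrestin channel")
  n <- nrow(receptor_puncta)
  if (n == 0L)
    return(list(n_receptor_only = 0L, n_double_positive = 0L,
                double_positive = logical()))
  amask <- arrestin$pixels > thr_arrestin
  inlab <- lab > 0
  tot <- tabulate(lab[inlab], nbins = n)
  hit <- tabulate(lab[inlab & amask], nbins = n)
  dp <- hit / tot >= overlap_fraction
  list(n_receptor_only = sum(!dp), n_double_positive = sum(dp),
       double_positive = dp)
}

#' Puncta density inside an ROI
#'
#' Count of puncta whose centroid lies inside the ROI, scaled to the
#' conventional reporting unit of counts per 100 um^2.
#'
#' @param puncta A [puncta_set()].
#' @param r A [roi()].
#' @return Density (puncta per 100 um^2).
#' @export
puncta_density <- function(puncta, r) {
  stopifnot(inherits(puncta, "puncta_set"), inherits(r, "roi"))
  ps <- attr(puncta, "pixel_size_um")
  inside <- puncta$centroid_row >= r$row &
    puncta$centroid_row < r$row + r$side &
    puncta$centroid_col >= r$col &
    puncta$centroid_col < r$col + r$side
  sum(inside) * 100 / roi_area_um2(r, ps)
}

# bilinear interpolation at continuous 0-based (row, col) positions
.bilinear <- function(mat, rr, cc) {
  nr <- nrow(mat); nc <- ncol(mat)
  rr <- pmin(pmax(rr, 0), nr - 1)
  cc <- pmin(pmax(cc, 0), nc - 1)
  r0 <- pmin(floor(rr), nr - 2); c0 <- pmin(floor(cc), nc - 2)
  fr <- rr - r0; fc <- cc - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  mat[i00] * (1 - fr) * (1 - fc) + mat[i10] * fr * (1 - fc) +
    mat[i01] * (1 - fr) * fc + mat[i11] * fr * fc
}

#' Two-channel line profile
#'
#' Samples both channels by bilinear interpolation at evenly spaced points
#' along a straight segment, e.g. a trajectory from the plasma membrane to
#' the nucleus. Distances are physical (um) from the start point.
#'
#' @param img A [two_channel_image()].
#' @param start,end Numeric `c(row, col)` endpoints in 0-based pixel
#'   coordinates, within image bounds.
#' @param n_samples Number of samples, >= 2.
#' @return Data frame with columns `distance_um`, `receptor_AU`,
#'   `arrestin_AU`.
#' @export
line_profile <- function(img, start, end, n_samples) {
  stopifnot(inherits(img, "two_channel_image"),
            length(start) == 2L, length(end) == 2L, n_samples >= 2)
  d <- dim(img$receptor$pixels)
  for (p in list(start, end))
    if (p[1] < 0 || p[2] < 0 || p[1] > d[1] - 1 || p[2] > d[2] - 1)
      stop("profile endpoint outside image bounds")
  t <- seq(0, 1, length.out = n_samples)
  rr <- start[1] + t * (end[1] - start[1])
  cc <- start[2] + t * (end[2] - start[2])
  ps <- img$receptor$pixel_size_um
  data.frame(distance_um = t * sqrt(sum((end - start)^2)) * ps,
             receptor_AU = .bilinear(img$receptor$pixels, rr, cc),
             arrestin_AU = .bilinear(img$arrestin$pixels, rr, cc))
}
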