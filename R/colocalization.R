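#' Two-channel image pair
#'
#' @param channel_a,channel_b non-negative 2-D intensity matrices of equal
#'   shape.
#' @param mask optional logical matrix of the same shape selecting the
#'   pixels to analyse (default: all).
#' @return Object of class `image_pair`.
#' @export
image_pair <- function(channel_a, channel_b, mask = NULL) {
  if (!is.matrix(channel_a) || !is.matrix(channel_b))
    stop_data("channels must be 2-D matrices")
  if (!all(dim(channel_a) == dim(channel_b)))
    stop_data("channel shapes differ")
  if (any(!is.finite(channel_a)) || any(!is.finite(channel_b)))
    stop_data("intensities must be finite")
  if (any(channel_a < 0) || any(channel_b < 0))
    stop_data("intensities must be non-negative")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  if (!all(dim(mask) == dim(channel_a)))
    stop_data("mask shape differs from channels")
  if (sum(mask) < 2) stop_data("mask must contain at least 2 pixels")
  structure(list(channel_a = channel_a, channel_b = channel_b, mask = mask),
            class = "image_pair")
}

#' Pixelwise Pearson colocalization coefficient
#'
#' Pearson correlation between the two channels over the mask; the standard
#' intensity-correlation colocalization statistic.
#'
#' @param pair an [image_pair()].
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_coloc <- function(pair) {
  a <- pair$channel_a[pair$mask]
  b <- pair$channel_b[pair$mask]
  if (sd(a) == 0 || sd(b) == 0)
    stop_data("constant channel; Pearson coefficient undefined")
  cor(a, b)
}

# Otsu threshold of a channel (values rescaled to [0,1] for EBImage).
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) stop_data("constant channel; Otsu threshold undefined")
  u <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(u, nrow = 1), range = c(0, 1), levels = 256)
  rng[1] + thr * diff(rng)
}

#' Thresholded region-overlap colocalization
#'
#' Formalizes "colocalization assessed by regions": each channel is
#' binarized by a per-channel threshold (Otsu by default, or fixed), and the
#' overlap of the two regions is summarized by the Manders coefficients and
#' the Jaccard index:
#' `M1` = fraction of channel-a intensity inside the overlap relative to
#' channel-a intensity inside region A; `M2` symmetrically for channel b;
#' `jaccard = |A and B| / |A or B|` on pixel counts.
#'
#' @param pair an [image_pair()].
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_thresholds numeric length-2 vector `(threshold_a,
#'   threshold_b)` when `threshold_method = "fixed"`; pixels strictly above
#'   the threshold belong to the region.
#' @return List with `M1`, `M2`, `jaccard`, `threshold_a`, `threshold_b`.
#' @export
region_overlap <- function(pair, threshold_method = c("otsu", "fixed"),
                           fixed_thresholds = NULL) {
  threshold_method <- match.arg(threshold_method)
  a <- pair$channel_a[pair$mask]
  b <- pair$channel_b[pair$mask]
  if (threshold_method == "fixed") {
    if (is.null(fixed_thresholds) || length(fixed_thresholds) != 2)
      stop_config("fixed_thresholds must be a length-2 numeric vector")
    ta <- fixed_thresholds[1]; tb <- fixed_thresholds[2]
  } else {
    ta <- otsu_threshold(a); tb <- otsu_threshold(b)
  }
  A <- a > ta; B <- b > tb
  if (!any(A) || !any(B))
    stop_data("empty thresholded region; overlap coefficients undefined")
  both <- A & B
  list(M1 = sum(a[both]) / sum(a[A]),
       M2 = sum(b[both]) / sum(b[B]),
       jaccard = sum(both) / sum(A | B),
       threshold_a = ta, threshold_b = tb)
}

#' Colocalization trend over a time course
#'
#' Mean and SD of a chosen colocalization statistic over replicate image
#' pairs at each time point.
#'
#' @param pairs list of [image_pair()] objects.
#' @param times numeric vector of time labels (minutes), one per pair.
#' @param statistic `"pearson"`, `"jaccard"`, `"M1"` or `"M2"`.
#' @param ... passed to [region_overlap()] for region statistics.
#' @return data.frame with columns `time_min`, `mean`, `sd`, `n`.
#' @export
coloc_timecourse <- function(pairs, times,
                             statistic = c("pearson", "jaccard", "M1", "M2"),
                             ...) {
  statistic <- match.arg(statistic)
  if (length(pairs) != length(times))
    stop_data("one time label per image pair required")
  vals <- vapply(pairs, function(p) {
    if (statistic == "pearson") pearson_coloc(p)
    else region_overlap(p, ...)[[statistic]]
  }, numeric(1))
  out <- lapply(sort(unique(times)), function(tt) {
    v <- vals[times == tt]
    data.frame(time_min = tt, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0, n = length(v))
  })
  do.call(rbind, out)
}

#' Read a two-channel image pair from single-channel TIFF files
#' @param path_a,path_b paths to single-channel grayscale TIFFs.
#' @param mask optional logical matrix.
#' @return An [image_pair()].
#' @export
read_image_pair <- function(path_a, path_b, mask = NULL) {
  a <- tiff::readTIFF(path_a)
  b <- tiff::readTIFF(path_b)
  if (length(dim(a)) > 2) a <- a[, , 1]
  if (length(dim(b)) > 2) b <- b[, , 1]
  image_pair(a, b, mask)
}

#' Write an image pair as single-channel TIFF files
#'
#' Each channel is rescaled to `[0, 1]` by its maximum and written as a
#' 16-bit grayscale TIFF.
#'
#' @param pair an [image_pair()].
#' @param path_a,path_b output paths.
#' @return Invisibly, `c(path_a, path_b)`.
#' @export
write_image_pair <- function(pair, path_a, path_b) {
  sc <- function(m) if (max(m) > 0) m / max(m) else m
  tiff::writeTIFF(sc(pair$channel_a), path_a, bits.per.sample = 16)
  tiff::writeTIFF(sc(pair$channel_b), path_b, bits.per.sample = 16)
  invisible(c(path_a, path_b))
}
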