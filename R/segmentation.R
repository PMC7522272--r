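#' MBR frame sequence
#'
#' A time-stamped stack of 2-D mean-blur-rate maps: the raw LSFG
#' measurement. Frames are stored as a rows x cols x time numeric array.
#'
#' @param frames 3-D array `[rows, cols, frames]` of MBR values (AU, >= 0).
#' @param frame_rate_hz Acquisition rate (Hz).
#' @param acquisition_s Acquisition duration (s); the frame count must equal
#'   `round(frame_rate_hz * acquisition_s)`.
#' @return Object of class `mbr_frames`.
#' @export
mbr_frames <- function(frames, frame_rate_hz, acquisition_s) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("frames must be a rows x cols x time array", call. = FALSE)
  }
  nt <- dim(frames)[3L]
  if (nt != round(frame_rate_hz * acquisition_s)) {
    stop(sprintf(
      "frame count %d does not match round(frame_rate_hz * acquisition_s) = %d",
      nt, round(frame_rate_hz * acquisition_s)), call. = FALSE)
  }
  if (any(!is.finite(frames)) || any(frames < 0)) {
    stop("MBR values must be finite and >= 0", call. = FALSE)
  }
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 acquisition_s = acquisition_s),
            class = "mbr_frames")
}

#' @export
print.mbr_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<mbr_frames> %dx%d px, %d frames @ %g Hz (%g s)\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$acquisition_s))
  invisible(x)
}

#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle, mimicking the manually placed
#' "rubber band" on the optic nerve head: rows `[row0, row0 + height)`,
#' columns `[col0, col0 + width)`.
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels (> 0).
#' @return Object of class `roi_rect`.
#' @export
roi_rect <- function(row0, col0, height, width) {
  v <- c(row0 = row0, col0 = col0, height = height, width = width)
  if (any(v != round(v)) || row0 < 0 || col0 < 0 || height < 1 || width < 1) {
    stop("ROI must have integer, non-negative origin and positive size",
         call. = FALSE)
  }
  structure(as.list(v), class = "roi_rect")
}

#' Crop a frame sequence to an ROI
#'
#' @param seq An [mbr_frames()] sequence.
#' @param rect An [roi_rect()]; must lie fully inside the frames.
#' @return The cropped [mbr_frames()] (metadata preserved).
#' @export
crop_roi <- function(seq, rect) {
  stopifnot(inherits(seq, "mbr_frames"), inherits(rect, "roi_rect"))
  d <- dim(seq$frames)
  if (rect$row0 + rect$height > d[1L] || rect$col0 + rect$width > d[2L]) {
    stop(sprintf("ROI (%d,%d,%d,%d) exceeds frame bounds %dx%d",
                 rect$row0, rect$col0, rect$height, rect$width, d[1L], d[2L]),
         call. = FALSE)
  }
  rows <- rect$row0 + seq_len(rect$height)
  cols <- rect$col0 + seq_len(rect$width)
  mbr_frames(seq$frames[rows, cols, , drop = FALSE],
             seq$frame_rate_hz, seq$acquisition_s)
}

#' Vessel/tissue region masks
#'
#' Disjoint boolean maps partitioning an ROI into a vessel compartment
#' (bright in the composite MBR map) and a tissue compartment.
#'
#' @param vessel,tissue Logical matrices of identical shape; disjoint,
#'   jointly covering the ROI, neither empty.
#' @return Object of class `region_masks`.
#' @export
region_masks <- function(vessel, tissue) {
  if (!identical(dim(vessel), dim(tissue))) {
    stop("vessel and tissue masks must have identical shape", call. = FALSE)
  }
  if (any(vessel & tissue) || !all(vessel | tissue)) {
    stop("masks must be disjoint and jointly cover the ROI", call. = FALSE)
  }
  if (!any(vessel) || !any(tissue)) {
    stop("degenerate segmentation: empty vessel or tissue compartment",
         call. = FALSE)
  }
  structure(list(vessel = vessel, tissue = tissue), class = "region_masks")
}

#' Segment a composite MBR map into vessel and tissue
#'
#' Thresholds the time-mean MBR map: pixels above the threshold form the
#' vessel compartment (vessels are bright in MBR maps), the rest is tissue.
#' The threshold is either Otsu's between-class-variance maximizer on a
#' 256-bin histogram, or the `(1 - quantile_q)` quantile so that a fraction
#' `quantile_q` of pixels becomes vessel. Segmentation is deterministic and
#' performed once on the composite map, so masks are constant over the
#' acquisition.
#'
#' @param mean_map Numeric matrix (finite, non-constant).
#' @param method `"otsu"` (default) or `"quantile"`.
#' @param quantile_q Vessel pixel fraction for the quantile method
#'   (default 0.2).
#' @return A [region_masks()] with attribute `threshold`.
#' @export
segment_vessel_tissue <- function(mean_map, method = c("otsu", "quantile"),
                                  quantile_q = 0.2) {
  method <- match.arg(method)
  if (!all(is.finite(mean_map))) {
    stop("mean map must be finite", call. = FALSE)
  }
  rng <- range(mean_map)
  if (rng[1L] == rng[2L]) {
    stop("degenerate segmentation: constant map, no threshold separates ",
         "vessel from tissue", call. = FALSE)
  }
  thr <- switch(method,
    otsu = otsu_threshold(as.numeric(mean_map)),
    quantile = stats::quantile(as.numeric(mean_map), 1 - quantile_q,
                               names = FALSE)
  )
  vessel <- mean_map > thr
  if (!any(vessel) || all(vessel)) {
    stop("degenerate segmentation: threshold left one compartment empty",
         call. = FALSE)
  }
  structure(region_masks(vessel, !vessel), threshold = thr)
}

## Otsu's method on a 256-bin histogram: threshold maximizing between-class
## variance; returns the value separating the two classes.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  breaks[which.max(sigma_b) + 1L]
}

#' Region-mean MBR time series
#'
#' Reduces a (cropped) frame sequence to the three region-mean series used
#' by the waveform analysis: MA (overall ROI mean), MV (vessel-mask mean)
#' and MT (tissue-mask mean). By construction MA is the pixel-count-weighted
#' mean of MV and MT at every frame.
#'
#' @param seq An [mbr_frames()] sequence over the ROI.
#' @param masks A [region_masks()] of the same spatial shape.
#' @return Data frame with columns `frame_index` (0-based), `time_s`, `MA`,
#'   `MV`, `MT`.
#' @export
extract_region_waveforms <- function(seq, masks) {
  stopifnot(inherits(seq, "mbr_frames"), inherits(masks, "region_masks"))
  d <- dim(seq$frames)
  if (!identical(d[1:2], dim(masks$vessel))) {
    stop("masks do not match the ROI shape", call. = FALSE)
  }
  nt <- d[3L]
  flat <- matrix(seq$frames, nrow = d[1L] * d[2L], ncol = nt)
  v <- as.vector(masks$vessel)
  mv <- colMeans(flat[v, , drop = FALSE])
  mt <- colMeans(flat[!v, , drop = FALSE])
  ma <- colMeans(flat)
  data.frame(frame_index = seq_len(nt) - 1L,
             time_s = (seq_len(nt) - 1L) / seq$frame_rate_hz,
             MA = ma, MV = mv, MT = mt)
}
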