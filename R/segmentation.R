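#' Segmentation backend configuration
#'
#' The pupil-candidate mask source is pluggable. The `threshold` backend is a
#' classical dark-pupil baseline: under near-infrared illumination the pupil
#' is the darkest region, so pixels with intensity below `intensity_thr` are
#' marked, then a morphological opening (speckle removal) followed by closing
#' (fills corneal-glint holes) with a disc of radius `morph_radius` cleans the
#' mask. The `external_masks` backend passes through masks produced elsewhere
#' (e.g. by a CNN) and read with [read_mask_sequence()].
#'
#' @param backend `"threshold"` or `"external_masks"`.
#' @param intensity_thr intensity cutoff in 0-255 (threshold backend); pixels
#'   strictly below it are pupil candidates.
#' @param morph_radius non-negative disc radius in pixels for opening/closing;
#'   0 disables morphology.
#' @return a `segmenter_config` list.
#' @export
segmenter_config <- function(backend = c("threshold", "external_masks"),
                             intensity_thr = 80, morph_radius = 2) {
  backend <- match.arg(backend)
  if (intensity_thr < 0 || intensity_thr > 255) stop("intensity_thr must be in [0, 255]")
  if (morph_radius < 0) stop("morph_radius must be >= 0")
  structure(list(backend = backend, intensity_thr = intensity_thr,
                 morph_radius = as.integer(morph_radius)),
            class = "segmenter_config")
}

#' Segment one eye frame into a binary pupil-candidate mask
#'
#' @param frame grayscale matrix, intensities 0-255.
#' @param config a [segmenter_config()].
#' @return integer 0/1 matrix of the same shape.
#' @export
#' @examples
#' f <- matrix(200L, 64, 64); f[20:40, 20:40] <- 30L
#' m <- segment_frame(f, segmenter_config(intensity_thr = 80, morph_radius = 0))
#' sum(m)  # the dark block
segment_frame <- function(frame, config = segmenter_config()) {
  if (config$backend != "threshold")
    stop("segment_frame computes masks only for the 'threshold' backend; ",
         "external masks are supplied via recording_from_masks()/read_mask_sequence()")
  if (length(dim(frame)) != 2L) stop("frame must be a 2-D grayscale matrix")
  mask <- matrix(as.integer(frame < config$intensity_thr), nrow(frame), ncol(frame))
  if (config$morph_radius > 0 && any(mask == 1L)) {
    brush <- EBImage::makeBrush(2L * config$morph_radius + 1L, shape = "disc")
    m <- EBImage::closing(EBImage::opening(mask, brush), brush)
    mask <- matrix(as.integer(m > 0), nrow(frame), ncol(frame))
  }
  mask
}

#' Segment every frame of a recording
#'
#' @param recording an `eye_recording` of kind `images` (or `masks`, returned
#'   unchanged — the external-mask pass-through).
#' @param config a [segmenter_config()].
#' @return an `eye_recording` of kind `masks`.
#' @export
segment_recording <- function(recording, config = segmenter_config()) {
  stopifnot(inherits(recording, "eye_recording"))
  if (recording$kind == "masks") return(recording)
  if (recording$kind != "images") stop("cannot segment a recording of kind ", recording$kind)
  masks <- lapply(recording$payload, segment_frame, config = config)
  new_recording("masks", masks, recording$fps)
}

#' Pixel intersection-over-union of two binary masks
#'
#' IoU = |pred AND truth| / |pred OR truth|. When both masks are empty the two
#' agree that there is no pupil (e.g. a closed-eye frame) and the IoU is
#' defined as 1.
#'
#' @param pred,truth 0/1 matrices of identical shape.
#' @return a value in `[0, 1]`.
#' @export
compute_iou <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch between masks")
  p <- pred > 0; t <- truth > 0
  union <- sum(p | t)
  if (union == 0L) return(1)
  sum(p & t) / union
}

#' Mean IoU over a set of mask pairs
#'
#' @param pred,truth lists of 0/1 matrices, pairwise same shape.
#' @return an `iou_report`: list with `per_frame_iou` and `mean_iou`
#'   (unweighted arithmetic mean).
#' @export
compute_miou <- function(pred, truth) {
  if (length(pred) < 1L || length(pred) != length(truth))
    stop("need >= 1 prediction/truth pair of equal count")
  per <- mapply(compute_iou, pred, truth)
  structure(list(per_frame_iou = as.numeric(per), mean_iou = mean(per)),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf("<iou_report> %d frames, mIoU = %.4f (range %.4f-%.4f)\n",
              length(x$per_frame_iou), x$mean_iou,
              min(x$per_frame_iou), max(x$per_frame_iou)))
  invisible(x)
}
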