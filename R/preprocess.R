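#' Mammogram preprocessing
#'
#' Breast segmentation (Otsu threshold + largest connected component),
#' percentile-clip intensity normalization inside the breast footprint,
#' contiguous patch tiling for self-supervised pretraining, and fixed-size
#' tumor-ROI extraction around an annotated lesion center.
#'
#' @name mammo_preprocess
NULL

#' Preprocessing configuration
#'
#' @param patch_size Side length of square SSL patches (px). Desk default 64
#'   (256 at full scale).
#' @param patch_stride Tiling stride; defaults to `patch_size` (contiguous,
#'   non-overlapping tiling).
#' @param min_tissue_fraction Minimum fraction of breast-mask pixels for a
#'   patch to be retained.
#' @param roi_size Side length of the tumor ROI crop (px); 500 at the full
#'   scale of clinical mammograms.
#' @param clip_percentiles Lower/upper intensity percentiles (inside the
#'   mask) clipped before min-max scaling.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(patch_size = 64, patch_stride = patch_size,
                              min_tissue_fraction = 0.25, roi_size = 500,
                              clip_percentiles = c(1, 99)) {
  if (patch_stride > patch_size) stop("patch_stride must be <= patch_size")
  if (roi_size <= 0) stop("roi_size must be positive")
  if (length(clip_percentiles) != 2 || any(clip_percentiles < 0) ||
      any(clip_percentiles > 100) ||
      clip_percentiles[1] >= clip_percentiles[2])
    stop("clip_percentiles must be (low, high) within [0, 100]")
  structure(list(patch_size = patch_size, patch_stride = patch_stride,
                 min_tissue_fraction = min_tissue_fraction,
                 roi_size = roi_size, clip_percentiles = clip_percentiles),
            class = "preprocess_config")
}

#' Segment the breast footprint
#'
#' Global Otsu threshold followed by retention of the largest connected
#' foreground component.
#'
#' @param image 2-D numeric matrix (row = y), any intensity range.
#' @return Logical matrix of the same shape.
#' @export
segment_breast <- function(image) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  rng <- range(image)
  if (rng[1] == rng[2]) stop("constant image cannot be segmented")
  scaled <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1))
  fg <- scaled > thr
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(fg * 1)))))
  if (max(lab) == 0) stop("no foreground component found")
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Normalize intensities inside the breast mask
#'
#' Intensities inside the mask are clipped to the configured percentiles
#' (computed inside the mask), min-max scaled to `[0, 1]`; pixels outside
#' the mask are set to 0. A constant-inside-mask image maps to all zeros.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix from [segment_breast()].
#' @param config A [preprocess_config()].
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalize_intensity <- function(image, mask, config = preprocess_config()) {
  if (!any(mask)) stop("empty mask")
  vals <- image[mask]
  q <- stats::quantile(vals, config$clip_percentiles / 100, names = FALSE)
  out <- matrix(0, nrow(image), ncol(image))
  if (q[2] > q[1]) {
    out[mask] <- (clamp(image[mask], q[1], q[2]) - q[1]) / (q[2] - q[1])
  }
  out
}

#' Tile contiguous patches from a normalized image
#'
#' Lays a stride grid of `patch_size` squares fully inside the image
#' (0-based top-left coordinates) and retains patches whose breast-mask
#' fraction is at least `min_tissue_fraction`.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix (same shape).
#' @param config A [preprocess_config()].
#' @return A list with `patches` (list of `patch_size` x `patch_size`
#'   matrices for retained cells), and `grid`, a `data.frame` with `row`,
#'   `col` (0-based top-left), `tissue_fraction` and `retained` for every
#'   grid cell.
#' @export
tile_patches <- function(image, mask, config = preprocess_config()) {
  ps <- config$patch_size; st <- config$patch_stride
  h <- nrow(image); w <- ncol(image)
  if (ps > h || ps > w) {
    warning("patch_size exceeds image dimensions; no patches")
    return(list(patches = list(),
                grid = data.frame(row = integer(0), col = integer(0),
                                  tissue_fraction = numeric(0),
                                  retained = logical(0))))
  }
  rows <- seq(0, h - ps, by = st)
  cols <- seq(0, w - ps, by = st)
  grid <- expand.grid(row = rows, col = cols)
  grid$tissue_fraction <- mapply(function(r, c)
    mean(mask[(r + 1):(r + ps), (c + 1):(c + ps)]), grid$row, grid$col)
  grid$retained <- grid$tissue_fraction >= config$min_tissue_fraction
  patches <- lapply(which(grid$retained), function(i) {
    r <- grid$row[i]; c <- grid$col[i]
    image[(r + 1):(r + ps), (c + 1):(c + ps)]
  })
  list(patches = patches, grid = grid)
}

#' Extract a fixed-size ROI crop around an annotated center
#'
#' Returns exactly `roi_size` x `roi_size` pixels centered on
#' `(center_y, center_x)` (0-based); parts of the window outside the image
#' are zero-padded, so border centers keep the output shape.
#'
#' @param image Numeric matrix.
#' @param annotation A list/row with `center_x` (column) and `center_y`
#'   (row), 0-based, inside the image.
#' @param roi_size Side length in pixels.
#' @return `roi_size` x `roi_size` numeric matrix.
#' @export
extract_roi <- function(image, annotation, roi_size = 500) {
  cy <- annotation$center_y; cx <- annotation$center_x
  h <- nrow(image); w <- ncol(image)
  if (cy < 0 || cy >= h || cx < 0 || cx >= w)
    stop("annotation center outside image")
  lo <- floor(roi_size / 2)
  r0 <- cy - lo; c0 <- cx - lo          # 0-based top-left of the window
  out <- matrix(0, roi_size, roi_size)
  rs <- max(0, r0):min(h - 1, r0 + roi_size - 1)
  cs <- max(0, c0):min(w - 1, c0 + roi_size - 1)
  if (length(rs) > 0 && length(cs) > 0) {
    out[rs - r0 + 1, cs - c0 + 1] <- image[rs + 1, cs + 1]
  }
  out
}
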