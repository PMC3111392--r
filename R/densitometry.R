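#' @title Chromogenic densitometry: channel inversion
#'
#' @description The red channel of an 8-bit RGB brightfield image carries
#' the least counterstain noise; inverting it (255 - x) makes stained
#' nuclei bright on a dark background so that fluorescence-style
#' segmentation can be applied.
#'
#' @param rgb 8-bit RGB image as a `height x width x 3` array (0..255).
#' @return Inverted red channel as a numeric matrix.
#' @export
red_channel_inverted <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] < 3) {
    stop("input must be an RGB array (height x width x 3)", call. = FALSE)
  }
  255 - rgb[, , 1]
}

#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background of a grayscale image by grayscale
#' morphological opening with a disk structuring element (the
#' morphological equivalent of rolling-ball subtraction) and subtracts it,
#' clamping at zero. Compensates for lighting and shading variation before
#' thresholding. The estimate is unreliable within one ball radius of the
#' image border (structuring-element truncation).
#'
#' @param gray Numeric matrix (intensities, any range >= 0).
#' @param radius_px Ball radius in pixels; must exceed the object radius
#'   scale so that objects are removed from the background estimate.
#' @return Background-subtracted matrix (>= 0).
#' @export
subtract_background <- function(gray, radius_px) {
  if (!is.matrix(gray)) stop("`gray` must be a matrix", call. = FALSE)
  if (!is.numeric(radius_px) || radius_px <= 0) {
    stop("`radius_px` must be > 0", call. = FALSE)
  }
  top <- max(gray, 255)
  brush <- EBImage::makeBrush(2 * round(radius_px) + 1, shape = "disc")
  bg <- EBImage::opening(EBImage::Image(gray / top), brush)
  pmax(gray - as.matrix(bg) * top, 0)
}

#' Otsu threshold over the 256-bin intensity histogram
#'
#' Finds the integer cut point `t` in 0..254 that maximizes the
#' between-class variance of the two classes \{pixels <= t\} and
#' \{pixels > t\} on the 8-bit histogram (values binned by `floor` after
#' clamping to 0..255). When several cut points tie, their mean is
#' returned, so a clean two-level image yields a threshold strictly
#' between the two modes. Foreground is defined as pixels strictly above
#' the threshold.
#'
#' @param gray Numeric matrix with at least two distinct values.
#' @return Threshold intensity (numeric scalar).
#' @export
otsu_threshold <- function(gray) {
  v <- floor(pmin(pmax(as.numeric(gray), 0), 255))
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) {
    stop("degenerate histogram: image has a single intensity level",
         call. = FALSE)
  }
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)[1:255]
  s0 <- cumsum(counts * lev)[1:255]
  w1 <- n - w0
  s1 <- sum(counts * lev) - s0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[ok] <- (w0[ok] / n) * (w1[ok] / n) *
    (s0[ok] / w0[ok] - s1[ok] / w1[ok])^2
  best <- max(bcv)
  ties <- which(bcv >= best - abs(best) * 1e-12)
  mean(lev[ties])  # cut points are 0..254 (index k = cut at level k-1)
}

#' Segment stained nuclei and measure per-object absorbance
#'
#' Splits a binary foreground mask into objects with a distance-transform
#' watershed (touching nuclei are separated at the basin boundaries of the
#' distance map), discards objects below a minimum area, and measures each
#' object's mean intensity on the *original* (non-inverted) red channel,
#' from which the absorbance density is computed against the image's
#' illumination constant. Watershed splitting relabels foreground pixels
#' but never removes them.
#'
#' @param foreground Logical (or 0/1) matrix: the thresholded mask.
#' @param red_original Numeric matrix: the untouched red channel used for
#'   intensity measurement.
#' @param illumination Illumination intensity constant shared by the image
#'   batch.
#' @param min_area Minimum object area in pixels (default 20).
#' @param tolerance Watershed minimum height between object maxima
#'   (default 1, suppressing noise-driven oversegmentation).
#' @return Object of class `nuclei_segmentation`: a list with `objects`
#'   (`data.frame`: `object_id`, `area`, `row`, `col` centroid 0-based,
#'   `mean_intensity`, `od`) and `labels` (integer matrix of object ids,
#'   0 = background).
#' @export
segment_nuclei <- function(foreground, red_original, illumination,
                           min_area = 20, tolerance = 1) {
  fg <- matrix(as.numeric(foreground != 0), nrow(foreground),
               ncol(foreground))
  if (!all(dim(fg) == dim(red_original))) {
    stop("mask and red channel dimensions differ", call. = FALSE)
  }
  empty <- data.frame(object_id = integer(), area = integer(),
                      row = numeric(), col = numeric(),
                      mean_intensity = numeric(), od = numeric())
  if (!any(fg > 0)) {
    return(structure(list(objects = empty, labels = matrix(0L, nrow(fg),
                                                           ncol(fg))),
                     class = "nuclei_segmentation"))
  }
  dm <- EBImage::distmap(EBImage::Image(fg))
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(fg), ncol(fg))
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  rows <- lapply(ids, function(id) {
    px <- which(lab == id)
    if (length(px) < min_area) return(NULL)
    mi <- mean(red_original[px])
    data.frame(object_id = id, area = length(px),
               row = mean((px - 1) %% nrow(lab)),
               col = mean((px - 1) %/% nrow(lab)),
               mean_intensity = mi,
               od = absorbance_density(mi, illumination))
  })
  objects <- do.call(rbind, rows)
  if (is.null(objects)) objects <- empty
  # relabel discarded small objects to background in the label image
  keep <- objects$object_id
  lab[!(lab %in% keep)] <- 0L
  structure(list(objects = objects, labels = lab),
            class = "nuclei_segmentation")
}

#' Absorbance (optical) density of a transmitted-light measurement
#'
#' \eqn{OD = \log_{10}(I_0) - \log_{10}(I)} with illumination \eqn{I_0}
#' and measured mean intensity \eqn{I}; base 10 follows the optical
#' density convention (any base scales all ODs proportionally and leaves
#' group comparisons unchanged). Can be negative for objects brighter
#' than the illumination estimate.
#'
#' @param mean_intensity Measured mean intensity (> 0); vectorized.
#' @param illumination Illumination intensity (> 0).
#' @return Absorbance density (dimensionless).
#' @examples
#' absorbance_density(25.5, 255)  # 1.0
#' @export
absorbance_density <- function(mean_intensity, illumination) {
  if (any(mean_intensity <= 0) || any(illumination <= 0)) {
    stop("intensities must be positive to form an optical density",
         call. = FALSE)
  }
  log10(illumination) - log10(mean_intensity)
}

#' Two-group comparison by pooled-variance Student t-test
#'
#' Unpaired two-sided Student t-test with pooled variance and
#' `n_a + n_b - 2` degrees of freedom, as used for object optical
#' densities, region intensities and band ratios. Degenerate inputs with
#' zero pooled variance give `p = 1` when the means are equal and `p = 0`
#' (with a warning) when they differ.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `statistic` (t), `df`, `p_value`, and the two group
#'   means.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, df = length(a) + length(b) - 2,
                  p_value = 1, mean_a = mean(a), mean_b = mean(b)))
    }
    warning("zero pooled variance with unequal means; p reported as 0")
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_value = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Background-corrected region intensity
#'
#' Specific intensity of an anatomical region or blot band: the raw mean
#' intensity minus the background mean, in arbitrary units (negative
#' values are preserved, not clamped). Region masks are user-supplied;
#' anatomical delineation is not automated.
#'
#' @param region_mean Mean intensity over the region of interest.
#' @param background_mean Mean intensity over the background region.
#' @param region Region label (e.g. `"AVPV"`, `"ARC_dorsal_fibers"`).
#' @return A one-row `data.frame`: `region`, `raw_mean`,
#'   `background_mean`, `specific_intensity`.
#' @export
region_specific_intensity <- function(region_mean, background_mean,
                                      region = "region") {
  data.frame(region = region, raw_mean = region_mean,
             background_mean = background_mean,
             specific_intensity = region_mean - background_mean,
             stringsAsFactors = FALSE)
}

#' Ratio of a target band to its loading-control band
#'
#' Per-sample normalization of a western-blot band intensity by its
#' loading-control band (e.g. a 39 kDa target over beta-tubulin); the
#' ratio is invariant to a common exposure scale factor.
#'
#' @param target Target band intensities, one per sample.
#' @param control Loading-control band intensities (> 0), same length.
#' @param sample Optional sample labels for error messages.
#' @return Numeric vector of ratios.
#' @export
band_ratio <- function(target, control, sample = NULL) {
  if (length(target) != length(control)) {
    stop("target and control must have the same length", call. = FALSE)
  }
  sample <- sample %||% as.character(seq_along(target))
  bad <- which(control <= 0)
  if (length(bad)) {
    stop("non-positive control band intensity for sample(s): ",
         paste(sample[bad], collapse = ", "), call. = FALSE)
  }
  target / control
}

#' Estimate the batch illumination constant
#'
#' Modal red-channel intensity (most frequent 8-bit level), i.e. the
#' dominant background level of a brightfield image. Used when no
#' explicit illumination constant is configured; the same constant should
#' be applied to every image of a batch acquired under identical
#' conditions.
#'
#' @param red Red-channel matrix (0..255).
#' @return Modal intensity (numeric scalar).
#' @export
estimate_illumination <- function(red) {
  v <- round(pmin(pmax(as.numeric(red), 0), 255))
  counts <- tabulate(v + 1L, nbins = 256L)
  which.max(counts) - 1
}

#' Full in situ hybridization densitometry pipeline
#'
#' Runs the complete per-image chain: red channel extraction and
#' inversion, background subtraction, Otsu thresholding (foreground
#' strictly above threshold on the inverted, background-subtracted
#' image), watershed segmentation of touching nuclei, and per-object
#' absorbance density measured on the original red channel.
#'
#' @param rgb 8-bit RGB array (`height x width x 3`).
#' @param illumination Illumination constant; `NULL` to estimate it as
#'   the modal red intensity via [estimate_illumination()].
#' @param ball_radius Background-subtraction ball radius, pixels.
#' @param min_area Minimum object area, pixels.
#' @return List with `objects` (per-object `data.frame`), `labels`,
#'   `threshold` (Otsu cut on the processed image), and `illumination`.
#' @seealso [generate_stained_image()] for ground-truth fixtures.
#' @export
quantify_ish <- function(rgb, illumination = NULL, ball_radius = 15,
                         min_area = 20) {
  red <- rgb[, , 1]
  illumination <- illumination %||% estimate_illumination(red)
  inv <- red_channel_inverted(rgb)
  proc <- subtract_background(inv, ball_radius)
  thr <- otsu_threshold(proc)
  seg <- segment_nuclei(proc > thr, red, illumination,
                        min_area = min_area)
  list(objects = seg$objects, labels = seg$labels, threshold = thr,
       illumination = illumination)
}
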