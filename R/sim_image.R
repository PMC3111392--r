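#' Simulate a chromogenic stained-section image with planted nuclei
#'
#' Builds an 8-bit RGB brightfield-style image: the red channel carries a
#' uniform illumination background on which circular "nuclei" absorb light
#' according to a planted absorbance (optical) density, so that each
#' object's noise-free red mean is `illumination * 10^(-od)`. Green and
#' blue channels carry counterstain-like constants and are ignored by the
#' densitometry pipeline. Gaussian pixel noise is added and the result is
#' rounded and clipped to 0..255 (with a warning if clipping occurred).
#'
#' Object centres are placed at least `2 * object_radius_px + 2` pixels
#' apart, except for an optional fraction of deliberately touching pairs
#' whose centres sit 1.5 radii apart (to exercise watershed splitting).
#'
#' @param n_objects Number of nuclei to plant.
#' @param illumination Background red intensity in (0, 255].
#' @param object_od Absorbance density per object; scalar or vector of
#'   length `n_objects`.
#' @param object_radius_px Object radius, pixels.
#' @param noise_sd Gaussian pixel noise SD, intensity units.
#' @param dim Image height and width, pixels.
#' @param touching_pairs Number of planted touching pairs (each pair
#'   consumes two of `n_objects`).
#' @param seed Integer seed.
#' @return A list with `image` (height x width x 3 integer array, 0..255)
#'   and `truth` (`data.frame` of object centres, radii and planted `od`,
#'   plus the illumination as an attribute).
#' @examples
#' sim <- generate_stained_image(10, illumination = 220, object_od = 0.5,
#'                               seed = 1)
#' dim(sim$image)
#' @export
generate_stained_image <- function(n_objects, illumination = 220,
                                   object_od = 0.5, object_radius_px = 6,
                                   noise_sd = 2, dim = c(192, 192),
                                   touching_pairs = 0, seed = 1) {
  if (illumination <= 0 || illumination > 255) {
    stop("`illumination` must be in (0, 255]", call. = FALSE)
  }
  if (n_objects < 0) stop("`n_objects` must be >= 0", call. = FALSE)
  if (2 * touching_pairs > n_objects) {
    stop("touching_pairs consume 2 objects each", call. = FALSE)
  }
  od <- rep_len(object_od, max(n_objects, 1L))
  r <- object_radius_px
  h <- dim[1]; w <- dim[2]

  with_seed(seed, {
    # rejection-sample centres with a minimum separation
    min_sep <- 2 * r + 2
    centres <- matrix(numeric(0), ncol = 2)
    pair_of <- integer(0)
    n_single <- n_objects - 2 * touching_pairs
    place <- function(centres, min_d) {
      for (try in seq_len(10000)) {
        cand <- c(stats::runif(1, r + 2, h - r - 2),
                  stats::runif(1, r + 2, w - r - 2))
        if (!nrow(centres) ||
            all(sqrt(rowSums(sweep(centres, 2, cand)^2)) >= min_d)) {
          return(cand)
        }
      }
      stop("could not place objects: image too crowded", call. = FALSE)
    }
    for (i in seq_len(n_single)) {
      centres <- rbind(centres, place(centres, min_sep))
      pair_of <- c(pair_of, 0L)
    }
    for (p in seq_len(touching_pairs)) {
      # first member needs clearance for its partner too
      c1 <- place(centres, min_sep + 1.5 * r)
      ang <- stats::runif(1, 0, 2 * pi)
      c2 <- c1 + 1.5 * r * c(cos(ang), sin(ang))
      c2 <- pmin(pmax(c2, r + 2), c(h, w) - r - 2)
      centres <- rbind(centres, c1, c2)
      pair_of <- c(pair_of, p, p)
    }

    red <- matrix(illumination, h, w)
    rr <- row(red); cc <- col(red)
    for (i in seq_len(n_objects)) {
      inside <- (rr - centres[i, 1])^2 + (cc - centres[i, 2])^2 <= r^2
      red[inside] <- illumination * 10^(-od[i])
    }
    if (noise_sd > 0) {
      red <- red + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    }
    red <- round(red)
    clipped <- sum(red < 0 | red > 255)
    if (clipped > 0) {
      warning(sprintf("%d pixel(s) clipped to the 0..255 range", clipped))
      red <- pmin(pmax(red, 0), 255)
    }
    img <- array(0L, c(h, w, 3))
    img[, , 1] <- as.integer(red)
    img[, , 2] <- 180L  # counterstain-like constants
    img[, , 3] <- 200L

    truth <- if (n_objects > 0) {
      data.frame(object = seq_len(n_objects),
                 row = centres[, 1], col = centres[, 2],
                 radius = r, od = od[seq_len(n_objects)],
                 touching_pair = pair_of)
    } else {
      data.frame(object = integer(), row = numeric(), col = numeric(),
                 radius = numeric(), od = numeric(),
                 touching_pair = integer())
    }
    attr(truth, "illumination") <- illumination
    list(image = img, truth = truth)
  })
}
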