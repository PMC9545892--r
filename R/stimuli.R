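## Stimulus construction and Fourier-domain filtering.
##
## Filters are specified as real gain rasters over the unshifted FFT
## coordinate grid. Gains depend only on the orientation or radial frequency
## of each Fourier coordinate, which makes them Hermitian-symmetric
## (gain(u, v) == gain(-u, -v)) so filtered images stay real-valued.

# FFT coordinate grids for an n x n raster: horizontal/vertical frequency in
# cycles/degree, radial frequency, and Fourier-plane angle in degrees.
# Matrix rows index vertical (y) frequency, columns horizontal (x).
fourier_grid <- function(n, pixels_per_degree) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  f <- k / n * pixels_per_degree          # cycles/degree along one axis
  fx <- matrix(f, n, n, byrow = TRUE)
  fy <- matrix(f, n, n, byrow = FALSE)
  list(fx = fx, fy = fy,
       fr = sqrt(fx^2 + fy^2),
       theta = (atan2(fy, fx) * 180 / pi) %% 180)
}

# Average a gain raster with its value at the negated Fourier coordinate
# ((u, v) -> (-u, -v) modulo the raster). Radial gains already satisfy this;
# orientation gains need it only on the Nyquist row/column of even-sized
# rasters, where +n/2 and -n/2 coincide and the raw angle map is one-sided.
hermitian_symmetrize <- function(m) {
  conj_idx <- function(n) c(1L, rev(seq_len(n - 1L) + 1L))
  (m + m[conj_idx(nrow(m)), conj_idx(ncol(m))]) / 2
}

new_fourier_filter <- function(transfer, kind, center, fwhm_or_cutoff,
                               pixels_per_degree) {
  structure(list(transfer = transfer, kind = kind, center = center,
                 fwhm_or_cutoff = fwhm_or_cutoff,
                 pixels_per_degree = pixels_per_degree),
            class = "fourier_filter")
}

#' @export
print.fourier_filter <- function(x, ...) {
  cat(sprintf("<fourier_filter> %s, center/cutoff = %g, fwhm/cutoff = %g, %dx%d\n",
              x$kind, x$center, x$fwhm_or_cutoff,
              nrow(x$transfer), ncol(x$transfer)))
  invisible(x)
}

# Wrapped-Gaussian profile over the 180-degree-periodic orientation circle,
# normalised to peak gain 1 at zero angular distance. `d` in degrees.
wrapped_gaussian_180 <- function(d, fwhm_deg, k_range = -3:3) {
  sigma <- fwhm_deg / (2 * sqrt(2 * log(2)))
  s <- function(x) {
    acc <- 0
    for (k in k_range) acc <- acc + exp(-(x + 180 * k)^2 / (2 * sigma^2))
    acc
  }
  s(d) / s(0)
}

#' Orientation-pass Fourier filter
#'
#' Gain at each Fourier coordinate depends only on its orientation in the
#' Fourier plane: a Gaussian over angular distance from `center_deg`, wrapped
#' on the 180-degree-periodic orientation circle, with peak gain 1 at the
#' centre and gain 0.5 at `center_deg +/- fwhm_deg / 2`. The DC term keeps
#' gain 1 so mean luminance survives until the explicit rescale in
#' [apply_filter()].
#'
#' Note the convention: `center_deg` is the angle of the Fourier wave vector.
#' Image-domain stripes/edges are perpendicular to their wave vector, so a
#' filter that *preserves horizontal image structure* has its Fourier centre
#' at 90 degrees (see [stimulus_filters()]).
#'
#' @param center_deg Centre orientation in degrees, interpreted modulo 180.
#' @param fwhm_deg Full width at half maximum in degrees, in (0, 180). The
#'   wide-angle cut-off used for the face/house stimuli is 75.
#' @param raster_shape Integer pair (or single integer) giving the raster
#'   size; must be square.
#' @param pixels_per_degree Raster calibration (carried along for metadata;
#'   orientation gains do not depend on it).
#' @return A `"fourier_filter"` with a gain raster in FFT (unshifted) layout.
#' @export
orientation_filter <- function(center_deg, fwhm_deg, raster_shape,
                               pixels_per_degree) {
  if (!(fwhm_deg > 0 && fwhm_deg < 180))
    stop("`fwhm_deg` must lie in (0, 180)")
  n <- check_square_shape(raster_shape)
  center_deg <- center_deg %% 180
  g <- fourier_grid(n, pixels_per_degree)
  d <- (g$theta - center_deg + 90) %% 180 - 90   # wrapped to [-90, 90)
  transfer <- hermitian_symmetrize(wrapped_gaussian_180(d, fwhm_deg))
  transfer[1, 1] <- 1                            # DC passes
  new_fourier_filter(transfer, "orientation", center_deg, fwhm_deg,
                     pixels_per_degree)
}

#' Spatial-frequency Fourier filter
#'
#' Gain depends only on radial frequency in cycles/degree. The low-pass form
#' is a Gaussian centred on DC with gain 0.5 at `cutoff_cpd` (the cut-off is
#' the half-maximum point); the high-pass form is one minus that Gaussian, so
#' its DC gain is 0 and its gain at the cut-off is again 0.5. Cut-offs of 2
#' (low) and 6 (high) cycles/degree are the values used for the face/house
#' stimulus set.
#'
#' @param kind `"low"` or `"high"`.
#' @param cutoff_cpd Half-maximum frequency in cycles/degree; must be below
#'   the Nyquist frequency `pixels_per_degree / 2`.
#' @inheritParams orientation_filter
#' @return A `"fourier_filter"`.
#' @export
frequency_filter <- function(kind = c("low", "high"), cutoff_cpd,
                             raster_shape, pixels_per_degree) {
  kind <- match.arg(kind)
  n <- check_square_shape(raster_shape)
  nyq <- pixels_per_degree / 2
  if (!(cutoff_cpd > 0 && cutoff_cpd < nyq))
    stop(sprintf("`cutoff_cpd` must lie in (0, Nyquist = %g c/deg)", nyq))
  g <- fourier_grid(n, pixels_per_degree)
  sigma <- cutoff_cpd / sqrt(2 * log(2))         # gain 0.5 at the cut-off
  lp <- exp(-g$fr^2 / (2 * sigma^2))
  transfer <- if (kind == "low") lp else 1 - lp
  new_fourier_filter(transfer, "frequency", cutoff_cpd, cutoff_cpd,
                     pixels_per_degree)
}

check_square_shape <- function(raster_shape) {
  if (length(raster_shape) == 1L) raster_shape <- rep(raster_shape, 2L)
  if (length(raster_shape) != 2L || raster_shape[1] != raster_shape[2])
    stop("raster must be square")
  as.integer(raster_shape[1])
}

#' Apply a Fourier filter to an image
#'
#' Multiplies the image spectrum by the filter's gain raster, inverts the
#' transform, then (by default) rescales the global mean luminance to exactly
#' mid-grey (0.5) by an additive shift and clips to \[0, 1\]. The additive
#' rescale preserves contrast structure; clipping happens after it. The
#' imaginary residue of the inverse transform must be below `1e-8` (it is, for
#' any Hermitian-symmetric filter) or an error is raised.
#'
#' @param img A [vt_image()].
#' @param filt A `"fourier_filter"` whose transfer raster matches `img`.
#' @param rescale Rescale mean luminance to 0.5? Disable to study the raw
#'   linear-filter output (e.g. for cascade identities).
#' @param clip Clip to \[0, 1\] after rescaling?
#' @param label Filter token stored on the result.
#' @return A filtered [vt_image()].
#' @export
apply_filter <- function(img, filt, rescale = TRUE, clip = TRUE,
                         label = NULL) {
  stopifnot(inherits(img, "vt_image"), inherits(filt, "fourier_filter"))
  if (!all(dim(img$pixels) == dim(filt$transfer)))
    stop("image and filter raster shapes differ")
  n2 <- length(img$pixels)
  out_c <- fft(fft(img$pixels) * filt$transfer, inverse = TRUE) / n2
  resid <- max(abs(Im(out_c)))
  if (resid > 1e-8)
    stop(sprintf("imaginary residue %.3g exceeds 1e-8; filter not Hermitian?",
                 resid))
  out <- Re(out_c)
  if (rescale) out <- out - mean(out) + 0.5
  if (clip) out <- pmin(pmax(out, 0), 1)
  vt_image(out, img$pixels_per_degree, img$category,
           if (is.null(label)) img$filter_label else label)
}

#' The four texture-manipulating stimulus filters
#'
#' Builds the filter set used throughout: low-pass (cut-off 2 c/deg),
#' high-pass (cut-off 6 c/deg), and horizontal- and vertical-pass orientation
#' filters (wrapped Gaussians, FWHM 75 degrees). Orientation names refer to
#' the *image-domain* structure preserved: the horizontal-pass filter centres
#' its Fourier gain on 90 degrees, the vertical-pass on 0 degrees.
#'
#' @param raster_shape Raster size (square).
#' @param pixels_per_degree Calibration in pixels/degree.
#' @param low_cutoff_cpd,high_cutoff_cpd Half-maximum frequencies.
#' @param orientation_fwhm_deg Orientation FWHM in degrees.
#' @return Named list of `"fourier_filter"` objects: `low`, `high`,
#'   `horizontal`, `vertical`.
#' @export
stimulus_filters <- function(raster_shape, pixels_per_degree,
                             low_cutoff_cpd = 2, high_cutoff_cpd = 6,
                             orientation_fwhm_deg = 75) {
  list(
    low = frequency_filter("low", low_cutoff_cpd, raster_shape,
                           pixels_per_degree),
    high = frequency_filter("high", high_cutoff_cpd, raster_shape,
                            pixels_per_degree),
    horizontal = orientation_filter(90, orientation_fwhm_deg, raster_shape,
                                    pixels_per_degree),
    vertical = orientation_filter(0, orientation_fwhm_deg, raster_shape,
                                  pixels_per_degree))
}

# --- synthetic stimulus generator ------------------------------------------

soft_edge <- function(x, width) 1 / (1 + exp(-x / width))

#' Generate a synthetic face- or house-like image
#'
#' Deterministic-per-seed stand-in for photographic stimuli, drawn on a
#' uniform mid-grey background subtending `size_px / pixels_per_degree`
#' degrees. The two categories differ systematically in spatial envelope:
#' faces are a centred soft-edged ellipse with internal blob features (eyes,
#' mouth) plus fine surface grain; houses are a rectilinear arrangement of
#' sharp-edged rectangles (body, windows, door) whose edges concentrate
#' energy at horizontal/vertical orientations and high spatial frequencies.
#' Position, size, tone and feature placement jitter with the seed, so
#' within-category images are similar but not identical.
#'
#' @param category `"face"` or `"house"`.
#' @param size_px Raster side in pixels (at least 64).
#' @param seed Integer seed; the same seed gives a bit-identical raster.
#' @param pixels_per_degree Calibration; the default maps the raster onto a
#'   10-degree stimulus.
#' @return A [vt_image()] with `category` set and `filter_label = "none"`.
#' @export
make_synthetic_image <- function(category = c("face", "house"), size_px = 256L,
                                 seed = 0L,
                                 pixels_per_degree = size_px / 10) {
  category <- match.arg(category)
  size_px <- as.integer(size_px)
  if (size_px < 64L) stop("`size_px` must be at least 64")
  px <- withr::with_seed(as.integer(seed), {
    n <- size_px
    ax <- seq(-1, 1, length.out = n)
    x <- matrix(ax, n, n, byrow = TRUE)
    y <- matrix(ax, n, n, byrow = FALSE)
    img <- matrix(0.5, n, n)
    if (category == "face") {
      cx <- runif(1, -0.06, 0.06); cy <- runif(1, -0.06, 0.06)
      rx <- runif(1, 0.50, 0.60); ry <- runif(1, 0.64, 0.76)
      tone <- runif(1, 0.60, 0.68)
      e <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2
      mask <- soft_edge(1 - e, 0.03)
      feat <- matrix(0, n, n)
      ey <- cy - ry * runif(1, 0.28, 0.36)
      ex <- rx * runif(1, 0.34, 0.44)
      es <- runif(1, 0.06, 0.09)
      for (s in c(-1, 1))
        feat <- feat - 0.30 * exp(-(((x - cx - s * ex) / es)^2 +
                                    ((y - ey) / es)^2) / 2)
      my <- cy + ry * runif(1, 0.38, 0.50)
      feat <- feat - 0.25 * exp(-(((x - cx) / (rx * 0.45))^2 +
                                  ((y - my) / 0.05)^2) / 2)
      feat <- feat - 0.10 * exp(-(((x - cx) / 0.05)^2 +
                                  ((y - cy - 0.08) / 0.16)^2) / 2)
      for (b in seq_len(6)) {
        bx <- cx + runif(1, -0.5, 0.5) * rx
        by <- cy + runif(1, -0.5, 0.5) * ry
        feat <- feat + runif(1, -0.08, 0.08) *
          exp(-(((x - bx)^2 + (y - by)^2)) / (2 * runif(1, 0.05, 0.15)^2))
      }
      grain <- matrix(rnorm(n * n, 0, 0.025), n, n)
      img <- 0.5 + mask * (tone - 0.5 + feat + grain)
    } else {
      bx0 <- runif(1, -0.80, -0.70); bx1 <- runif(1, 0.70, 0.80)
      by0 <- runif(1, -0.72, -0.62); by1 <- runif(1, 0.62, 0.72)
      tone <- runif(1, 0.58, 0.66)
      body <- (x >= bx0 & x <= bx1 & y >= by0 & y <= by1)
      img[body] <- tone
      nwx <- 3L; nwy <- sample(2:3, 1)
      wx <- seq(bx0 + 0.18, bx1 - 0.18, length.out = nwx)
      wy <- seq(by0 + 0.22, by1 - 0.34, length.out = nwy)
      ww <- runif(1, 0.10, 0.14); wh <- runif(1, 0.12, 0.16)
      wtone <- runif(1, 0.25, 0.35)
      for (i in seq_len(nwx)) for (j in seq_len(nwy)) {
        win <- (abs(x - wx[i]) <= ww & abs(y - wy[j]) <= wh)
        img[win] <- wtone
        bar <- (abs(x - wx[i]) <= 0.015 | abs(y - wy[j]) <= 0.015) & win
        img[bar] <- tone + 0.1
      }
      dx <- runif(1, -0.25, 0.25)
      door <- (abs(x - dx) <= 0.10 & y >= by1 - runif(1, 0.30, 0.38) & y <= by1)
      img[door] <- runif(1, 0.30, 0.40)
      edge <- (body & (abs(x - bx0) <= 0.012 | abs(x - bx1) <= 0.012 |
                       abs(y - by0) <= 0.012 | abs(y - by1) <= 0.012))
      img[edge] <- 0.2
      grain <- matrix(rnorm(n * n, 0, 0.02), n, n)
      img[body] <- img[body] + grain[body]
    }
    pmin(pmax(img, 0), 1)
  })
  vt_image(px, pixels_per_degree, category, "none")
}

#' Generate a labelled, filtered stimulus set
#'
#' Draws `n_per_category` synthetic images per category (seeded by a
#' documented counter scheme: image `i` of category `c` uses seed
#' `base_seed + 1000 * (c - 1) + i`) and passes each through the four
#' stimulus filters, yielding `2 * n_per_category * length(filters)` filtered
#' images plus the unfiltered originals.
#'
#' @param n_per_category Images per category.
#' @param size_px Raster side in pixels.
#' @param base_seed Base of the per-image seed counter.
#' @param filters Filter set; defaults to [stimulus_filters()] at this raster.
#' @param pixels_per_degree Calibration (default: 10-degree stimulus).
#' @return A list with `images` (list of filtered [vt_image()]s),
#'   `originals`, and `info` (data frame: `id`, `category`, `filter`,
#'   `image_index`).
#' @export
generate_stimulus_set <- function(n_per_category = 48L, size_px = 256L,
                                  base_seed = 0L, filters = NULL,
                                  pixels_per_degree = size_px / 10) {
  cats <- c("face", "house")
  if (is.null(filters))
    filters <- stimulus_filters(size_px, pixels_per_degree)
  originals <- list(); images <- list()
  info <- data.frame(id = character(), category = character(),
                     filter = character(), image_index = integer(),
                     stringsAsFactors = FALSE)
  for (ci in seq_along(cats)) {
    for (i in seq_len(n_per_category)) {
      img <- make_synthetic_image(cats[ci], size_px,
                                  seed = base_seed + 1000L * (ci - 1L) + i,
                                  pixels_per_degree = pixels_per_degree)
      originals[[paste(cats[ci], i, sep = "_")]] <- img
      for (fn in names(filters)) {
        fimg <- apply_filter(img, filters[[fn]], label = fn)
        id <- paste(cats[ci], fn, i, sep = "_")
        images[[id]] <- fimg
        info <- rbind(info, data.frame(id = id, category = cats[ci],
                                       filter = fn, image_index = i,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  list(images = images, originals = originals, info = info)
}
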