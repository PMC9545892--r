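## Shape and texture GIST descriptors.
##
## Both descriptors start from the same measurement: a bank of 64 log-Gabor
## filters (8 orientations x 8 spatial frequencies) applied in the Fourier
## domain, each yielding a non-negative energy map (the magnitude of the
## quadrature-pair / analytic response), which is then windowed into an 8 x 8
## grid of means. The shape variant averages across filters and keeps the
## grid (spatial layout of energy, insensitive to spectral content); the
## texture variant averages across grid cells and keeps the filters
## (spectral content, insensitive to spatial layout).

#' Build a log-Gabor filter bank
#'
#' Filters are defined directly in the Fourier domain as the product of a
#' Gaussian in log radial frequency (1-octave FWHM by default, zero gain at
#' DC) and a single-lobed Gaussian in Fourier-plane angle (period 360
#' degrees). Because each filter occupies only one half-plane, applying it to
#' a real image yields a complex analytic response whose magnitude is the
#' quadrature-pair energy used by [filter_energy_maps()].
#'
#' Centre frequencies are log-spaced between `f_min_cpd` and
#' `f_max_frac * Nyquist`; orientations are evenly spaced over 180 degrees
#' starting at 0. Filters are stored frequency-major: filter
#' `(f, o)` sits at index `(f - 1) * n_ori + o`.
#'
#' @param raster_shape Raster size (square).
#' @param pixels_per_degree Calibration in pixels/degree.
#' @param n_ori,n_freq Number of orientation and frequency bands (8 x 8 gives
#'   the standard 64-filter bank).
#' @param f_min_cpd Lowest centre frequency in cycles/degree.
#' @param f_max_frac Highest centre frequency as a fraction of Nyquist.
#' @param logf_fwhm_octaves Radial bandwidth: FWHM in octaves of the
#'   log-frequency Gaussian.
#' @param ori_fwhm_deg Orientation bandwidth (FWHM, degrees); defaults to the
#'   orientation spacing `180 / n_ori`.
#' @return A `"gabor_bank"`: list with `filters` (list of gain rasters in FFT
#'   layout), `orientations_deg`, `frequencies_cpd`, `index` (data frame
#'   mapping filter index to orientation/frequency), `raster_shape`,
#'   `pixels_per_degree`.
#' @export
build_gabor_bank <- function(raster_shape, pixels_per_degree, n_ori = 8L,
                             n_freq = 8L, f_min_cpd = 0.25,
                             f_max_frac = 0.8, logf_fwhm_octaves = 1,
                             ori_fwhm_deg = 180 / n_ori) {
  if (n_ori < 1L || n_freq < 1L) stop("need at least one band per axis")
  n <- check_square_shape(raster_shape)
  nyq <- pixels_per_degree / 2
  f_max <- f_max_frac * nyq
  if (f_max >= nyq) stop("highest centre frequency must be below Nyquist")
  if (f_min_cpd <= 0 || f_min_cpd > f_max)
    stop("invalid centre-frequency range")
  freqs <- exp(seq(log(f_min_cpd), log(f_max), length.out = n_freq))
  oris <- (seq_len(n_ori) - 1L) * 180 / n_ori
  g <- fourier_grid(n, pixels_per_degree)
  theta360 <- atan2(g$fy, g$fx) * 180 / pi       # full-circle angle
  sig_r <- (logf_fwhm_octaves * log(2)) / (2 * sqrt(2 * log(2)))
  sig_o <- ori_fwhm_deg / (2 * sqrt(2 * log(2)))
  logfr <- suppressWarnings(log(g$fr))           # -Inf at DC -> gain 0
  filters <- vector("list", n_ori * n_freq)
  index <- data.frame(filter = integer(), frequency_index = integer(),
                      orientation_index = integer())
  k <- 0L
  for (fi in seq_len(n_freq)) {
    radial <- exp(-(logfr - log(freqs[fi]))^2 / (2 * sig_r^2))
    radial[1, 1] <- 0
    for (oi in seq_len(n_ori)) {
      d <- (theta360 - oris[oi] + 180) %% 360 - 180   # single lobe
      k <- k + 1L
      filters[[k]] <- radial * exp(-d^2 / (2 * sig_o^2))
      index <- rbind(index, data.frame(filter = k, frequency_index = fi,
                                       orientation_index = oi))
    }
  }
  structure(list(filters = filters, orientations_deg = oris,
                 frequencies_cpd = freqs, index = index, raster_shape = n,
                 pixels_per_degree = pixels_per_degree),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank> %d filters (%d ori x %d freq), %g-%g c/deg, %dpx\n",
              length(x$filters), length(x$orientations_deg),
              length(x$frequencies_cpd), min(x$frequencies_cpd),
              max(x$frequencies_cpd), x$raster_shape))
  invisible(x)
}

#' Quadrature-pair energy maps for every filter in a bank
#'
#' Applies each Fourier-domain log-Gabor to the image and takes the magnitude
#' of the complex (analytic) response, so every map is a non-negative energy
#' raster. The filters have zero DC gain, which makes the maps invariant to
#' adding a constant luminance offset.
#'
#' @param img A [vt_image()] whose raster matches the bank.
#' @param bank A [build_gabor_bank()].
#' @return List of `length(bank$filters)` non-negative matrices.
#' @export
filter_energy_maps <- function(img, bank) {
  stopifnot(inherits(img, "vt_image"), inherits(bank, "gabor_bank"))
  if (nrow(img$pixels) != bank$raster_shape)
    stop("image raster does not match the bank")
  n2 <- length(img$pixels)
  spec <- fft(img$pixels)
  lapply(bank$filters, function(g)
    Mod(fft(spec * g, inverse = TRUE) / n2))
}

#' Average a raster over a square grid of windows
#'
#' Cell `(i, j)` is the mean of the pixels in the corresponding window. The
#' raster side must be divisible by `grid`; optionally the excess rows and
#' columns can be cropped. Flattening elsewhere in the package is row-major:
#' cell `(i, j)` of the grid maps to vector position `(i - 1) * grid + j`.
#'
#' @param map Numeric matrix.
#' @param grid Grid side (default 8).
#' @param remainder `"error"` (default) or `"crop"` when the side is not
#'   divisible by `grid`.
#' @return `grid` x `grid` matrix of window means.
#' @export
grid_average <- function(map, grid = 8L, remainder = c("error", "crop")) {
  remainder <- match.arg(remainder)
  stopifnot(is.matrix(map), is.numeric(map))
  grid <- as.integer(grid)
  if (nrow(map) < grid || ncol(map) < grid)
    stop("raster smaller than the grid")
  trim <- function(k) (k %/% grid) * grid
  if (nrow(map) %% grid || ncol(map) %% grid) {
    if (remainder == "error")
      stop("raster side not divisible by `grid` (use remainder = \"crop\")")
    map <- map[seq_len(trim(nrow(map))), seq_len(trim(ncol(map))), drop = FALSE]
  }
  rfac <- (seq_len(nrow(map)) - 1L) %/% (nrow(map) %/% grid)
  cfac <- (seq_len(ncol(map)) - 1L) %/% (ncol(map) %/% grid)
  sums <- t(rowsum(t(rowsum(map, rfac)), cfac))
  dimnames(sums) <- NULL
  sums / ((nrow(map) / grid) * (ncol(map) / grid))
}

new_gist_vector <- function(values, variant, source_image_id = NA_character_) {
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(as.numeric(values), variant = variant,
            source_image_id = source_image_id, class = "gist_vector")
}

#' @export
print.gist_vector <- function(x, ...) {
  cat(sprintf("<gist_vector> %s, length %d, mean %.4g\n",
              attr(x, "variant"), length(x), mean(unclass(x))))
  invisible(x)
}

gist_grids <- function(img, bank, grid) {
  lapply(filter_energy_maps(img, bank), grid_average, grid = grid)
}

#' Shape-GIST descriptor
#'
#' Averages the windowed energy grids across all filters in the bank, keeping
#' the spatial grid: the result describes *where* contrast energy sits in the
#' image (the spatial envelope) while aggregating away its orientation and
#' spatial-frequency content. The 8 x 8 grid is flattened row-major into a
#' 64-value vector.
#'
#' @inheritParams filter_energy_maps
#' @param grid Spatial grid side (default 8, giving 64 values).
#' @param source_image_id Optional identifier stored on the vector.
#' @return A `"gist_vector"` with `variant = "shape"`.
#' @export
shape_gist <- function(img, bank, grid = 8L, source_image_id = NA_character_) {
  grids <- gist_grids(img, bank, grid)
  g <- Reduce(`+`, grids) / length(grids)
  new_gist_vector(as.vector(t(g)), "shape", source_image_id)
}

#' Texture-GIST descriptor
#'
#' Averages each filter's windowed energy grid over its cells, keeping one
#' value per filter: the result describes *which* orientations and spatial
#' frequencies carry energy, irrespective of where. Values follow the bank's
#' frequency-major filter order ([build_gabor_bank()]), giving 64 values for
#' the standard bank.
#'
#' @inheritParams shape_gist
#' @return A `"gist_vector"` with `variant = "texture"`.
#' @export
texture_gist <- function(img, bank, grid = 8L,
                         source_image_id = NA_character_) {
  grids <- gist_grids(img, bank, grid)
  new_gist_vector(vapply(grids, mean, numeric(1)), "texture", source_image_id)
}

#' Descriptor table for a stimulus set
#'
#' Computes one GIST variant for every image in a [generate_stimulus_set()]
#' result (or any named list of [vt_image()]s with a matching info frame).
#'
#' @param stimulus_set Output of [generate_stimulus_set()].
#' @param bank A [build_gabor_bank()] matching the images' raster.
#' @param variant `"shape"` or `"texture"`.
#' @return A data frame: `id`, `category`, `filter`, then `v1..v64`.
#' @export
gist_table <- function(stimulus_set, bank, variant = c("shape", "texture")) {
  variant <- match.arg(variant)
  fun <- if (variant == "shape") shape_gist else texture_gist
  rows <- lapply(seq_len(nrow(stimulus_set$info)), function(i) {
    id <- stimulus_set$info$id[i]
    v <- fun(stimulus_set$images[[id]], bank, source_image_id = id)
    as.numeric(v)
  })
  vals <- do.call(rbind, rows)
  colnames(vals) <- paste0("v", seq_len(ncol(vals)))
  cbind(stimulus_set$info[, c("id", "category", "filter")],
        as.data.frame(vals))
}
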