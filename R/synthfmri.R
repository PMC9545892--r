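## Synthetic fMRI data generators.
##
## Two forward models are provided, mirroring the two experimental designs:
## (1) per-participant condition voxel patterns whose between-condition
## correlation structure is a controllable mixture of the shape- and
## texture-GIST model matrices plus subject noise, and (2) block-design BOLD
## time series in which stimulus repetition suppresses the neural response
## and attribute changes release it, passed through a single-gamma HRF.

#' Project a symmetric matrix to the nearest valid correlation structure
#'
#' Eigenvalues below zero are clipped at zero and the diagonal is
#' renormalised to 1. Mixtures whose smallest eigenvalue is below
#' `-fail_tol` are considered genuinely indefinite and raise an error rather
#' than being silently repaired.
#'
#' @param m Symmetric matrix with unit diagonal intent.
#' @param fail_tol Most negative eigenvalue tolerated before failing.
#' @return A positive semi-definite matrix with unit diagonal.
#' @export
nearest_psd_corr <- function(m, fail_tol = 0.1) {
  stopifnot(isSymmetric(unname(m)))
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -fail_tol)
    stop(sprintf("mixture is indefinite (min eigenvalue %.3g); not repairable",
                 min(e$values)))
  if (min(e$values) < 0) {
    warning("mixture not PSD; clipping negative eigenvalues")
    v <- pmax(e$values, 0)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
  }
  m
}

new_subject_patterns <- function(subject_id, patterns, roi_id = "sim") {
  stopifnot(is.matrix(patterns), all(is.finite(patterns)),
            !is.null(rownames(patterns)))
  structure(list(subject_id = subject_id, patterns = patterns,
                 condition_labels = rownames(patterns), roi_id = roi_id),
            class = "subject_patterns")
}

#' @export
print.subject_patterns <- function(x, ...) {
  cat(sprintf("<subject_patterns> %s/%s: %d conditions x %d voxels\n",
              x$subject_id, x$roi_id, nrow(x$patterns), ncol(x$patterns)))
  invisible(x)
}

#' Simulate per-participant condition voxel patterns
#'
#' Draws one group-level pattern per condition such that between-condition
#' pattern correlations equal the target mixture
#' `beta_shape * R_shape + beta_texture * R_texture` (off-diagonal; the
#' diagonal is set to 1 and the mixture is PSD-repaired via
#' [nearest_psd_corr()]). The construction applies a matrix square root of
#' the target correlation to standard-normal voxel noise that is first
#' empirically whitened across conditions, so the group patterns' sample
#' correlation matrix matches the target exactly at any voxel count (not
#' just asymptotically); without this, the finite-voxel sampling error of
#' the single shared group pattern would act as a fixed effect common to
#' every participant. Each subject's patterns are the group patterns plus
#' Gaussian noise of standard deviation `subject_noise_sd`, drawn as
#' finite-population random effects: the across-participant mean of the
#' noise is removed, so the simulated sample's average pattern equals the
#' group pattern and leave-one-out group estimates contain no noise
#' component shared by all participants (which would otherwise act as a
#' spurious fixed effect in group statistics).
#'
#' @param shape_rsm,texture_rsm Model `"rsm"`s over the same condition
#'   labels (e.g. one scan's 4 conditions).
#' @param beta_shape,beta_texture Ground-truth mixture weights.
#' @param n_subjects Number of participants (20 matches the multivariate
#'   experiment's sample).
#' @param n_voxels Voxels per pattern.
#' @param subject_noise_sd Subject noise SD; 0 makes all subjects identical
#'   to the group patterns.
#' @param seed Integer seed; same configuration and seed give identical
#'   output.
#' @return List of `n_subjects` `"subject_patterns"` objects, with the target
#'   correlation matrix attached as attribute `"target"` and the group
#'   patterns as `"group_patterns"`.
#' @export
simulate_exp1_patterns <- function(shape_rsm, texture_rsm, beta_shape,
                                   beta_texture, n_subjects = 20L,
                                   n_voxels = 500L, subject_noise_sd = 1,
                                   seed = 1L) {
  stopifnot(inherits(shape_rsm, "rsm"), inherits(texture_rsm, "rsm"),
            identical(shape_rsm$labels, texture_rsm$labels),
            subject_noise_sd >= 0)
  labels <- shape_rsm$labels
  k <- length(labels)
  target <- beta_shape * shape_rsm$matrix + beta_texture * texture_rsm$matrix
  diag(target) <- 1
  target <- nearest_psd_corr((target + t(target)) / 2)
  e <- eigen(target, symmetric = TRUE)
  sqrtm <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  if (n_voxels <= k)
    stop("`n_voxels` must exceed the number of conditions")
  withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(k * n_voxels), k, n_voxels)
    z <- z - rowMeans(z)                        # centre each condition row
    cz <- z %*% t(z) / (n_voxels - 1)
    z <- solve(t(chol(cz)), z)                  # exact empirical whitening
    group <- sqrtm %*% z
    rownames(group) <- labels
    noise <- array(0, c(k, n_voxels, n_subjects))
    if (subject_noise_sd > 0 && n_subjects > 1L) {
      noise[] <- rnorm(k * n_voxels * n_subjects, 0, subject_noise_sd)
      noise <- sweep(noise, c(1, 2), apply(noise, c(1, 2), mean))
    }
    subjects <- lapply(seq_len(n_subjects), function(s)
      new_subject_patterns(sprintf("sub%02d", s), group + noise[, , s]))
    attr(subjects, "target") <- target
    attr(subjects, "group_patterns") <- group
    subjects
  })
}

#' Generate one adaptation-scan block design
#'
#' One scan: 2 categories x 3 sequence types (`no_change`, `shape_change`,
#' `texture_change`) x 6 blocks = 36 blocks of 6 images (pairs of images
#' repeated three times), i.e. 216 image events. Images appear for 800 ms
#' with a 200 ms inter-stimulus interval, followed by a 9 s fixation epoch
#' (a 15 s block cycle). The fixation cross after 36 of the 216 images is
#' marked as a green attention target at seeded-random positions, and the
#' block order is shuffled per seed.
#'
#' @param seed Integer seed.
#' @param filter_type The scan's filter class (`"frequency"` or
#'   `"orientation"`), recorded on every block.
#' @param n_blocks_per_cond Blocks per category-by-sequence cell (default 6).
#' @param images_per_block Images per block (default 6).
#' @return An `"exp2_design"`: list with `blocks` (data frame `block`,
#'   `category`, `filter_type`, `sequence`), timing constants (`stim_s` 0.8,
#'   `isi_s` 0.2, `block_s`, `fixation_s` 9, `tr_s` 3), `green_targets`
#'   (sorted indices into the scan's image-event stream), and `n_events`.
#' @export
generate_exp2_design <- function(seed = 1L,
                                 filter_type = c("frequency", "orientation"),
                                 n_blocks_per_cond = 6L,
                                 images_per_block = 6L) {
  filter_type <- match.arg(filter_type)
  cells <- expand.grid(category = c("face", "house"),
                       sequence = c("no_change", "shape_change",
                                    "texture_change"),
                       stringsAsFactors = FALSE)
  blocks <- cells[rep(seq_len(nrow(cells)), each = n_blocks_per_cond), ]
  n_events <- nrow(blocks) * images_per_block
  n_targets <- round(n_events / 6)
  withr::with_seed(as.integer(seed), {
    blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
    targets <- sort(sample.int(n_events, n_targets))
  })
  rownames(blocks) <- NULL
  blocks <- data.frame(block = seq_len(nrow(blocks)),
                       category = blocks$category,
                       filter_type = filter_type,
                       sequence = blocks$sequence,
                       stringsAsFactors = FALSE)
  structure(list(blocks = blocks, images_per_block = images_per_block,
                 stim_s = 0.8, isi_s = 0.2,
                 block_s = images_per_block * 1.0, fixation_s = 9,
                 tr_s = 3, green_targets = targets, n_events = n_events),
            class = "exp2_design")
}

#' @export
print.exp2_design <- function(x, ...) {
  cat(sprintf(
    "<exp2_design> %d blocks x %d images = %d events, %d green targets (%s)\n",
    nrow(x$blocks), x$images_per_block, x$n_events,
    length(x$green_targets), x$blocks$filter_type[1]))
  invisible(x)
}

#' Default neural-pool parameters
#'
#' A pool is a population of neurons with a preferred category, flags for
#' whether its representation distinguishes shape and texture changes, gains
#' for preferred and non-preferred stimuli, and a repetition-suppression
#' factor. Defaults describe a strongly category-selective pool sensitive to
#' both attributes: preferred-stimulus responses adapt to 60% on exact
#' repeats and any detected attribute change fully releases adaptation,
#' while non-preferred stimuli drive the pool only weakly (5% gain), so
#' their sequence effects are negligible.
#'
#' @param preferred_category `"face"` (an FFA-like pool) or `"house"`
#'   (PPA-like).
#' @param sensitive_shape,sensitive_texture Does the pool detect exemplar
#'   (shape) / filter (texture) changes?
#' @param gain_pref,gain_nonpref Response gains (arbitrary units, > 0).
#' @param adapt_factor Multiplicative suppression of an immediately repeated
#'   identical stimulus, in \[0, 1\].
#' @return A named list of pool parameters.
#' @export
neural_pool <- function(preferred_category = c("face", "house"),
                        sensitive_shape = TRUE, sensitive_texture = TRUE,
                        gain_pref = 1, gain_nonpref = 0.05,
                        adapt_factor = 0.6) {
  preferred_category <- match.arg(preferred_category)
  stopifnot(gain_pref > 0, gain_nonpref > 0,
            adapt_factor >= 0, adapt_factor <= 1)
  list(preferred_category = preferred_category,
       sensitive_shape = sensitive_shape,
       sensitive_texture = sensitive_texture,
       gain_pref = gain_pref, gain_nonpref = gain_nonpref,
       adapt_factor = adapt_factor)
}

#' Per-stimulus response amplitudes of a neural pool within one block
#'
#' Blocks present three repeats of an image pair. The first stimulus of each
#' pair responds at the pool's category gain; the second responds at
#' `gain * adapt_factor` if the pool treats the pair as an exact repeat
#' (always in `no_change` blocks; in `shape_change` blocks only if the pool
#' is insensitive to shape; in `texture_change` blocks only if insensitive
#' to texture), and at full gain otherwise (release from adaptation).
#'
#' @param category Block category (`"face"` or `"house"`).
#' @param sequence_type `"no_change"`, `"shape_change"` or
#'   `"texture_change"`.
#' @param pool A [neural_pool()].
#' @param images_per_block Number of stimuli (default 6 = 3 pairs).
#' @return Numeric vector of `images_per_block` response amplitudes.
#' @export
neural_block_response <- function(category, sequence_type, pool,
                                  images_per_block = 6L) {
  sequence_type <- match.arg(sequence_type,
                             c("no_change", "shape_change", "texture_change"))
  gain <- if (category == pool$preferred_category) pool$gain_pref
          else pool$gain_nonpref
  pair_identical <- switch(sequence_type,
    no_change = TRUE,
    shape_change = !pool$sensitive_shape,
    texture_change = !pool$sensitive_texture)
  second <- gain * if (pair_identical) pool$adapt_factor else 1
  rep(c(gain, second), length.out = images_per_block)
}

#' Single-gamma haemodynamic response function
#'
#' Gamma-shaped impulse response with its mode at `peak_s` seconds and scale
#' `dispersion_s`, amplitude-normalised so the peak value is 1.
#'
#' @param t Time in seconds (vector).
#' @param peak_s Time-to-peak (default 6 s).
#' @param dispersion_s Gamma scale parameter (default 0.9 s).
#' @return HRF values at `t`.
#' @export
hrf_single_gamma <- function(t, peak_s = 6, dispersion_s = 0.9) {
  shape <- 1 + peak_s / dispersion_s
  h <- dgamma(t, shape = shape, scale = dispersion_s)
  h / dgamma(peak_s, shape = shape, scale = dispersion_s)
}

new_roi_timeseries <- function(samples, tr_s, block_onsets, blocks,
                               subject_id = "sim", roi_id = "sim",
                               psc = FALSE) {
  stopifnot(all(is.finite(samples)))
  structure(list(subject_id = subject_id, roi_id = roi_id,
                 samples = as.numeric(samples), tr_s = tr_s,
                 block_onsets = as.integer(block_onsets), blocks = blocks,
                 psc = psc),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s/%s: %d TRs (TR = %gs), %d blocks%s\n",
              x$subject_id, x$roi_id, length(x$samples), x$tr_s,
              length(x$block_onsets),
              if (x$psc) ", percent signal change" else ""))
  invisible(x)
}

#' Simulate an ROI-mean BOLD time series for one adaptation scan
#'
#' Per-stimulus neural amplitudes from [neural_block_response()] are placed
#' as impulses at the stimulus onsets of every block, convolved with a
#' single-gamma HRF on a fine time grid, sampled at the TR, and combined
#' with a baseline offset and seeded white noise. Samples are indexed so
#' that sample `i` is the signal at time `i * tr_s`; `block_onsets` holds the
#' 1-based index of each block's first TR, so TR 3 of a block falls 9 s
#' after block onset.
#'
#' @param design An [generate_exp2_design()].
#' @param pool A [neural_pool()].
#' @param noise_sd White-noise SD in raw signal units per TR.
#' @param seed Integer seed (noise only; the design carries its own seed).
#' @param hrf_peak_s,hrf_dispersion_s HRF parameters.
#' @param baseline Baseline signal level (raw units).
#' @param scale Multiplier from neural amplitude to raw signal units.
#' @param dt_s Fine-grid resolution for the convolution.
#' @param lead_in_s,lead_out_s Fixation before the first block and padding
#'   after the last block's fixation (the default 9 s tail leaves room for a
#'   6-TR epoch that overlaps the following cycle).
#' @param subject_id,roi_id Tokens recorded on the series.
#' @return An `"roi_timeseries"`.
#' @export
simulate_exp2_timeseries <- function(design, pool, noise_sd = 1, seed = 1L,
                                     hrf_peak_s = 6, hrf_dispersion_s = 0.9,
                                     baseline = 100, scale = 1, dt_s = 0.1,
                                     lead_in_s = 9, lead_out_s = 9,
                                     subject_id = "sim", roi_id = "sim") {
  stopifnot(inherits(design, "exp2_design"))
  cycle_s <- design$block_s + design$fixation_s
  nb <- nrow(design$blocks)
  total_s <- lead_in_s + nb * cycle_s + lead_out_s
  nt_fine <- round(total_s / dt_s) + 1L   # grid point k is time (k - 1) * dt
  imp <- numeric(nt_fine)
  soa <- design$stim_s + design$isi_s
  for (b in seq_len(nb)) {
    onset <- lead_in_s + (b - 1) * cycle_s
    amps <- neural_block_response(design$blocks$category[b],
                                  design$blocks$sequence[b], pool,
                                  design$images_per_block)
    for (j in seq_len(design$images_per_block)) {
      idx <- round((onset + (j - 1) * soa) / dt_s) + 1L
      imp[idx] <- imp[idx] + amps[j]
    }
  }
  h <- hrf_single_gamma(seq(0, 32, by = dt_s), hrf_peak_s, hrf_dispersion_s)
  sig_fine <- convolve(imp, rev(h), type = "open")[seq_len(nt_fine)]
  tr <- design$tr_s
  n_tr <- floor(total_s / tr)
  sample_idx <- round((seq_len(n_tr) * tr) / dt_s) + 1L
  sig <- sig_fine[sample_idx]
  noise <- withr::with_seed(as.integer(seed), rnorm(n_tr, 0, noise_sd))
  onsets_tr <- (lead_in_s + (seq_len(nb) - 1) * cycle_s) / tr + 1
  if (any(abs(onsets_tr - round(onsets_tr)) > 1e-9))
    stop("block onsets must fall on TR boundaries")
  new_roi_timeseries(baseline + scale * sig + noise, tr,
                     round(onsets_tr), design$blocks,
                     subject_id = subject_id, roi_id = roi_id)
}

#' Simulate a 3D statistical (z) map
#'
#' Sum of isotropic Gaussian bumps plus seeded white noise, used to exercise
#' peak finding and flood-fill ROI definition.
#'
#' @param dim Integer triple, volume dimensions.
#' @param peaks Matrix with one row per bump (voxel coordinates), or a
#'   length-3 vector for a single bump.
#' @param peak_height Bump amplitude (z units).
#' @param smoothness_vox Gaussian SD of each bump, in voxels.
#' @param noise_sd Background noise SD (z units).
#' @param seed Integer seed.
#' @return 3D numeric array.
#' @export
simulate_zmap <- function(dim = c(24L, 24L, 24L), peaks, peak_height = 8,
                          smoothness_vox = 2, noise_sd = 0, seed = 1L) {
  dim <- as.integer(dim)
  if (is.null(nrow(peaks))) peaks <- matrix(peaks, nrow = 1)
  if (any(peaks < 1) || any(t(peaks) > dim))
    stop("peaks must lie inside the volume")
  co <- arrayInd(seq_len(prod(dim)), dim)
  z <- numeric(prod(dim))
  for (p in seq_len(nrow(peaks))) {
    d2 <- (co[, 1] - peaks[p, 1])^2 + (co[, 2] - peaks[p, 2])^2 +
      (co[, 3] - peaks[p, 3])^2
    z <- z + peak_height * exp(-d2 / (2 * smoothness_vox^2))
  }
  if (noise_sd > 0)
    z <- z + withr::with_seed(as.integer(seed),
                              rnorm(prod(dim), 0, noise_sd))
  array(z, dim)
}
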