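## Study-level wrappers tying the generators to the analyses: these are what
## the parameter-recovery checks and worked examples run.

#' Condition labels for one scan
#'
#' The frequency scan presents `face`/`house` crossed with the `high`/`low`
#' spatial-frequency filters; the orientation scan crosses the categories
#' with the `horizontal`/`vertical` filters.
#'
#' @param filter_type `"frequency"` or `"orientation"`.
#' @return Character vector of 4 condition tokens (`category_filter`).
#' @export
scan_conditions <- function(filter_type = c("frequency", "orientation")) {
  filter_type <- match.arg(filter_type)
  filters <- if (filter_type == "frequency") c("high", "low")
             else c("horizontal", "vertical")
  as.vector(outer(c("face", "house"), filters, paste, sep = "_"))
}

#' Simulate and analyse one multivariate (pattern) experiment
#'
#' Generates per-participant condition patterns whose correlation structure
#' is a ground-truth mixture of the shape and texture model matrices
#' ([simulate_exp1_patterns()]) and runs the full multivariate pipeline
#' ([run_exp1_analysis()]) on them.
#'
#' @inheritParams simulate_exp1_patterns
#' @param include_diagonal Passed to [rsm_regression()].
#' @return As [run_exp1_analysis()], plus a `ground_truth` element.
#' @export
simulate_exp1_study <- function(shape_rsm, texture_rsm, beta_shape,
                                beta_texture, n_subjects = 20L,
                                n_voxels = 500L, subject_noise_sd = 1,
                                seed = 1L, include_diagonal = FALSE) {
  subjects <- simulate_exp1_patterns(shape_rsm, texture_rsm, beta_shape,
                                     beta_texture, n_subjects, n_voxels,
                                     subject_noise_sd, seed)
  out <- run_exp1_analysis(subjects, shape_rsm, texture_rsm,
                           include_diagonal = include_diagonal)
  out$ground_truth <- c(beta_shape = beta_shape, beta_texture = beta_texture)
  out
}

#' Simulate a full adaptation study
#'
#' Simulates `n_subjects` participants, each scanned twice (frequency- and
#' orientation-filtered stimuli) with two recorded ROIs: an FFA-like
#' face-preferring pool and a PPA-like house-preferring pool, both sensitive
#' to shape and texture changes. Each subject and scan draws its own block
#' order; per-subject multiplicative gain variability (log-normal, SD
#' `subject_gain_sd` on the log scale) models stable individual differences
#' in response amplitude. Returns the TR-3 peak table ready for
#' [rm_anova()] and [pairwise_contrasts()].
#'
#' @param n_subjects Number of participants (24 matches the adaptation
#'   experiment's sample).
#' @param pools Named list of [neural_pool()]s, one per ROI.
#' @param filter_types Scans to simulate.
#' @param noise_sd Per-TR white-noise SD in raw signal units (baseline 100,
#'   so 1 is about 1% of baseline).
#' @param subject_gain_sd SD of per-subject log gain multipliers.
#' @param seed Integer master seed; subject/scan seeds are derived from it.
#' @param ... Further arguments to [simulate_exp2_timeseries()].
#' @return Data frame from [adaptation_peak_table()].
#' @export
simulate_exp2_study <- function(n_subjects = 24L,
                                pools = list(FFA = neural_pool("face"),
                                             PPA = neural_pool("house")),
                                filter_types = c("frequency", "orientation"),
                                noise_sd = 1, subject_gain_sd = 0.15,
                                seed = 1L, ...) {
  seed <- as.integer(seed)
  gains <- withr::with_seed(seed, exp(rnorm(n_subjects, 0, subject_gain_sd)))
  series <- list()
  for (s in seq_len(n_subjects)) {
    for (fi in seq_along(filter_types)) {
      ft <- filter_types[fi]
      design <- generate_exp2_design(
        seed = (seed * 7919L + s * 131L + fi) %% .Machine$integer.max,
        filter_type = ft)
      for (rn in names(pools)) {
        pool <- pools[[rn]]
        pool$gain_pref <- pool$gain_pref * gains[s]
        pool$gain_nonpref <- pool$gain_nonpref * gains[s]
        series[[length(series) + 1L]] <- simulate_exp2_timeseries(
          design, pool, noise_sd = noise_sd,
          seed = (seed * 104729L + s * 1009L + fi * 17L +
                    match(rn, names(pools))) %% .Machine$integer.max,
          subject_id = sprintf("sub%02d", s), roi_id = rn, ...)
      }
    }
  }
  adaptation_peak_table(series)
}

#' Check the category-selective adaptation pattern
#'
#' Evaluates, on a contrast table from [pairwise_contrasts()], the full
#' qualitative pattern expected of category-selective regions sensitive to
#' both attributes: for each ROI's preferred category, the no-change
#' condition is significantly lower than both the shape-change and the
#' texture-change condition while the two change conditions do not differ;
#' and the non-preferred category shows no significant sequence effects.
#' Significance is Benjamini-Hochberg-adjusted p < `alpha`.
#'
#' @param contrasts A `"contrast_table"`.
#' @param preferred Named character vector mapping ROI to preferred
#'   category, e.g. `c(FFA = "face", PPA = "house")`.
#' @param alpha Significance level (default 0.05).
#' @return Logical scalar, with a `detail` attribute (per-ROI logical
#'   vector of the sub-checks).
#' @export
check_adaptation_pattern <- function(contrasts,
                                     preferred = c(FFA = "face",
                                                   PPA = "house"),
                                     alpha = 0.05) {
  get_row <- function(r, cc, a, b) {
    hit <- contrasts$roi == r & contrasts$category == cc &
      ((contrasts$level_a == a & contrasts$level_b == b) |
         (contrasts$level_a == b & contrasts$level_b == a))
    stopifnot(sum(hit) == 1L)
    row <- contrasts[hit, ]
    if (row$level_a != a) {    # orient so mean_diff = mean(a) - mean(b)
      row$mean_diff <- -row$mean_diff
      row$t <- -row$t
    }
    row
  }
  detail <- c()
  for (r in names(preferred)) {
    pref <- preferred[[r]]
    nonpref <- setdiff(unique(contrasts$category), pref)
    ns <- get_row(r, pref, "no_change", "shape_change")
    nt <- get_row(r, pref, "no_change", "texture_change")
    st <- get_row(r, pref, "shape_change", "texture_change")
    detail[paste0(r, ".adapt_shape")] <- ns$p_adj < alpha & ns$mean_diff < 0
    detail[paste0(r, ".adapt_texture")] <- nt$p_adj < alpha & nt$mean_diff < 0
    detail[paste0(r, ".equal_release")] <- !(st$p_adj < alpha)
    np <- contrasts[contrasts$roi == r & contrasts$category %in% nonpref, ]
    detail[paste0(r, ".nonpref_null")] <- all(!(np$p_adj < alpha))
  }
  structure(all(detail), detail = detail)
}

#' One adaptation-study replicate: simulate, analyse, check the pattern
#'
#' @inheritParams simulate_exp2_study
#' @inheritParams check_adaptation_pattern
#' @return As [check_adaptation_pattern()], with the contrast table attached
#'   as attribute `"contrasts"`.
#' @export
exp2_replicate <- function(seed, n_subjects = 24L,
                           pools = list(FFA = neural_pool("face"),
                                        PPA = neural_pool("house")),
                           noise_sd = 1, subject_gain_sd = 0.15,
                           alpha = 0.05, ...) {
  tab <- simulate_exp2_study(n_subjects = n_subjects, pools = pools,
                             noise_sd = noise_sd,
                             subject_gain_sd = subject_gain_sd,
                             seed = seed, ...)
  ctr <- pairwise_contrasts(tab)
  preferred <- vapply(pools, `[[`, character(1), "preferred_category")
  ok <- check_adaptation_pattern(ctr, preferred, alpha)
  attr(ok, "contrasts") <- ctr
  ok
}

#' Demo stimulus set, Gabor bank and model RSMs at reduced scale
#'
#' Builds a small synthetic face/house stimulus set (default 6 images per
#' category at 128 px, i.e. 12.8 px/deg for a 10-degree stimulus), the
#' 64-filter log-Gabor bank at that raster, and the shape/texture model
#' similarity matrices over the 8 `category_filter` conditions. Scaled down
#' from the full 48-images-per-category set purely for speed; the structure
#' is identical.
#'
#' @param n_per_category Images per category (default 6).
#' @param size_px Raster side (default 128).
#' @param base_seed Seed for the image counter scheme.
#' @return List: `set` ([generate_stimulus_set()] output), `bank`, `shape`,
#'   `texture` (model `"rsm"`s), and the descriptor tables.
#' @export
demo_model_rsms <- function(n_per_category = 6L, size_px = 128L,
                            base_seed = 0L) {
  set <- generate_stimulus_set(n_per_category, size_px,
                               base_seed = base_seed)
  bank <- build_gabor_bank(size_px, size_px / 10)
  mods <- model_rsms(set, bank)
  c(list(set = set, bank = bank), mods)
}
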