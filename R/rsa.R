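## Correlation-based MVPA with leave-one-participant-out cross-validation
## and representational-similarity regression.

#' Voxel-wise normalisation of condition patterns
#'
#' Subtracts, for every voxel, the mean response across all conditions, so
#' each voxel's condition mean is exactly zero afterwards. Adding a constant
#' per-voxel offset beforehand therefore leaves the output unchanged.
#'
#' @param p A `"subject_patterns"` object or a conditions-by-voxels matrix
#'   with condition row names.
#' @return Same type as the input, normalised.
#' @export
normalize_patterns <- function(p) {
  if (inherits(p, "subject_patterns")) {
    p$patterns <- normalize_patterns(p$patterns)
    return(p)
  }
  stopifnot(is.matrix(p), nrow(p) >= 2L)
  sweep(p, 2, colMeans(p))
}

new_neural_rsm <- function(subject_id, matrix, labels,
                           fisher_z_applied = FALSE) {
  dimnames(matrix) <- list(labels, labels)
  structure(list(subject_id = subject_id, labels = labels, matrix = matrix,
                 fisher_z_applied = fisher_z_applied),
            class = "neural_rsm")
}

#' @export
print.neural_rsm <- function(x, ...) {
  cat(sprintf("<neural_rsm> %s, %d conditions%s\n", x$subject_id,
              length(x$labels),
              if (x$fisher_z_applied) ", Fisher z" else ""))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Leave-one-participant-out neural similarity matrix
#'
#' The held-out participant's voxel-wise-normalised condition patterns are
#' correlated against group condition patterns formed from the mean of all
#' remaining participants' normalised patterns, re-normalised by again
#' subtracting the per-voxel mean across conditions. Cell `(a, b)` is the
#' Pearson correlation of the held-out subject's condition-`a` pattern with
#' the group condition-`b` pattern; rows (subject) and columns (group) are
#' distinct axes, so the matrix need not be symmetric and its diagonal is an
#' informative cross-subject correlation rather than a fixed 1.
#'
#' Patterns are expected pre-normalised with [normalize_patterns()]; a
#' zero-variance pattern yields `NA` cells with a warning, and such cells
#' are excluded downstream.
#'
#' @param all_subjects List of `"subject_patterns"` (at least 3), sharing
#'   condition labels and voxel count.
#' @param held_out Subject id (or index) of the held-out participant.
#' @return A `"neural_rsm"` for the held-out subject.
#' @export
lopo_rsm <- function(all_subjects, held_out) {
  stopifnot(length(all_subjects) >= 3L)
  ids <- vapply(all_subjects, function(s) s$subject_id, character(1))
  if (is.numeric(held_out)) held_out <- ids[held_out]
  i <- match(held_out, ids)
  if (is.na(i)) stop("unknown held-out subject: ", held_out)
  labels <- all_subjects[[1]]$condition_labels
  subj <- all_subjects[[i]]$patterns
  rest <- lapply(all_subjects[-i], function(s) s$patterns)
  group <- Reduce(`+`, rest) / length(rest)
  group <- normalize_patterns(group)
  k <- length(labels)
  m <- matrix(NA_real_, k, k)
  degenerate <- FALSE
  for (a in seq_len(k)) for (b in seq_len(k)) {
    x <- subj[a, ]; y <- group[b, ]
    if (sd(x) == 0 || sd(y) == 0) degenerate <- TRUE
    else m[a, b] <- cor(x, y)
  }
  if (degenerate)
    warning("zero-variance pattern(s): affected cells set to NA")
  new_neural_rsm(held_out, m, labels)
}

#' Fisher z-transform a neural similarity matrix
#'
#' Applies the variance-stabilising inverse hyperbolic tangent cell-wise,
#' prior to parametric statistics. Cells at exactly `|r| = 1` have no finite
#' transform and raise an error naming the offending cell.
#'
#' @param rsm A `"neural_rsm"`.
#' @return The matrix with `atanh` applied and `fisher_z_applied = TRUE`.
#' @export
fisher_z <- function(rsm) {
  stopifnot(inherits(rsm, "neural_rsm"))
  bad <- which(abs(rsm$matrix) >= 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("|r| = 1 at cell (%s, %s); Fisher z undefined",
                 rsm$labels[bad[1, 1]], rsm$labels[bad[1, 2]]))
  rsm$matrix <- atanh(rsm$matrix)
  rsm$fisher_z_applied <- TRUE
  rsm
}

zscore <- function(x) (x - mean(x)) / sd(x)

#' Regress a neural RSM on shape and texture model RSMs
#'
#' The off-diagonal cells of the neural similarity matrix are vectorised as
#' the outcome, the corresponding cells of the two model matrices as
#' regressors. Although the leave-one-participant-out diagonal is not a
#' fixed 1, it is dominated by cross-subject pattern reliability -- a
#' quantity both model matrices' unit-diagonals would absorb, spuriously
#' inflating both coefficients -- so it is excluded by default
#' (`include_diagonal = TRUE` restores the all-cells variant for
#' sensitivity checks). Outcome and regressors are z-scored, so an
#' ordinary least-squares fit
#' with intercept yields standardised coefficients; z-scoring also makes
#' the result exactly invariant to scaling the neural matrix by a positive
#' constant. `NA` cells (flagged degenerate correlations) are dropped from
#' all vectors.
#'
#' @param neural A `"neural_rsm"` (typically Fisher-z transformed).
#' @param shape_rsm,texture_rsm Model `"rsm"`s over the same condition
#'   labels.
#' @param include_diagonal Keep diagonal cells in the regression?
#' @param collinearity_tol Error if the absolute correlation between the two
#'   z-scored regressors exceeds this.
#' @return List: `subject_id`, `beta_shape`, `beta_texture`,
#'   `residual_variance`.
#' @export
rsm_regression <- function(neural, shape_rsm, texture_rsm,
                           include_diagonal = FALSE,
                           collinearity_tol = 0.999) {
  stopifnot(inherits(neural, "neural_rsm"),
            identical(neural$labels, shape_rsm$labels),
            identical(neural$labels, texture_rsm$labels))
  k <- length(neural$labels)
  keep <- if (include_diagonal) rep(TRUE, k * k)
          else as.vector(diag(k) == 0)
  y <- as.vector(neural$matrix)[keep]
  xs <- as.vector(shape_rsm$matrix)[keep]
  xt <- as.vector(texture_rsm$matrix)[keep]
  ok <- is.finite(y)
  y <- y[ok]; xs <- xs[ok]; xt <- xt[ok]
  if (length(y) < 4L) stop("too few usable cells for regression")
  zs <- zscore(xs); zt <- zscore(xt)
  if (abs(cor(zs, zt)) > collinearity_tol)
    stop("shape and texture regressors are collinear")
  zy <- zscore(y)
  fit <- lm.fit(cbind(intercept = 1, shape = zs, texture = zt), zy)
  list(subject_id = neural$subject_id,
       beta_shape = unname(coef(fit)["shape"]),
       beta_texture = unname(coef(fit)["texture"]),
       residual_variance = sum(fit$residuals^2) / fit$df.residual)
}

one_sample_row <- function(x) {
  n <- length(x)
  if (sd(x) == 0) {
    return(list(mean = mean(x), t = if (mean(x) == 0) 0 else Inf * sign(mean(x)),
                df = n - 1L, p = if (mean(x) == 0) 1 else NA_real_,
                dz = if (mean(x) == 0) 0 else Inf * sign(mean(x)),
                degenerate = TRUE))
  }
  tt <- t.test(x)
  list(mean = mean(x), t = unname(tt$statistic), df = n - 1L,
       p = tt$p.value, dz = mean(x) / sd(x), degenerate = FALSE)
}

#' Group-level statistics on per-subject regression coefficients
#'
#' One-sample t tests of each coefficient against zero, plus the paired
#' shape-minus-texture contrast, each with two-sided p, `df = n - 1` and
#' Cohen's d_z (mean of the per-subject values divided by their SD). A
#' zero-variance coefficient is flagged degenerate (infinite d_z) rather
#' than tested.
#'
#' @param results List of [rsm_regression()] results, or a data frame with
#'   `beta_shape` and `beta_texture` columns (one row per subject).
#' @return A `"group_stats"` data frame with rows `shape`, `texture`,
#'   `shape_vs_texture` and columns `mean`, `t`, `df`, `p`, `dz`,
#'   `degenerate`.
#' @export
group_stats <- function(results) {
  if (!is.data.frame(results))
    results <- data.frame(
      beta_shape = vapply(results, `[[`, numeric(1), "beta_shape"),
      beta_texture = vapply(results, `[[`, numeric(1), "beta_texture"))
  if (nrow(results) < 2L) stop("need at least 2 subjects")
  rows <- list(shape = one_sample_row(results$beta_shape),
               texture = one_sample_row(results$beta_texture),
               shape_vs_texture = one_sample_row(results$beta_shape -
                                                   results$beta_texture))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- cbind(effect = names(rows), out)
  rownames(out) <- NULL
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Full multivariate analysis of one scan
#'
#' Runs the complete Experiment-1 style pipeline over a set of participants:
#' voxel-wise normalisation, leave-one-participant-out neural similarity
#' matrices, Fisher z, per-subject regression on the shape and texture model
#' matrices, and group statistics.
#'
#' @param subjects List of `"subject_patterns"`.
#' @param shape_rsm,texture_rsm Model `"rsm"`s restricted to the scan's
#'   conditions (see [subset_rsm()]).
#' @param include_diagonal Passed to [rsm_regression()].
#' @return List: `coefficients` (data frame, one row per subject), `group`
#'   (a `"group_stats"`), `rsms` (the per-subject `"neural_rsm"`s).
#' @export
run_exp1_analysis <- function(subjects, shape_rsm, texture_rsm,
                              include_diagonal = FALSE) {
  subjects <- lapply(subjects, normalize_patterns)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  rsms <- lapply(ids, function(id) fisher_z(lopo_rsm(subjects, id)))
  res <- lapply(rsms, rsm_regression, shape_rsm = shape_rsm,
                texture_rsm = texture_rsm,
                include_diagonal = include_diagonal)
  coefs <- data.frame(
    subject_id = ids,
    beta_shape = vapply(res, `[[`, numeric(1), "beta_shape"),
    beta_texture = vapply(res, `[[`, numeric(1), "beta_texture"))
  list(coefficients = coefs, group = group_stats(coefs), rsms = rsms)
}
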