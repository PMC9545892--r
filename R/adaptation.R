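## Block-design fMR-adaptation analysis: percent signal change, epoching,
## fixed-TR peak extraction, repeated-measures ANOVA and planned contrasts.

#' Convert an ROI time series to percent signal change
#'
#' `100 * (x - run_mean) / run_mean`; the output therefore has mean exactly
#' zero over the run. The run mean must be strictly positive.
#'
#' @param ts An `"roi_timeseries"`.
#' @return The series in percent-signal-change units (`psc = TRUE`).
#' @export
percent_signal_change <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  m <- mean(ts$samples)
  if (m <= 0) stop("run mean must be strictly positive")
  ts$samples <- 100 * (ts$samples - m) / m
  ts$psc <- TRUE
  ts
}

#' Epoch a time series into baselined stimulus blocks
#'
#' Cuts a 6-TR (18 s at TR = 3 s) window from each block onset and subtracts
#' the block baseline, defined as the mean of the window's 6 TR values, so
#' every epoch has mean exactly zero. Blocks whose window would run past the
#' end of the run are dropped with a warning. If `conditions` is supplied,
#' epochs of the same condition are averaged into one mean epoch per
#' condition.
#'
#' @param ts An `"roi_timeseries"` (typically percent signal change).
#' @param onsets 1-based TR index of each block's first TR; defaults to the
#'   onsets recorded on the series.
#' @param conditions Optional condition token per block; when given, the
#'   result has one averaged row per condition.
#' @param n_tr Epoch length in TRs (default 6).
#' @return Numeric matrix, blocks (or conditions) x `n_tr`, each row summing
#'   to zero.
#' @export
epoch_blocks <- function(ts, onsets = ts$block_onsets, conditions = NULL,
                         n_tr = 6L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- length(ts$samples)
  ok <- onsets + n_tr - 1L <= n
  if (!all(ok)) {
    warning(sprintf("dropping %d truncated block(s)", sum(!ok)))
    if (!is.null(conditions)) conditions <- conditions[ok]
    onsets <- onsets[ok]
  }
  ep <- t(vapply(onsets, function(o) {
    w <- ts$samples[o + 0:(n_tr - 1L)]
    w - mean(w)
  }, numeric(n_tr)))
  colnames(ep) <- paste0("tr", seq_len(n_tr))
  if (is.null(conditions)) return(ep)
  stopifnot(length(conditions) == nrow(ep))
  g <- factor(conditions, levels = unique(conditions))
  rowsum(ep, g) / as.vector(table(g))
}

#' Response at a fixed TR within an epoch
#'
#' Returns the value at the stated TR (1-based within the block), not the
#' maximum: with a 6 s stimulus block, a single-gamma HRF peaking at 6 s and
#' TR = 3 s, the blood-oxygenation response peaks at the third TR (9 s after
#' block onset), so that TR is extracted as the peak response.
#'
#' @param epoch Numeric vector (one epoch) or matrix (epochs in rows).
#' @param peak_tr TR to extract, between 1 and the epoch length (default 3).
#' @return Scalar, or named vector for a matrix input.
#' @export
peak_at_tr <- function(epoch, peak_tr = 3L) {
  len <- if (is.matrix(epoch)) ncol(epoch) else length(epoch)
  if (peak_tr < 1L || peak_tr > len)
    stop(sprintf("`peak_tr` must lie in [1, %d]", len))
  if (is.matrix(epoch)) epoch[, peak_tr] else epoch[[peak_tr]]
}

check_balanced <- function(table, subject, factors) {
  counts <- table(table[, c(subject, factors)])
  if (any(counts != 1L))
    stop("design must be complete and balanced: one row per subject per cell")
  invisible(TRUE)
}

#' Repeated-measures ANOVA with generalised eta squared
#'
#' Fully within-subject ANOVA via the classical sum-of-squares
#' decomposition with subject as the error stratum (`aov` with an
#' `Error(subject/...)` term): every effect is tested against its own
#' subject-by-effect interaction, giving `df_den = (n - 1) * df_num`, with
#' no sphericity correction. Generalised eta squared for each effect is
#' `SS_effect / (SS_effect + SS_subjects + sum of all error SS)`, the
#' recommended effect size for fully repeated-measures designs.
#'
#' @param table Data frame with one row per subject per design cell.
#' @param factors Within-subject factor column names, e.g.
#'   `c("roi", "filter", "category", "sequence")`.
#' @param dv Dependent-variable column (default `"peak_psc"`).
#' @param subject Subject identifier column (default `"subject"`).
#' @return An `"anova_result"` data frame: `effect`, `df_num`, `df_den`,
#'   `F`, `p`, `ges`.
#' @export
rm_anova <- function(table, factors, dv = "peak_psc", subject = "subject") {
  stopifnot(all(c(dv, subject, factors) %in% names(table)))
  check_balanced(table, subject, factors)
  d <- table
  d[[subject]] <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])
  rhs <- paste(factors, collapse = " * ")
  fml <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                   dv, rhs, subject, rhs))
  fit <- aov(fml, data = d)
  sm <- summary(fit)
  rows <- list(); ss_err_total <- 0; ss_subj <- 0
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    resid_ss <- if ("Residuals" %in% terms)
      tab[terms == "Residuals", "Sum Sq"] else 0
    if (grepl(paste0("^Error: ", subject, "$"), stratum)) {
      ss_subj <- resid_ss
      next
    }
    ss_err_total <- ss_err_total + resid_ss
    for (i in which(terms != "Residuals")) {
      rows[[terms[i]]] <- data.frame(
        effect = gsub(":", " x ", terms[i]),
        df_num = tab[i, "Df"],
        df_den = tab[terms == "Residuals", "Df"],
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
        ss = tab[i, "Sum Sq"])
    }
  }
  out <- do.call(rbind, rows)
  out$ges <- out$ss / (out$ss + ss_subj + ss_err_total)
  out$ss <- NULL
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

paired_t_row <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    return(list(mean_diff = mean(d),
                t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = n - 1L, p = if (mean(d) == 0) 1 else NA_real_,
                dz = if (mean(d) == 0) 0 else Inf * sign(mean(d))))
  }
  tt <- t.test(d)
  list(mean_diff = mean(d), t = unname(tt$statistic), df = n - 1L,
       p = tt$p.value, dz = mean(d) / sd(d))
}

#' Planned pairwise sequence contrasts with Benjamini-Hochberg correction
#'
#' For every combination of ROI and category, all pairs of sequence levels
#' are contrasted with paired t tests (subject-matched; rows are collapsed
#' by averaging over `collapse` columns, e.g. filter type, first). With 2
#' categories and 3 sequences this yields 6 planned comparisons per ROI;
#' the step-up false-discovery-rate adjustment is applied within each ROI's
#' family of comparisons.
#'
#' A pair of genuinely identical conditions (all differences zero) is
#' reported as `t = 0`, `p = 1` rather than as an error; a nonzero constant
#' difference has no finite t and is returned with `p = NA`.
#'
#' @param table Data frame with `subject`, `roi`, `category`, `sequence`
#'   columns (names configurable) and the dependent variable.
#' @param dv Dependent-variable column (default `"peak_psc"`).
#' @param subject,roi,category,sequence Column names.
#' @param collapse Columns averaged out before contrasting (default
#'   `"filter"`, if present).
#' @param family Column(s) defining the correction family (default the ROI).
#' @return A `"contrast_table"` data frame: `roi`, `category`, `level_a`,
#'   `level_b`, `mean_diff`, `t`, `df`, `p`, `dz`, `p_adj`.
#' @export
pairwise_contrasts <- function(table, dv = "peak_psc", subject = "subject",
                               roi = "roi", category = "category",
                               sequence = "sequence",
                               collapse = intersect("filter", names(table)),
                               family = roi) {
  stopifnot(all(c(dv, subject, roi, category, sequence) %in% names(table)))
  keys <- c(subject, roi, category, sequence)
  if (length(collapse))
    table <- stats::aggregate(table[, dv, drop = FALSE], table[, keys], mean)
  rows <- list()
  for (r in unique(table[[roi]])) for (cc in unique(table[[category]])) {
    sub <- table[table[[roi]] == r & table[[category]] == cc, ]
    levs <- unique(as.character(sub[[sequence]]))
    for (pair in utils::combn(levs, 2, simplify = FALSE)) {
      a <- sub[sub[[sequence]] == pair[1], ]
      b <- sub[sub[[sequence]] == pair[2], ]
      a <- a[order(a[[subject]]), ]; b <- b[order(b[[subject]]), ]
      stopifnot(identical(as.character(a[[subject]]),
                          as.character(b[[subject]])))
      st <- paired_t_row(a[[dv]], b[[dv]])
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, category = cc, level_a = pair[1], level_b = pair[2],
        mean_diff = st$mean_diff, t = st$t, df = st$df, p = st$p,
        dz = st$dz)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  fam <- interaction(out[, family, drop = FALSE], drop = TRUE)
  for (f in levels(fam)) {
    idx <- fam == f
    out$p_adj[idx] <- p.adjust(out$p[idx], method = "BH")
  }
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Time series, epochs and peak table for a set of adaptation scans
#'
#' Runs the univariate analysis chain over a list of simulated (or loaded)
#' ROI time series: percent signal change, 6-TR epoching with block-mean
#' baselining, condition averaging, and extraction of the TR-3 peak,
#' producing the long-format table consumed by [rm_anova()] and
#' [pairwise_contrasts()].
#'
#' @param series List of `"roi_timeseries"` whose `blocks` data frame labels
#'   each block's category, filter type and sequence.
#' @param peak_tr TR extracted as the peak (default 3).
#' @return Data frame: `subject`, `roi`, `filter`, `category`, `sequence`,
#'   `peak_psc`.
#' @export
adaptation_peak_table <- function(series, peak_tr = 3L) {
  rows <- lapply(series, function(ts) {
    psc <- percent_signal_change(ts)
    cond <- with(ts$blocks, paste(category, sequence, sep = "."))
    ep <- epoch_blocks(psc, conditions = cond)
    peaks <- peak_at_tr(ep, peak_tr)
    parts <- strsplit(rownames(ep), ".", fixed = TRUE)
    data.frame(subject = ts$subject_id, roi = ts$roi_id,
               filter = ts$blocks$filter_type[1],
               category = vapply(parts, `[`, character(1), 1),
               sequence = vapply(parts, `[`, character(1), 2),
               peak_psc = unname(peaks))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
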