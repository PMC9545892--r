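## Condition-level similarity matrices from descriptor vectors.

new_rsm <- function(matrix, labels, variant = NULL) {
  dimnames(matrix) <- list(labels, labels)
  structure(list(labels = labels, matrix = matrix, variant = variant),
            class = "rsm")
}

#' @export
print.rsm <- function(x, ...) {
  cat(sprintf("<rsm> %d conditions%s\n", length(x$labels),
              if (is.null(x$variant)) "" else paste0(", variant = ", x$variant)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Condition similarity matrix with a leave-one-image-out scheme
#'
#' For each image `i` and condition `b`, the image's descriptor vector is
#' Pearson-correlated with the mean vector of condition `b`, computed with
#' image `i` excluded whenever `i` belongs to `b` (between-condition cells
#' use the full mean, since `i` is not a member). Cell `(a, b)` is the mean
#' of these correlations over the images of condition `a`, and the matrix is
#' symmetrised by averaging with its transpose. Diagonal cells are therefore
#' not forced to 1, but reach 1 exactly when a condition's images share one
#' identical vector.
#'
#' Zero-variance vectors (for which correlation is undefined) are dropped
#' with a warning before the computation.
#'
#' @param vectors Numeric matrix, one image per row (e.g. the value columns
#'   of a [gist_table()]), or a list of `"gist_vector"`s.
#' @param conditions Condition token per image (character or factor). Every
#'   condition needs at least 2 images.
#' @param variant Optional descriptor variant recorded on the result.
#' @param labels Condition order of the output; defaults to order of first
#'   appearance.
#' @return An `"rsm"` object: list with `labels`, `matrix`, `variant`.
#' @export
condition_similarity <- function(vectors, conditions, variant = NULL,
                                 labels = unique(as.character(conditions))) {
  if (is.list(vectors) && !is.data.frame(vectors))
    vectors <- do.call(rbind, lapply(vectors, as.numeric))
  vectors <- as.matrix(vectors)
  conditions <- as.character(conditions)
  stopifnot(nrow(vectors) == length(conditions))
  sds <- apply(vectors, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance vector(s)", sum(sds == 0)))
    keep <- sds > 0
    vectors <- vectors[keep, , drop = FALSE]
    conditions <- conditions[keep]
  }
  counts <- table(factor(conditions, levels = labels))
  if (any(counts < 2))
    stop("every condition needs at least 2 images for leave-one-out")
  k <- length(labels)
  sums <- rowsum(vectors, group = factor(conditions, levels = labels))
  m <- matrix(0, k, k)
  for (a in seq_len(k)) {
    ia <- which(conditions == labels[a])
    for (b in seq_len(k)) {
      r <- vapply(ia, function(i) {
        ref <- if (conditions[i] == labels[b])
          (sums[b, ] - vectors[i, ]) / (counts[b] - 1)
        else
          sums[b, ] / counts[b]
        cor(vectors[i, ], ref)
      }, numeric(1))
      m[a, b] <- mean(r)
    }
  }
  new_rsm((m + t(m)) / 2, labels, variant)
}

#' Restrict an RSM to a subset of conditions
#'
#' Used to cut the 4 x 4 per-scan model matrices (e.g. the
#' frequency-scan conditions `face_high, face_low, house_high, house_low`)
#' out of the full 8-condition similarity matrix.
#'
#' @param rsm An `"rsm"`.
#' @param labels Condition tokens to keep, in the desired order.
#' @return An `"rsm"` over `labels`.
#' @export
subset_rsm <- function(rsm, labels) {
  stopifnot(inherits(rsm, "rsm"))
  missing <- setdiff(labels, rsm$labels)
  if (length(missing))
    stop("conditions not in RSM: ", paste(missing, collapse = ", "))
  new_rsm(rsm$matrix[labels, labels, drop = FALSE], labels, rsm$variant)
}

#' Build shape and texture model RSMs from a stimulus set
#'
#' Convenience wrapper: computes both GIST variants for every filtered image
#' and turns each into a condition similarity matrix over the
#' `category_filter` conditions.
#'
#' @inheritParams gist_table
#' @return List with `shape` and `texture` (both `"rsm"`), plus the two
#'   descriptor tables.
#' @export
model_rsms <- function(stimulus_set, bank) {
  cond <- paste(stimulus_set$info$category, stimulus_set$info$filter,
                sep = "_")
  out <- list()
  for (variant in c("shape", "texture")) {
    tab <- gist_table(stimulus_set, bank, variant)
    out[[paste0(variant, "_table")]] <- tab
    out[[variant]] <- condition_similarity(
      as.matrix(tab[, grep("^v", names(tab))]), cond, variant)
  }
  out
}

#' Write / read an RSM as labelled CSV
#' @param rsm An `"rsm"`.
#' @param path File path.
#' @return `write_rsm_csv()` returns `path` invisibly; `read_rsm_csv()`
#'   returns an `"rsm"`.
#' @export
write_rsm_csv <- function(rsm, path) {
  stopifnot(inherits(rsm, "rsm"))
  write.csv(rsm$matrix, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rsm_csv
#' @param variant Variant token attached on read.
#' @export
read_rsm_csv <- function(path, variant = NULL) {
  d <- read.csv(path, row.names = 1, check.names = FALSE)
  new_rsm(as.matrix(d), rownames(d), variant)
}
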