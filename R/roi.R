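## Flood-fill ROI definition on statistical maps.

# Neighbourhood offsets for 6- (faces), 18- (faces + edges) or 26- (full
# cube) connectivity.
adjacency_offsets <- function(adjacency = c("6", "18", "26")) {
  adjacency <- match.arg(as.character(adjacency), c("6", "18", "26"))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(adjacency,
                 "6" = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

# Order voxel coordinate rows lexicographically by (x, y, z).
lex_order <- function(co) order(co[, 1], co[, 2], co[, 3])

#' Locate the peak voxel of a statistical map
#'
#' Returns the coordinates of the maximal value, optionally restricted to a
#' search mask. `NA`/`NaN` voxels are ignored; ties are broken by
#' lexicographic (x, y, z) coordinate order.
#'
#' @param zmap 3D numeric array.
#' @param search_mask Optional logical/numeric array of the same dimensions;
#'   only voxels where it is `TRUE`/nonzero are searched.
#' @return Integer triple (x, y, z).
#' @export
find_peak <- function(zmap, search_mask = NULL) {
  stopifnot(is.array(zmap), length(dim(zmap)) == 3L)
  v <- zmap
  if (!is.null(search_mask)) {
    stopifnot(all(dim(search_mask) == dim(zmap)))
    v[!(search_mask != 0)] <- NA
  }
  if (all(is.na(v))) stop("search region is empty or all-NA")
  mx <- max(v, na.rm = TRUE)
  co <- arrayInd(which(v == mx), dim(zmap))
  co <- co[lex_order(co), , drop = FALSE]
  as.integer(co[1, ])
}

#' Grow a fixed-size ROI by greedy flood fill
#'
#' Starting from a seed voxel (typically the map peak), the cluster grows by
#' repeatedly adding the frontier voxel -- a voxel spatially adjacent to the
#' current cluster -- with the highest z value, until `target_size` voxels
#' are included. This is equivalent to iteratively lowering a threshold and
#' admitting the next-highest contiguous voxel. The result is connected
#' under the chosen adjacency, contains the seed, and has exactly
#' `target_size` voxels. Frontier ties are broken by lexicographic (x, y, z)
#' order for determinism. Group-level ROIs use 256 voxels per hemisphere;
#' peak ROIs for the adaptation analysis use 16.
#'
#' @param zmap 3D numeric array.
#' @param seed_voxel Integer triple (x, y, z) inside the volume.
#' @param target_size Number of voxels to include (>= 1).
#' @param adjacency 6 (faces only, default), 18 or 26.
#' @param search_mask Optional array; growth is confined to nonzero voxels
#'   (e.g. one hemisphere).
#' @param roi_id Token stored on the mask.
#' @return An `"roi_mask"`: list with `voxel_indices` (`target_size` x 3
#'   integer matrix), `roi_id`, `seed_voxel`, `dim`, `adjacency`.
#' @export
flood_fill_roi <- function(zmap, seed_voxel, target_size, adjacency = 6,
                           search_mask = NULL, roi_id = "roi") {
  stopifnot(is.array(zmap), length(dim(zmap)) == 3L)
  dm <- dim(zmap)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) ||
      any(seed_voxel > dm))
    stop("`seed_voxel` must be an (x, y, z) triple inside the volume")
  target_size <- as.integer(target_size)
  if (target_size < 1L) stop("`target_size` must be >= 1")
  allowed <- if (is.null(search_mask)) NULL else (search_mask != 0)
  if (!is.null(allowed) && !allowed[seed_voxel[1], seed_voxel[2],
                                    seed_voxel[3]])
    stop("seed voxel lies outside the search mask")
  off <- adjacency_offsets(adjacency)
  in_cluster <- array(FALSE, dm)
  in_frontier <- array(FALSE, dm)
  cluster <- matrix(0L, target_size, 3)
  cluster[1, ] <- seed_voxel
  in_cluster[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <- TRUE
  frontier <- matrix(integer(0), 0, 3)
  add_neighbours <- function(vox) {
    nb <- sweep(off, 2, vox, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    if (!nrow(nb)) return(invisible())
    lin <- nb[, 1] + (nb[, 2] - 1L) * dm[1] + (nb[, 3] - 1L) * dm[1] * dm[2]
    new <- !in_cluster[lin] & !in_frontier[lin] & !is.na(zmap[lin])
    if (!is.null(allowed)) new <- new & allowed[lin]
    if (any(new)) {
      in_frontier[lin[new]] <<- TRUE
      frontier <<- rbind(frontier, nb[new, , drop = FALSE])
    }
    invisible()
  }
  add_neighbours(seed_voxel)
  for (k in seq_len(target_size - 1L) + 1L) {
    if (!nrow(frontier))
      stop(sprintf(
        "connected region exhausted at %d voxels (target %d)", k - 1L,
        target_size))
    zf <- zmap[frontier]
    best <- which(zf == max(zf))
    if (length(best) > 1L) {
      tied <- frontier[best, , drop = FALSE]
      best <- best[lex_order(tied)[1]]
    }
    vox <- frontier[best, ]
    frontier <- frontier[-best, , drop = FALSE]
    in_frontier[vox[1], vox[2], vox[3]] <- FALSE
    in_cluster[vox[1], vox[2], vox[3]] <- TRUE
    cluster[k, ] <- vox
    add_neighbours(vox)
  }
  structure(list(voxel_indices = cluster, roi_id = roi_id,
                 seed_voxel = seed_voxel, dim = dm,
                 adjacency = as.integer(as.character(adjacency))),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d voxels, seed (%d, %d, %d), %d-connectivity\n",
              x$roi_id, nrow(x$voxel_indices), x$seed_voxel[1],
              x$seed_voxel[2], x$seed_voxel[3], x$adjacency))
  invisible(x)
}

#' Convert an ROI mask to a binary array
#' @param mask An `"roi_mask"`.
#' @return Logical array of the mask's volume dimensions.
#' @export
roi_mask_array <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  a <- array(FALSE, mask$dim)
  a[mask$voxel_indices] <- TRUE
  a
}

#' Is an ROI mask spatially connected?
#' @param mask An `"roi_mask"`.
#' @param adjacency Connectivity to check under (defaults to the mask's own).
#' @return `TRUE` if every voxel is reachable from the seed.
#' @export
roi_is_connected <- function(mask, adjacency = mask$adjacency) {
  a <- roi_mask_array(mask)
  off <- adjacency_offsets(adjacency)
  dm <- mask$dim
  visited <- array(FALSE, dm)
  queue <- matrix(mask$seed_voxel, 1)
  visited[queue] <- TRUE
  while (nrow(queue)) {
    vox <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    nb <- sweep(off, 2, vox, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, ]
      if (a[v[1], v[2], v[3]] && !visited[v[1], v[2], v[3]]) {
        visited[v[1], v[2], v[3]] <- TRUE
        queue <- rbind(queue, v)
      }
    }
  }
  sum(visited) == nrow(mask$voxel_indices)
}

#' NIfTI I/O for z-maps and ROI masks
#'
#' Thin wrappers over \pkg{RNifti} so statistical maps and masks can be
#' exchanged with standard neuroimaging tools.
#'
#' @param x 3D array (z-map) or `"roi_mask"`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly; readers return an array.
#' @export
write_zmap_nifti <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' @rdname write_zmap_nifti
#' @export
read_zmap_nifti <- function(path) {
  a <- RNifti::readNifti(path)
  array(as.numeric(a), dim(a))
}

#' @rdname write_zmap_nifti
#' @param mask An `"roi_mask"`.
#' @export
write_roi_nifti <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(roi_mask_array(mask) * 1L), path)
  invisible(path)
}
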