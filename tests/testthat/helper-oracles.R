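# Independent brute-force greedy flood fill: rebuilds the frontier from
# scratch every iteration by scanning all non-members for 6-adjacency to
# the cluster, taking the highest z (ties: lexicographic x, y, z scan
# order). Used as the oracle for flood_fill_roi().
oracle_flood_fill <- function(z, seed, size) {
  dm <- dim(z)
  cluster <- matrix(seed, 1)
  while (nrow(cluster) < size) {
    best <- NULL
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (s in 1:dm[3]) {
      if (any(cluster[, 1] == x & cluster[, 2] == y & cluster[, 3] == s))
        next
      adj <- any(abs(cluster[, 1] - x) + abs(cluster[, 2] - y) +
                   abs(cluster[, 3] - s) == 1)
      if (!adj) next
      if (is.null(best) || z[x, y, s] > z[best[1], best[2], best[3]])
        best <- c(x, y, s)
    }
    cluster <- rbind(cluster, best)
  }
  unname(cluster)
}
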