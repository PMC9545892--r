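# Multivariate pipeline: normalisation, LOPO similarity, Fisher z,
# RSM regression and group statistics.

test_that("voxel-wise normalisation zeroes condition means", {
  # two conditions (rows) by two voxels: voxel responses (1, 3) and (2, 2)
  toy <- matrix(c(1, 3, 2, 2), 2, 2,
                dimnames = list(c("c1", "c2"), NULL))
  expect_equal(unname(normalize_patterns(toy)),
               rbind(c(-1, 0), c(1, 0)))

  set.seed(41)
  p <- matrix(rnorm(4 * 10), 4, 10, dimnames = list(paste0("c", 1:4), NULL))
  np <- normalize_patterns(p)
  expect_lt(max(abs(colMeans(np))), 1e-12)

  # invariant to a constant per-voxel offset
  off <- matrix(rep(rnorm(10), each = 4), 4, 10)
  expect_equal(normalize_patterns(p + off), np, tolerance = 1e-12)
})

make_subjects <- function(mats, roi = "sim") {
  lapply(seq_along(mats), function(i)
    structure(list(subject_id = sprintf("sub%02d", i),
                   patterns = mats[[i]],
                   condition_labels = rownames(mats[[i]]), roi_id = roi),
              class = "subject_patterns"))
}

test_that("LOPO similarity matches a hand-coded oracle", {
  set.seed(42)
  labs <- c("a", "b", "c")
  mats <- replicate(4, {
    m <- matrix(rnorm(3 * 6), 3, 6); rownames(m) <- labs; m
  }, simplify = FALSE)
  subs <- make_subjects(mats)
  r <- lopo_rsm(subs, "sub02")
  expect_equal(dim(r$matrix), c(3, 3))
  expect_identical(r$subject_id, "sub02")

  group <- (mats[[1]] + mats[[3]] + mats[[4]]) / 3
  group <- sweep(group, 2, colMeans(group))
  oracle <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    oracle[a, b] <- cor(mats[[2]][a, ], group[b, ])
  expect_equal(unname(r$matrix), oracle, tolerance = 1e-12)

  # identical subjects with distinct condition patterns: unit diagonal
  same <- make_subjects(replicate(3, mats[[1]], simplify = FALSE))
  rs <- lopo_rsm(lapply(same, normalize_patterns), 1)
  expect_equal(unname(diag(rs$matrix)), rep(1, 3), tolerance = 1e-12)

  expect_error(lopo_rsm(subs[1:2], 1), ">= 3")
  expect_error(lopo_rsm(subs, "nobody"), "unknown")

  flatm <- mats
  flatm[[2]][1, ] <- 7   # zero-variance pattern for the held-out subject
  expect_warning(rf <- lopo_rsm(make_subjects(flatm), 2), "zero-variance")
  expect_true(all(is.na(rf$matrix[1, ])))
})

test_that("Fisher z is the inverse hyperbolic tangent with guarded poles", {
  m <- matrix(c(0, 0.5, -0.3, 0.9), 2, 2)
  r <- make_neural(m, c("a", "b"))
  z <- fisher_z(r)
  expect_true(z$fisher_z_applied)
  expect_equal(z$matrix[1, 1], 0)
  expect_equal(z$matrix[2, 1], 0.549306144334055, tolerance = 1e-12)

  # strictly increasing over a grid of correlations
  g <- seq(-0.95, 0.95, by = 0.05)
  zz <- fisher_z(make_neural(matrix(g[1:36], 6, 6), letters[1:6]))
  expect_true(all(diff(as.vector(zz$matrix)) > 0))

  expect_error(fisher_z(make_neural(matrix(c(0, 1, 0, 0), 2, 2),
                                    c("a", "b"))),
               "Fisher z undefined")
})

test_that("RSM regression recovers coefficients against an OLS oracle", {
  mods <- scan_model_rsms("frequency")
  labs <- mods$shape$labels
  k <- 4

  # outcome identical to the shape model: (1, 0) exactly
  r <- rsm_regression(make_neural(mods$shape$matrix, labs),
                      mods$shape, mods$texture)
  expect_equal(r$beta_shape, 1, tolerance = 1e-10)
  expect_equal(r$beta_texture, 0, tolerance = 1e-10)

  off <- diag(k) == 0
  zsc <- function(x) (x - mean(x)) / sd(x)
  zs <- zsc(mods$shape$matrix[off]); zt <- zsc(mods$texture$matrix[off])

  # outcome orthogonalised against both regressors: both betas zero
  set.seed(43)
  y0 <- stats::residuals(stats::lm(rnorm(12) ~ zs + zt))
  m0 <- matrix(0, k, k); m0[off] <- y0
  r0 <- rsm_regression(make_neural(m0, labs), mods$shape, mods$texture)
  expect_equal(r0$beta_shape, 0, tolerance = 1e-10)
  expect_equal(r0$beta_texture, 0, tolerance = 1e-10)

  # normal-equations oracle on a noisy mixture
  y <- 0.6 * zs + 0.2 * zt + rnorm(12, 0, 0.1)
  m <- matrix(0, k, k); m[off] <- y
  rr <- rsm_regression(make_neural(m, labs), mods$shape, mods$texture)
  X <- cbind(1, zs, zt)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% zsc(y))
  expect_equal(rr$beta_shape, beta_oracle[2], tolerance = 1e-8)
  expect_equal(rr$beta_texture, beta_oracle[3], tolerance = 1e-8)

  # exact invariance to positive scaling of the neural matrix
  r3 <- rsm_regression(make_neural(3.7 * m, labs), mods$shape, mods$texture)
  expect_equal(r3$beta_shape, rr$beta_shape, tolerance = 1e-12)
  expect_equal(r3$beta_texture, rr$beta_texture, tolerance = 1e-12)

  expect_error(rsm_regression(make_neural(m, labs), mods$shape, mods$shape),
               "collinear")
})

test_that("group statistics match the one-sample t formula", {
  b <- data.frame(beta_shape = c(0.5, 0.7, 0.4, 0.6, 0.55),
                  beta_texture = c(0.1, -0.1, 0.05, 0, -0.05))
  g <- group_stats(b)
  n <- 5
  t_oracle <- mean(b$beta_shape) / (sd(b$beta_shape) / sqrt(n))
  expect_equal(g$t[g$effect == "shape"], t_oracle, tolerance = 1e-12)
  expect_equal(g$p[g$effect == "shape"],
               2 * stats::pt(-abs(t_oracle), n - 1), tolerance = 1e-12)
  expect_equal(g$df[g$effect == "shape"], 4)
  expect_equal(g$dz[g$effect == "shape"],
               mean(b$beta_shape) / sd(b$beta_shape), tolerance = 1e-12)

  d <- b$beta_shape - b$beta_texture
  expect_equal(g$t[g$effect == "shape_vs_texture"],
               mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-12)

  # exactly symmetric coefficients: t = 0, p = 1
  sym <- data.frame(beta_shape = c(-0.2, 0.2, -0.1, 0.1),
                    beta_texture = rnorm(4))
  gs <- group_stats(sym)
  expect_equal(gs$t[gs$effect == "shape"], 0, tolerance = 1e-12)
  expect_equal(gs$p[gs$effect == "shape"], 1, tolerance = 1e-12)

  # constant nonzero coefficients are flagged degenerate, not tested
  dg <- group_stats(data.frame(beta_shape = rep(0.4, 4),
                               beta_texture = rnorm(4)))
  expect_true(dg$degenerate[dg$effect == "shape"])
  expect_identical(dg$dz[dg$effect == "shape"], Inf)

  expect_error(group_stats(b[1, ]), "at least 2")
})

test_that("the full pipeline recovers a pure-shape ground truth", {
  mods <- scan_model_rsms("frequency")
  res <- simulate_exp1_study(mods$shape, mods$texture, 0.7, 0,
                             n_subjects = 12, seed = 77)
  g <- res$group
  expect_gt(g$mean[g$effect == "shape"], 0)
  expect_lt(g$p[g$effect == "shape"], 0.05)
  expect_lt(g$p[g$effect == "shape_vs_texture"], 0.05)
  expect_gt(g$mean[g$effect == "shape_vs_texture"], 0)
  # texture coefficient not significantly above zero
  tex <- g[g$effect == "texture", ]
  expect_false(tex$p < 0.05 && tex$mean > 0)
})
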