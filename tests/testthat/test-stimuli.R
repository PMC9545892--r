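# Synthetic stimulus generation and Fourier-domain filtering.

test_that("synthetic images are seeded, mid-grey and category-structured", {
  img <- make_synthetic_image("face", 128, seed = 0)
  expect_s3_class(img, "vt_image")
  expect_equal(dim(img$pixels), c(128, 128))
  expect_lt(abs(mean(img$pixels) - 0.5), 0.1)
  expect_gt(var(as.vector(img$pixels)), 0)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))

  again <- make_synthetic_image("face", 128, seed = 0)
  expect_identical(img$pixels, again$pixels)
  other <- make_synthetic_image("face", 128, seed = 1)
  expect_false(identical(img$pixels, other$pixels))

  house <- make_synthetic_image("house", 128, seed = 0)
  expect_false(identical(img$pixels, house$pixels))

  expect_error(make_synthetic_image("tree", 128, 0))
  expect_error(make_synthetic_image("face", 32, 0), "at least 64")
})

# Independent re-evaluation of the wrapped-Gaussian orientation profile,
# brute-forced over many 180-degree shifts.
oracle_orientation_gain <- function(theta_deg, center_deg, fwhm_deg) {
  sigma <- fwhm_deg / (2 * sqrt(2 * log(2)))
  s <- function(d) {
    tot <- 0
    for (k in -50:50) tot <- tot + exp(-(d + 180 * k)^2 / (2 * sigma^2))
    tot
  }
  s(theta_deg - center_deg) / s(0)
}

test_that("orientation filters follow the wrapped-Gaussian contract", {
  n <- 64; ppd <- 12.8
  filt <- orientation_filter(0, 75, n, ppd)
  # gain is exactly 1 along the centre orientation (fy = 0 row, fx > 0)
  expect_equal(unname(filt$transfer[1, 2:5]), rep(1, 4), tolerance = 1e-12)
  expect_equal(filt$transfer[1, 1], 1)  # DC passes

  # a 90-degree FWHM filter has gain 0.5 at 45 degrees (fx == fy diagonal),
  # up to the small wrapped-tail correction (~0.2% at this bandwidth)
  f90 <- orientation_filter(0, 90, n, ppd)
  expect_equal(f90$transfer[3, 3], 0.5, tolerance = 5e-3)

  # whole-raster equivalence with the brute-force wrapped-sum oracle,
  # including at 90 degrees from centre (odd raster, where the Fourier
  # angle map alone determines the gain with no Nyquist ambiguity)
  no <- 63
  for (center in c(0, 37, 90)) {
    f <- orientation_filter(center, 75, no, ppd)
    k <- 0:(no - 1); k[k > no / 2] <- k[k > no / 2] - no
    fx <- matrix(k, no, no, byrow = TRUE); fy <- matrix(k, no, no)
    theta <- (atan2(fy, fx) * 180 / pi) %% 180
    expected <- oracle_orientation_gain(theta, center, 75)
    expected[1, 1] <- 1
    expect_equal(f$transfer, expected, tolerance = 1e-10)
  }

  # Hermitian symmetry: gain(u, v) == gain(-u, -v)
  f <- orientation_filter(30, 75, n, ppd)
  idx <- 2:n
  expect_equal(f$transfer[idx, idx], f$transfer[rev(idx), rev(idx)],
               tolerance = 1e-12)

  expect_error(orientation_filter(0, 0, n, ppd), "0, 180")
  expect_error(orientation_filter(0, 180, n, ppd), "0, 180")
})

test_that("frequency filters are half-maximum at their cut-off", {
  n <- 128; ppd <- 12.8   # frequency step 0.1 c/deg, Nyquist 6.4
  lo <- frequency_filter("low", 2, n, ppd)
  expect_equal(lo$transfer[1, 1], 1)            # DC pass
  expect_equal(lo$transfer[1, 21], 0.5, tolerance = 1e-12)  # 2.0 c/deg

  hi <- frequency_filter("high", 6, n, ppd)
  expect_equal(hi$transfer[1, 1], 0)            # DC blocked
  expect_equal(hi$transfer[1, 61], 0.5, tolerance = 1e-12)  # 6.0 c/deg

  # closed-form oracle at 3 c/deg for the 6 c/deg high-pass
  sigma <- 6 / sqrt(2 * log(2))
  expect_equal(hi$transfer[1, 31], 1 - exp(-9 / (2 * sigma^2)),
               tolerance = 1e-12)

  expect_error(frequency_filter("low", 6.4, n, ppd), "Nyquist")
  expect_error(frequency_filter("low", 7, n, ppd), "Nyquist")
})

test_that("apply_filter rescales, preserves realness and acts per-bin", {
  n <- 64; ppd <- 12.8
  set.seed(11)
  img <- vt_image(matrix(runif(n * n, 0.45, 0.55), n, n), ppd)

  # all-pass filter: identity up to the mean rescale
  ap <- frequency_filter("low", 2, n, ppd)
  ap$transfer[] <- 1
  out <- apply_filter(img, ap)
  expect_equal(out$pixels, img$pixels - mean(img$pixels) + 0.5,
               tolerance = 1e-10)

  # rescaling contract: mean exactly 0.5 (low-contrast input, no clipping)
  for (f in stimulus_filters(n, ppd))
    expect_equal(mean(apply_filter(img, f)$pixels), 0.5, tolerance = 1e-12)

  # realness for all four stimulus filters on a random image (an error
  # would be raised if the imaginary residue exceeded 1e-8)
  rimg <- vt_image(matrix(runif(n * n), n, n), ppd)
  for (f in stimulus_filters(n, ppd))
    expect_true(is.numeric(apply_filter(rimg, f)$pixels))

  # pure 4 c/deg grating through the 2 c/deg low-pass: amplitude scales by
  # exactly the filter's gain at that frequency bin
  cyc <- 4 * n / ppd                       # cycles across the raster
  x <- matrix(0:(n - 1), n, n, byrow = TRUE)
  gr <- vt_image(0.5 + 0.2 * cos(2 * pi * cyc * x / n), ppd)
  lo <- frequency_filter("low", 2, n, ppd)
  fout <- apply_filter(gr, lo)
  amp_in <- Mod(fft(gr$pixels))[1, cyc + 1]
  amp_out <- Mod(fft(fout$pixels))[1, cyc + 1]
  sigma <- 2 / sqrt(2 * log(2))
  expect_equal(amp_out / amp_in, exp(-16 / (2 * sigma^2)), tolerance = 1e-8)

  # cascade identity: applying twice equals applying the squared gain once
  a <- apply_filter(apply_filter(rimg, lo, rescale = FALSE, clip = FALSE),
                    lo, rescale = FALSE, clip = FALSE)
  lo2 <- lo; lo2$transfer <- lo$transfer^2
  b <- apply_filter(rimg, lo2, rescale = FALSE, clip = FALSE)
  expect_equal(a$pixels, b$pixels, tolerance = 1e-8)

  small <- vt_image(matrix(0.5, 32, 32), ppd)
  expect_error(apply_filter(small, lo), "differ")
})

test_that("shape descriptors separate the two synthetic categories", {
  set <- demo_fixture()$set
  bank <- bank128()
  orig <- set$originals
  vecs <- t(vapply(orig, function(im) as.numeric(shape_gist(im, bank)),
                   numeric(64)))
  cats <- vapply(orig, function(im) im$category, character(1))
  cm <- cor(t(vecs))
  off <- upper.tri(cm)
  same <- outer(cats, cats, "==")
  expect_gt(mean(cm[off & same]), mean(cm[off & !same]))
})
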