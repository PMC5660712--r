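# fixture: a flat membrane patch of known area for density checks
flat_membrane <- function(nx = 84, nz = 8) {
  lab <- array(1L, c(nx, nx, nz)); lab[, , (nz / 2 + 1):nz] <- 2L
  extract_membrane(label_volume(lab, 6))
}

test_that("membrane labeling realizes the configured areal density", {
  m <- flat_membrane()
  # two flanking layers, each nx^2 voxels of 6 nm -> total area in um^2
  area_um2 <- sum(m$mask) * (6e-3)^2
  counts <- vapply(1:200, function(s)
    nrow(label_membranes(m, c(4000, 4000), jitter_sd = 0, seed = s)),
    numeric(1))
  expected <- 4000 * area_um2
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # Poisson: variance comparable to the mean
  expect_gt(var(counts), 0.5 * expected)
  expect_lt(var(counts), 2 * expected)
})

test_that("membrane labeling is seeded and respects emptiness and jitter", {
  m <- flat_membrane(36, 4)
  f1 <- label_membranes(m, c(5000, 5000), seed = 3)
  f2 <- label_membranes(m, c(5000, 5000), seed = 3)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_equal(nrow(label_membranes(m, c(0, 0), seed = 1)), 0)

  # realized displacement SD reproduces the configured localization accuracy:
  # all parent-1 membrane voxels of the flat fixture lie in one known z-plane
  f <- label_membranes(m, c(10000, 10000), jitter_sd = 20, seed = 5)
  z1 <- f$z[f$parent == 1L]
  plane <- (4 / 2 - 0.5) * 6
  expect_equal(mean(z1), plane, tolerance = 0.2)
  expect_equal(sd(z1), 20, tolerance = 0.1)
})

test_that("per-neuron density variation creates per-neuron brightness spread", {
  m <- flat_membrane(60, 6)
  n_per <- function(per) {
    f <- label_membranes(m, c(4000, 10000), per_neuron = per, seed = 11)
    tab <- table(factor(f$parent, c(1, 2)))
    abs(diff(as.vector(tab))) / sum(tab)
  }
  spread_on <- mean(vapply(1:20, function(s) {
    f <- label_membranes(m, c(4000, 10000), per_neuron = TRUE, seed = s)
    stats::sd(table(factor(f$parent, c(1, 2))))
  }, numeric(1)))
  spread_off <- mean(vapply(1:20, function(s) {
    f <- label_membranes(m, c(4000, 10000), per_neuron = FALSE, seed = s)
    stats::sd(table(factor(f$parent, c(1, 2))))
  }, numeric(1)))
  expect_gt(spread_on, spread_off)
})

test_that("volumetric labeling matches density, membership and emptiness", {
  lab <- array(1L, c(56, 56, 56))          # (0.336 um)^3
  lab[1:28, , ] <- 2L
  v <- label_volume(lab, 6)
  vol_um3 <- sum(lab == 2L) * (6e-3)^3
  counts <- vapply(1:200, function(s)
    nrow(label_volume_compartment(v, 2L, c(2000, 2000), seed = s)), numeric(1))
  expected <- 2000 * vol_um3
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 200))

  f <- label_volume_compartment(v, 2L, c(3000, 3000), seed = 9)
  vox <- floor(cbind(f$x, f$y, f$z) / 6) + 1
  expect_true(all(lab[vox] == 2L))         # membership oracle

  expect_equal(nrow(label_volume_compartment(v, 2L, c(0, 0), seed = 1)), 0)
})

test_that("puncta sigmas are uniform on the configured range", {
  m <- flat_membrane(120, 6)
  f <- label_membranes(m, c(9500, 9500), seed = 2)
  f <- apply_puncta(f, c(1, 48), seed = 3)
  expect_gte(nrow(f), 8000)
  ks <- suppressWarnings(stats::ks.test(f$sigma, "punif", 1, 48))
  expect_gt(ks$p.value, 0.01)
})

test_that("rasterization conserves per-point amplitude", {
  ext <- c(300, 300, 300)
  for (sg in c(0, 3, 20, 48)) {
    f <- fluorophore_field(data.frame(x = 151, y = 148, z = 150,
                                      amplitude = 2.5, channel = 1L,
                                      sigma = sg, parent = 1L), ext)
    vol <- rasterize_field(f, c(50, 50, 50), 6)
    expect_equal(sum(vol), 2.5, tolerance = 1e-3)
  }
})

test_that("brainbow mixtures are simplex points and channels follow them", {
  gt <- tiny_gt(c(24, 24, 24), count = 4, seed = 2)
  mix <- assign_brainbow_colors(gt, seed = 5)
  expect_equal(rowSums(mix), rep(1, 4), ignore_attr = TRUE)
  expect_identical(mix, assign_brainbow_colors(gt, seed = 5))

  # degenerate mixture (1, 0, 0) -> all points channel R
  f <- fluorophore_field(data.frame(x = runif(500, 0, 100), y = runif(500, 0, 100),
                                    z = runif(500, 0, 100), amplitude = 1,
                                    channel = 1L, sigma = 0, parent = 1L),
                         c(144, 144, 144))
  m1 <- matrix(c(1, 0, 0), 1, dimnames = list("1", NULL))
  expect_true(all(apply_color_mixture(f, m1, seed = 1)$channel == 1L))

  # multinomial about the mixture (chi-squared)
  n <- 10000
  f2 <- fluorophore_field(data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100),
                                     z = runif(n, 0, 100), amplitude = 1,
                                     channel = 1L, sigma = 0, parent = 1L),
                          c(144, 144, 144))
  mx <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list("1", NULL))
  ch <- apply_color_mixture(f2, mx, seed = 2)$channel
  p <- stats::chisq.test(table(factor(ch, 1:3)), p = c(0.5, 0.3, 0.2))$p.value
  expect_gt(p, 0.01)
})

test_that("barcodes look up their parent neuron and realize the density", {
  gt <- tiny_gt(c(50, 50, 50), count = 5, seed = 4)   # (0.3 um)^3
  bc <- place_barcodes(gt, 300, seed = 8)
  vox <- pmin(pmax(floor(cbind(bc$x, bc$y, bc$z) / 6) + 1, 1), 50)
  expect_identical(bc$identity, gt$labels[vox])        # lookup oracle
  expect_equal(nrow(place_barcodes(gt, 0, seed = 1)), 0)

  vol_um3 <- prod(dim(gt$labels)) * (6e-3)^3
  counts <- vapply(1:100, function(s) nrow(place_barcodes(gt, 300, seed = s)),
                   numeric(1))
  expected <- 300 * vol_um3
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 100))
})

test_that("noiseless rendering of a single on-grid punctum reproduces the PSF", {
  psf <- scale_psf(make_confocal_psf(pitch_nm = rep(120, 3)), 20)
  ext <- c(360, 360, 360)    # 60^3 voxels at 6 nm
  f <- fluorophore_field(data.frame(x = 183, y = 183, z = 183, amplitude = 1,
                                    channel = 1L, sigma = 0, parent = 1L), ext)
  st <- render_stack(f, psf, voxel_size = 6, z_step = 6, noise = FALSE)
  img <- st$data
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(31, 31, 31))
  # impulse-response oracle: direct PSF lookup around the peak
  k <- psf$intensity; kc <- (dim(k) + 1) %/% 2
  for (dx in -2:2) {
    expect_equal(img[31 + dx, 31, 31], k[kc[1] + dx, kc[2], kc[3]],
                 tolerance = 1e-6)
  }
})

test_that("noiseless rendering is linear in the fluorophore field", {
  psf <- scale_psf(make_confocal_psf(pitch_nm = rep(120, 3)), 20)
  ext <- c(240, 240, 240)
  mk <- function(seed) {
    set.seed(seed)
    n <- 40
    fluorophore_field(data.frame(x = runif(n, 30, 210), y = runif(n, 30, 210),
                                 z = runif(n, 30, 210), amplitude = runif(n, 0.5, 2),
                                 channel = 1L, sigma = runif(n, 0, 30),
                                 parent = 1L), ext)
  }
  f1 <- mk(1); f2 <- mk(2)
  r <- function(f) render_stack(f, psf, voxel_size = 6, z_step = 120,
                                noise = FALSE)$data
  expect_equal(r(bind_fields(f1, f2)), r(f1) + r(f2), tolerance = 1e-8)
})

test_that("noise model: empty field gives the read-noise floor, Poisson law holds", {
  psf <- scale_psf(make_confocal_psf(pitch_nm = rep(120, 3)), 20)
  ext <- c(180, 180, 180)
  empty <- fluorophore_field(NULL, ext)
  st <- render_stack(empty, psf, voxel_size = 6, z_step = 120,
                     snr_poisson_range = c(7, 7), snr_read_range = c(50, 50),
                     seed = 4)
  # clipped-at-zero Gaussian floor: mean close to sd/sqrt(2*pi)
  expect_lt(mean(st$data), 1)

  # Poisson variance ~ mean at a bright pixel over repeated renders
  f <- fluorophore_field(data.frame(x = 90, y = 90, z = 90, amplitude = 1,
                                    channel = 1L, sigma = 10, parent = 1L), ext)
  vals <- vapply(1:100, function(s) {
    render_stack(f, psf, voxel_size = 6, z_step = 120,
                 snr_poisson_range = c(10, 10), snr_read_range = c(1e6, 1e6),
                 seed = s)$data[15, 15, 1]
  }, numeric(1))
  expect_lt(abs(var(vals) / mean(vals) - 1), 0.35)
})

test_that("realized brightest-pixel SNRs land in the configured ranges", {
  gt <- tiny_gt(c(40, 40, 40), count = 3, seed = 6)
  psf <- scale_psf(make_confocal_psf(pitch_nm = rep(120, 3)), 20)
  f <- apply_puncta(label_membranes(extract_membrane(gt), seed = 1), seed = 2)
  st <- render_stack(f, psf, voxel_size = 6, z_step = 120, seed = 3)
  expect_gte(st$snr_poisson, 7); expect_lte(st$snr_poisson, 12)
  expect_gte(st$snr_read, 50); expect_lte(st$snr_read, 100)
  # seeded determinism end to end
  st2 <- render_stack(f, psf, voxel_size = 6, z_step = 120, seed = 3)
  expect_identical(st$data, st2$data)
})

test_that("rendering rejects an incompatible PSF pitch", {
  psf <- make_confocal_psf(pitch_nm = rep(120, 3))   # un-scaled: 120 nm pitch
  f <- fluorophore_field(NULL, c(120, 120, 120))
  expect_error(render_stack(f, psf, voxel_size = 6), "incompatible")
})
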