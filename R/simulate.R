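#' Fluorophore point field
#'
#' Continuous-coordinate set of fluorophore puncta.  Stored as a data.frame
#' with columns `x`, `y`, `z` (nm), `amplitude` (> 0), `channel` (1 = R,
#' 2 = G, 3 = B), `sigma` (per-point Gaussian cluster SD, nm) and `parent`
#' (ground-truth label the punctum belongs to; 0 for background).
#'
#' @param df data.frame with the columns above (missing optional columns are
#'   filled with defaults).
#' @param extent_nm physical extent of the parent volume, length 3 (nm).
#' @return object of class `fluorophore_field`.
#' @export
fluorophore_field <- function(df = NULL, extent_nm) {
  if (is.null(df) || nrow(df) == 0)
    df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                     amplitude = numeric(0), channel = integer(0),
                     sigma = numeric(0), parent = integer(0))
  if (is.null(df$amplitude)) df$amplitude <- rep(1, nrow(df))
  if (is.null(df$channel)) df$channel <- rep(1L, nrow(df))
  if (is.null(df$sigma)) df$sigma <- rep(0, nrow(df))
  if (is.null(df$parent)) df$parent <- rep(0L, nrow(df))
  if (any(df$amplitude <= 0)) stop("amplitudes must be > 0")
  structure(df, extent_nm = as.numeric(extent_nm),
            class = c("fluorophore_field", "data.frame"))
}

#' Concatenate fluorophore fields
#' @param ... `fluorophore_field` objects over the same volume.
#' @return combined `fluorophore_field`.
#' @export
bind_fields <- function(...) {
  fs <- list(...)
  fs <- fs[!vapply(fs, is.null, logical(1))]
  fluorophore_field(do.call(rbind, lapply(fs, as.data.frame)),
                    attr(fs[[1]], "extent_nm"))
}

#' Stochastic membrane labeling
#'
#' Places fluorophores near membrane voxels.  Each neuron draws its own areal
#' density uniformly from `density_range` (puncta per square micron of
#' membrane; membrane area is estimated as membrane-voxel count times the
#' voxel face area), counts are Poisson, and each punctum sits at a membrane
#' voxel center displaced by an isotropic Gaussian localization error
#' (`jitter_sd`, default 20 nm, the combined primary+secondary antibody
#' error sqrt(14^2 + 14^2)).
#'
#' @param mask a `membrane_mask` from [extract_membrane()].
#' @param density_range puncta per um^2; default the membrane row of the
#'   simulation parameter table, 4000-10000.
#' @param jitter_sd localization SD in nm (default 20).
#' @param per_neuron if TRUE (default) every neuron draws its own density,
#'   reproducing the dim-neuron/bright-neuron variability; if FALSE one draw
#'   is shared by all neurons.
#' @param seed optional integer seed.
#' @return a `fluorophore_field` (channel 1).
#' @export
label_membranes <- function(mask, density_range = c(4000, 10000),
                            jitter_sd = 20, per_neuron = TRUE, seed = NULL) {
  stopifnot(inherits(mask, "membrane_mask"))
  run <- function() {
    vs <- mask$voxel_size[1]
    face_um2 <- (vs * 1e-3)^2
    idx <- which(mask$mask)
    ext <- dim(mask$mask) * mask$voxel_size
    if (length(idx) == 0) return(fluorophore_field(NULL, ext))
    owner <- mask$owner[idx]
    labs <- sort(unique(owner))
    dens <- if (per_neuron) stats::runif(length(labs), density_range[1], density_range[2])
            else rep(stats::runif(1, density_range[1], density_range[2]), length(labs))
    out <- vector("list", length(labs))
    d3 <- dim(mask$mask)
    for (i in seq_along(labs)) {
      vox <- idx[owner == labs[i]]
      n <- stats::rpois(1, dens[i] * length(vox) * face_um2)
      if (n == 0) next
      pick <- vox[sample.int(length(vox), n, replace = TRUE)]
      ai <- arrayInd(pick, d3)
      pos <- (ai - 0.5) %*% diag(mask$voxel_size) +
             matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3)
      out[[i]] <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                             amplitude = 1, channel = 1L, sigma = 0,
                             parent = labs[i])
    }
    fluorophore_field(do.call(rbind, out), ext)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Volumetric compartment labeling (cytosol / background)
#'
#' Uniform random fluorophores inside a region of the volume, at a volumetric
#' density drawn uniformly from `density_range` (puncta per cubic micron);
#' counts are Poisson.  Models non-specific binding and autofluorescence
#' (background) or cytosolic label.
#'
#' @param volume a `label_volume`.
#' @param region either a label predicate `function(label) logical` or a
#'   vector of labels defining the region; default the whole volume.
#' @param density_range puncta per um^3 (cytosol default 2000-4000).
#' @param seed optional integer seed.
#' @return a `fluorophore_field` (channel 1; `parent` = voxel label).
#' @export
label_volume_compartment <- function(volume, region = NULL,
                                     density_range = c(2000, 4000),
                                     seed = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  run <- function() {
    d3 <- dim(volume$labels)
    ext <- d3 * volume$voxel_size
    sel <- if (is.null(region)) rep(TRUE, length(volume$labels))
           else if (is.function(region)) region(as.vector(volume$labels))
           else as.vector(volume$labels) %in% region
    idx <- which(sel)
    if (length(idx) == 0) return(fluorophore_field(NULL, ext))
    vol_um3 <- length(idx) * prod(volume$voxel_size * 1e-3)
    dens <- stats::runif(1, density_range[1], density_range[2])
    n <- stats::rpois(1, dens * vol_um3)
    if (n == 0) return(fluorophore_field(NULL, ext))
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    ai <- arrayInd(pick, d3)
    pos <- (ai - 1) %*% diag(volume$voxel_size) +
           matrix(stats::runif(3 * n), n, 3) %*% diag(volume$voxel_size)
    fluorophore_field(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                 amplitude = 1, channel = 1L, sigma = 0,
                                 parent = as.vector(volume$labels)[pick]),
                      ext)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Assign puncta cluster sizes
#'
#' Each fluorophore becomes a local cluster (punctum): it receives a Gaussian
#' spread SD drawn uniformly from `cluster_sd_range` (default 1-48 nm, the
#' local-cluster row of the parameter table).  Rasterization later spreads
#' the point's amplitude with that Gaussian.
#'
#' @param field a `fluorophore_field`.
#' @param cluster_sd_range nm, default c(1, 48).
#' @param seed optional integer seed.
#' @return the field with `sigma` filled in.
#' @export
apply_puncta <- function(field, cluster_sd_range = c(1, 48), seed = NULL) {
  stopifnot(inherits(field, "fluorophore_field"))
  run <- function() {
    field$sigma <- stats::runif(nrow(field), cluster_sd_range[1], cluster_sd_range[2])
    field
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Random BrainBow color mixtures per neuron
#'
#' Draws, for every neuron label, a random average color (a point on the RGB
#' simplex, uniform/Dirichlet(1,1,1)).  Use [apply_color_mixture()] to then
#' assign each fluorophore exactly one channel, multinomially according to
#' its neuron's mixture (channels mutually exclusive per punctum).
#'
#' @param volume a `label_volume`.
#' @param seed optional integer seed.
#' @return matrix `n_labels x 3`, rownames = label IDs, rows sum to 1.
#' @export
assign_brainbow_colors <- function(volume, seed = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  run <- function() {
    labs <- setdiff(sort(unique(as.vector(volume$labels))), 0L)
    g <- matrix(stats::rgamma(3 * length(labs), 1), ncol = 3)
    mix <- g / rowSums(g)
    rownames(mix) <- labs
    mix
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Assign one channel per fluorophore from per-neuron color mixtures
#'
#' @param field a `fluorophore_field` with `parent` labels.
#' @param mixtures matrix from [assign_brainbow_colors()].
#' @param seed optional integer seed.
#' @return the field with `channel` resampled; background (`parent` 0) points
#'   keep their channel.
#' @export
apply_color_mixture <- function(field, mixtures, seed = NULL) {
  stopifnot(inherits(field, "fluorophore_field"))
  run <- function() {
    for (lab in rownames(mixtures)) {
      sel <- field$parent == as.integer(lab)
      n <- sum(sel)
      if (n == 0) next
      field$channel[sel] <- sample.int(3L, n, replace = TRUE, prob = mixtures[lab, ])
    }
    field
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Random cell-identity barcodes
#'
#' Barcodes are uniformly distributed over the volume (including fine
#' processes) at the given volumetric density and are read out without error:
#' a barcode's integer identity is the ground-truth label of the neuron
#' containing it.  Points falling in unassigned (label 0) space are dropped.
#'
#' @param volume a `label_volume` (the ground truth).
#' @param density barcodes per um^3 (parameter-table range 5-300; the
#'   headline reconstruction uses 30).
#' @param seed optional integer seed.
#' @return object of class `barcode_set`: data.frame `x, y, z` (nm),
#'   `identity` (int), with attributes `density` and `extent_nm`.
#' @export
place_barcodes <- function(volume, density = 30, seed = NULL) {
  stopifnot(inherits(volume, "label_volume"), density >= 0)
  run <- function() {
    d3 <- dim(volume$labels)
    ext <- d3 * volume$voxel_size
    n <- stats::rpois(1, density * prod(ext * 1e-3))
    if (n == 0) {
      df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       identity = integer(0))
    } else {
      pos <- matrix(stats::runif(3 * n), n, 3) %*% diag(ext)
      vox <- pmin(pmax(floor(pos %*% diag(1 / volume$voxel_size)) + 1, 1),
                  matrix(d3, n, 3, byrow = TRUE))
      id <- volume$labels[cbind(vox[, 1], vox[, 2], vox[, 3])]
      df <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], identity = id)
      df <- df[df$identity > 0, , drop = FALSE]
      rownames(df) <- NULL
    }
    structure(df, density = density, extent_nm = ext,
              class = c("barcode_set", "data.frame"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Rasterize a fluorophore field onto the fine simulation grid
#'
#' Deposits every punctum's amplitude onto the grid with its per-point
#' Gaussian spread (separable weights normalized so each point's total
#' amplitude is conserved exactly).
#'
#' @param field a `fluorophore_field`.
#' @param shape_vox grid dimensions.
#' @param voxel_size nm per voxel (isotropic fine grid).
#' @param channel which channel to rasterize (default 1).
#' @return 3D numeric array of expected fluorophore mass per voxel.
#' @export
rasterize_field <- function(field, shape_vox, voxel_size = 6, channel = 1L) {
  sel <- field$channel == channel
  pts <- cbind(field$x[sel], field$y[sel], field$z[sel])
  array(cpp_rasterize_points(as.integer(shape_vox), voxel_size, pts,
                             field$amplitude[sel], field$sigma[sel]),
        shape_vox)
}

# FFT convolution with reflective padding; kernel must be odd-sized and is
# centered.  Returns array of the same size as vol.
fft_convolve <- function(vol, kernel) {
  d <- dim(vol); kd <- dim(kernel)
  rh <- kd %/% 2
  pad_idx <- lapply(1:3, function(a) {
    n <- d[a]; r <- min(rh[a], n - 1)
    c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  })
  pv <- vol[pad_idx[[1]], pad_idx[[2]], pad_idx[[3]], drop = FALSE]
  P <- dim(pv)
  kw <- array(0, P)
  ctr <- rh + 1
  # wrap kernel so its center sits at index (1,1,1)
  src <- lapply(1:3, function(a) seq_len(kd[a]))
  dst <- lapply(1:3, function(a) ((src[[a]] - ctr[a]) %% P[a]) + 1L)
  kw[dst[[1]], dst[[2]], dst[[3]]] <- kernel[src[[1]], src[[2]], src[[3]]]
  out <- Re(stats::fft(stats::fft(pv) * stats::fft(kw), inverse = TRUE)) / prod(P)
  r <- pmin(rh, d - 1)
  out[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3]), drop = FALSE]
}

#' Simulated confocal image stack
#'
#' @param data 3D array (single channel) or 4D (x, y, z, channel), photon
#'   counts.
#' @param xy_pitch,z_step sampling pitches in pre-expansion nm.
#' @param snr_poisson,snr_read realized brightest-pixel SNRs (per channel).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(data, xy_pitch, z_step, snr_poisson = NA, snr_read = NA) {
  stopifnot(all(data >= 0), xy_pitch > 0, z_step > 0)
  structure(list(data = data, xy_pitch = xy_pitch, z_step = z_step,
                 snr_poisson = snr_poisson, snr_read = snr_read),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %s, xy %g nm, z %g nm, SNR_p %s, SNR_r %s\n",
              paste(dim(x$data), collapse = " x "), x$xy_pitch, x$z_step,
              paste(signif(x$snr_poisson, 3), collapse = "/"),
              paste(signif(x$snr_read, 3), collapse = "/")))
  invisible(x)
}

#' Render a fluorophore field into a confocal image stack
#'
#' Forward optical model: (1) rasterize the puncta (with per-point Gaussian
#' spread) onto the fine isotropic grid; (2) convolve with the
#' expansion-scaled confocal PSF (frequency domain, reflective padding);
#' (3) sample the lateral grid at `xy_pitch` (= physical pitch / M /
#' expansion = 4.8 um / 40 / 20 = 6 nm) and one plane per `z_step` (default
#' 120 nm pre-expansion); (4) draw target brightest-pixel SNRs uniformly from
#' their ranges, scale so the brightest pixel's expected photon count is
#' `snr_poisson^2`, apply Poisson sampling, and add Gaussian read noise with
#' SD = brightest expected value / `snr_read`, clipping at 0.
#'
#' With `noise = FALSE` the raw expected intensities are returned without SNR
#' scaling, so noiseless rendering is linear in the field.
#'
#' @param field a `fluorophore_field` (all channels present are rendered).
#' @param psf a `psf_kernel` whose pitch matches the fine grid (after
#'   [scale_psf()]).
#' @param shape_vox fine-grid dimensions (defaults to the field's extent at
#'   `voxel_size`).
#' @param voxel_size fine-grid voxel size, nm (default 6).
#' @param xy_pitch,z_step sampling pitches, pre-expansion nm.
#' @param snr_poisson_range,snr_read_range brightest-pixel SNR ranges.
#' @param noise apply Poisson + read noise (default TRUE).
#' @param seed optional integer seed.
#' @return an `image_stack` (3D for one channel, 4D otherwise).
#' @export
render_stack <- function(field, psf, shape_vox = NULL, voxel_size = 6,
                         xy_pitch = 6, z_step = 120,
                         snr_poisson_range = c(7, 12),
                         snr_read_range = c(50, 100),
                         noise = TRUE, seed = NULL) {
  stopifnot(inherits(psf, "psf_kernel"))
  if (abs(xy_pitch - voxel_size) > 1e-9)
    stop("xy_pitch must equal the rasterization voxel size")
  if (max(abs(psf$voxel_pitch - voxel_size)) > 1e-6)
    stop("PSF pitch (", paste(signif(psf$voxel_pitch, 4), collapse = ", "),
         " nm) incompatible with the ", voxel_size, " nm rasterization grid; ",
         "use scale_psf()/resample_psf() first")
  ext <- attr(field, "extent_nm")
  if (is.null(shape_vox)) shape_vox <- as.integer(round(ext / voxel_size))
  ratio <- max(1L, as.integer(round(z_step / voxel_size)))
  nz_img <- max(1L, shape_vox[3] %/% ratio)   # one plane per complete z bin
  zsel <- pmin((seq_len(nz_img) - 1L) * ratio + ceiling(ratio / 2), shape_vox[3])
  run <- function() {
    chans <- sort(unique(field$channel))
    if (length(chans) == 0) chans <- 1L
    planes <- list(); sp <- numeric(0); sr <- numeric(0)
    for (ch in chans) {
      fine <- rasterize_field(field, shape_vox, voxel_size, ch)
      img <- fft_convolve(fine, psf$intensity)
      img <- img[, , zsel, drop = FALSE]
      img[img < 0] <- 0
      if (noise) {
        snr_p <- stats::runif(1, snr_poisson_range[1], snr_poisson_range[2])
        snr_r <- stats::runif(1, snr_read_range[1], snr_read_range[2])
        mx <- max(img)
        if (mx > 0) img <- img * (snr_p^2 / mx)
        read_sd <- snr_p^2 / snr_r
        img <- array(stats::rpois(length(img), img), dim(img)) +
               array(stats::rnorm(length(img), 0, read_sd), dim(img))
        img[img < 0] <- 0
        sp <- c(sp, snr_p); sr <- c(sr, snr_r)
      } else {
        sp <- c(sp, NA); sr <- c(sr, NA)
      }
      planes[[as.character(ch)]] <- img
    }
    data <- if (length(planes) == 1) planes[[1]] else
      array(unlist(planes), c(dim(planes[[1]]), length(planes)))
    image_stack(data, xy_pitch, z_step, sp, sr)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
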