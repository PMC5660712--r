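#' Scalar Debye diffraction field of a high-NA objective
#'
#' Evaluates the classical scalar Debye integral for an aberration-free
#' circular-aperture objective,
#' \deqn{U(v,u) = \frac{2\pi i}{\lambda} \int_0^\alpha P(\theta)\,
#'   J_0\!\left(v\,\frac{\sin\theta}{\sin\alpha}\right)
#'   \exp\!\left(i u\,\frac{\sin^2(\theta/2)}{2\sin^2(\alpha/2)}\right)
#'   \sin\theta\, d\theta,}
#' at normalized radial coordinates `v = k r sin(alpha)` and normalized axial
#' coordinates `u = 4 k z sin^2(alpha/2)`, with `k = 2 pi n / lambda` and
#' `alpha = asin(NA/n)`.  The constant on-axis phase factor is dropped (it
#' does not affect intensity).  Quadrature is fixed-order Gauss-Legendre with
#' the order doubled until the field changes by less than `tol`.
#'
#' @param na numerical aperture (0 < NA < n).
#' @param wavelength wavelength in nm.
#' @param v_grid,u_grid numeric vectors of normalized radial/axial coords; the
#'   field is returned on their outer product grid.
#' @param n_immersion immersion refractive index (default 1.33, water-dipped
#'   objective into an expanded hydrogel).
#' @param apodization function of theta; default aplanatic `sqrt(cos(theta))`.
#' @param tol convergence tolerance on max |U| change when doubling the
#'   quadrature order.
#' @return complex matrix `length(v_grid) x length(u_grid)`.
#' @export
debye_field <- function(na, wavelength, v_grid, u_grid,
                        n_immersion = 1.33,
                        apodization = function(theta) sqrt(cos(theta)),
                        tol = 1e-6) {
  if (na <= 0 || na >= n_immersion)
    stop("need 0 < NA < immersion index")
  if (!all(is.finite(v_grid)) || !all(is.finite(u_grid)))
    stop("grids must be finite")
  alpha <- asin(na / n_immersion)
  eval_order <- function(m) {
    gl <- gauss_legendre(m, 0, alpha)
    th <- gl$nodes; w <- gl$weights
    s <- sin(th)
    amp <- w * apodization(th) * s                    # quadrature x apodization
    jb <- outer(v_grid, s / sin(alpha), function(v, q) besselJ(abs(v * q), 0))
    ax <- exp(1i * outer(sin(th / 2)^2 / (2 * sin(alpha / 2)^2), u_grid))
    (2 * pi / wavelength) * ((jb * rep(amp, each = length(v_grid))) %*% ax)
  }
  m <- 32L
  U <- eval_order(m)
  repeat {
    U2 <- eval_order(2L * m)
    if (max(abs(U2 - U)) <= tol * max(abs(U2), 1e-300)) return(U2)
    U <- U2
    m <- 2L * m
    if (m > 4096L) stop("Debye quadrature did not converge (order > 4096); ",
                        "max change ", format(max(abs(U2 - U))))
  }
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch via symmetric
# tridiagonal eigen-decomposition).
gauss_legendre <- function(m, a, b) {
  i <- seq_len(m - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, m, m)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * nodes + (a + b) / 2,
       weights = (b - a) / 2 * weights)
}

#' Confocal point-spread-function kernel
#'
#' Samples excitation and emission Debye fields on a 3D voxel grid and forms
#' the confocal PSF under an ideal (point) pinhole: intensity =
#' |U_ex|^2 * |U_em|^2, normalized to unit sum.  Support is truncated at
#' twice the FWHM on each side of the peak per axis (total width 4 x FWHM)
#' and renormalized.
#'
#' @param na numerical aperture (default 1.15).
#' @param wavelength_ex,wavelength_em excitation/emission wavelengths in nm
#'   (defaults 561/590, red membrane channel).
#' @param pitch_nm physical (optical-side) voxel pitch `(dx, dy, dz)` in nm at
#'   which the fields are sampled.
#' @param n_immersion immersion index (default 1.33).
#' @param expansion_factor recorded on the kernel; see [scale_psf()].
#' @param support_fwhm support half-width per axis in units of that axis'
#'   FWHM (default 2).
#' @return An object of class `psf_kernel`: list with `intensity` (3D array,
#'   unit sum), `voxel_pitch` nm, wavelengths, `na`, `expansion_factor`.
#' @export
make_confocal_psf <- function(na = 1.15, wavelength_ex = 561,
                              wavelength_em = 590, pitch_nm = c(120, 120, 120),
                              n_immersion = 1.33, expansion_factor = 1,
                              support_fwhm = 2) {
  if (length(pitch_nm) == 1) pitch_nm <- rep(pitch_nm, 3)
  alpha <- asin(na / n_immersion)
  k_ex <- 2 * pi * n_immersion / wavelength_ex
  k_em <- 2 * pi * n_immersion / wavelength_em
  conf_int <- function(r_nm, z_nm) {
    vx <- k_ex * r_nm * sin(alpha); ux <- 4 * k_ex * z_nm * sin(alpha / 2)^2
    vm <- k_em * r_nm * sin(alpha); um <- 4 * k_em * z_nm * sin(alpha / 2)^2
    iex <- abs(diag_field(na, wavelength_ex, vx, ux, n_immersion))^2
    iem <- abs(diag_field(na, wavelength_em, vm, um, n_immersion))^2
    iex * iem
  }
  # 1D profiles to size the support
  fw <- confocal_fwhm_nm(na, wavelength_ex, wavelength_em, n_immersion)
  half <- pmax(1L, as.integer(ceiling(support_fwhm * c(fw$lateral, fw$lateral, fw$axial) / pitch_nm)))
  xs <- (-half[1]:half[1]) * pitch_nm[1]
  ys <- (-half[2]:half[2]) * pitch_nm[2]
  zs <- (-half[3]:half[3]) * pitch_nm[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  r <- sqrt(g$x^2 + g$y^2)
  inten <- array(conf_int(r, g$z), c(length(xs), length(ys), length(zs)))
  inten <- inten / sum(inten)
  structure(list(intensity = inten, voxel_pitch = as.numeric(pitch_nm),
                 wavelength_ex = wavelength_ex, wavelength_em = wavelength_em,
                 na = na, n_immersion = n_immersion,
                 expansion_factor = expansion_factor),
            class = "psf_kernel")
}

# Evaluate the Debye field at paired (v, u) coordinates (not the outer grid).
diag_field <- function(na, wavelength, v, u, n_immersion) {
  uu <- sort(unique(u))
  out <- complex(length(v))
  for (uval in uu) {
    sel <- u == uval
    out[sel] <- debye_field(na, wavelength, v[sel], uval, n_immersion)[, 1]
  }
  out
}

#' Lateral and axial FWHM of the confocal PSF, in nm
#'
#' Computed from finely sampled on-axis profiles of the confocal intensity
#' with linear interpolation at half maximum.
#'
#' @inheritParams make_confocal_psf
#' @return list with `lateral` and `axial` FWHM in nm (optical-side units).
#' @export
confocal_fwhm_nm <- function(na = 1.15, wavelength_ex = 561, wavelength_em = 590,
                             n_immersion = 1.33) {
  alpha <- asin(na / n_immersion)
  k_ex <- 2 * pi * n_immersion / wavelength_ex
  k_em <- 2 * pi * n_immersion / wavelength_em
  # generous search ranges scaled by diffraction estimates
  r <- seq(0, 2 * wavelength_em / na, length.out = 600)
  z <- seq(0, 8 * wavelength_em / (n_immersion * (1 - cos(alpha))), length.out = 600)
  ilat <- abs(debye_field(na, wavelength_ex, k_ex * r * sin(alpha), 0, n_immersion)[, 1])^2 *
          abs(debye_field(na, wavelength_em, k_em * r * sin(alpha), 0, n_immersion)[, 1])^2
  iax <- abs(debye_field(na, wavelength_ex, 0, 4 * k_ex * z * sin(alpha / 2)^2, n_immersion)[1, ])^2 *
         abs(debye_field(na, wavelength_em, 0, 4 * k_em * z * sin(alpha / 2)^2, n_immersion)[1, ])^2
  list(lateral = 2 * half_crossing(r, ilat), axial = 2 * half_crossing(z, iax))
}

# first crossing of profile below half its value at x = 0, linearly interpolated
half_crossing <- function(x, y) {
  h <- y[1] / 2
  i <- which(y < h)[1]
  if (is.na(i)) return(NA_real_)
  x[i - 1] + (x[i] - x[i - 1]) * (y[i - 1] - h) / (y[i - 1] - y[i])
}

#' FWHM of a sampled PSF kernel along each axis
#'
#' Profile through the peak voxel with linear interpolation at half maximum,
#' in the kernel's own pitch units (nm).
#'
#' @param psf a `psf_kernel`.
#' @return length-3 numeric FWHM (nm), in the kernel's (possibly
#'   expansion-scaled) units.
#' @export
psf_fwhm <- function(psf) {
  d <- dim(psf$intensity)
  ctr <- (d + 1) %/% 2
  out <- numeric(3)
  for (a in 1:3) {
    idx <- as.list(ctr)
    idx[[a]] <- seq_len(d[a])
    prof <- do.call(`[`, c(list(psf$intensity), idx))
    x <- (seq_len(d[a]) - ctr[a]) * psf$voxel_pitch[a]
    right <- half_crossing(x[x >= 0], prof[x >= 0])
    left <- half_crossing(-rev(x[x <= 0]), rev(prof[x <= 0]))
    out[a] <- left + right
  }
  out
}

#' Combine excitation and emission intensity fields into a confocal PSF
#'
#' Ideal-pinhole confocal model: the detected intensity is the voxelwise
#' product of the excitation and emission intensity PSFs, renormalized to
#' unit sum.
#'
#' @param excitation,emission `psf_kernel` objects (or plain intensity
#'   arrays) on the same grid.
#' @return a `psf_kernel` with the combined intensity.
#' @export
confocal_psf <- function(excitation, emission) {
  iex <- if (inherits(excitation, "psf_kernel")) excitation$intensity else excitation
  iem <- if (inherits(emission, "psf_kernel")) emission$intensity else emission
  if (!identical(dim(iex), dim(iem))) stop("excitation/emission grids differ")
  out <- if (inherits(excitation, "psf_kernel")) excitation else
    structure(list(voxel_pitch = c(1, 1, 1), expansion_factor = 1),
              class = "psf_kernel")
  out$intensity <- iex * iem / sum(iex * iem)
  out
}

#' Apply the expansion-factor rescaling to a PSF
#'
#' Expansion microscopy is modeled by shrinking the PSF rather than expanding
#' the specimen: the voxel pitch is divided by the expansion factor while the
#' sampled intensity array (and its normalization) is unchanged.
#'
#' @param psf a `psf_kernel`.
#' @param expansion_factor linear expansion factor (>= 1), default 20.
#' @return the rescaled `psf_kernel` (pitch now in pre-expansion sample nm).
#' @export
scale_psf <- function(psf, expansion_factor = 20) {
  stopifnot(inherits(psf, "psf_kernel"), expansion_factor >= 1)
  psf$voxel_pitch <- psf$voxel_pitch / expansion_factor
  psf$expansion_factor <- expansion_factor
  psf
}

#' Resample a PSF kernel onto a new voxel pitch
#'
#' Each target voxel integrates the trilinearly interpolated intensity over
#' its footprint (supersampled 3x per axis), scaled by the sub-voxel volume,
#' so total intensity is conserved to well under 0.5%; the result is then
#' renormalized to unit sum.
#'
#' @param psf a `psf_kernel`.
#' @param new_pitch length-3 (or scalar) target pitch in nm.
#' @param renormalize logical; set `FALSE` to inspect raw conservation.
#' @return a `psf_kernel` on the new grid.
#' @export
resample_psf <- function(psf, new_pitch, renormalize = TRUE) {
  if (length(new_pitch) == 1) new_pitch <- rep(new_pitch, 3)
  d <- dim(psf$intensity)
  ctr <- (d + 1) / 2
  half_ext <- (d - 1) / 2 * psf$voxel_pitch
  nd <- pmax(1L, as.integer(ceiling(half_ext / new_pitch)) * 2L + 1L)
  m <- 3L                                    # supersampling per axis
  sub <- (seq_len(m) - (m + 1) / 2) / m      # offsets within a target voxel
  ax <- lapply(1:3, function(a) {
    centers <- (seq_len(nd[a]) - (nd[a] + 1) / 2)
    as.vector(outer(sub, centers, "+")) * new_pitch[a] / psf$voxel_pitch[a] + ctr[a]
  })
  fine <- trilinear(psf$intensity, ax[[1]], ax[[2]], ax[[3]])
  # aggregate the m^3 sub-samples of each target voxel
  out <- array(0, nd)
  for (a in seq_len(m)) for (b in seq_len(m)) for (cc in seq_len(m))
    out <- out + fine[seq(a, by = m, length.out = nd[1]),
                      seq(b, by = m, length.out = nd[2]),
                      seq(cc, by = m, length.out = nd[3]), drop = FALSE]
  out <- out * prod(new_pitch) / prod(psf$voxel_pitch) / m^3
  if (renormalize) out <- out / sum(out)
  psf$intensity <- out
  psf$voxel_pitch <- as.numeric(new_pitch)
  psf
}

# trilinear interpolation of arr at the grid xq x yq x zq (index coords)
trilinear <- function(arr, xq, yq, zq) {
  d <- dim(arr)
  # zero-pad by one voxel so out-of-range queries interpolate against zero
  pd <- array(0, d + 2L)
  pd[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- arr
  cl <- function(v, n) pmin(pmax(v, 0), n + 1) + 1
  xq <- cl(xq, d[1]); yq <- cl(yq, d[2]); zq <- cl(zq, d[3])
  x0 <- pmin(floor(xq), d[1] + 1); x1 <- x0 + 1; fx <- xq - x0
  y0 <- pmin(floor(yq), d[2] + 1); y1 <- y0 + 1; fy <- yq - y0
  z0 <- pmin(floor(zq), d[3] + 1); z1 <- z0 + 1; fz <- zq - z0
  out <- array(0, c(length(xq), length(yq), length(zq)))
  for (iz in seq_along(zq)) {
    w0 <- pd[, , z0[iz]] * (1 - fz[iz]) + pd[, , z1[iz]] * fz[iz]
    sx <- w0[x0, , drop = FALSE] * (1 - fx) + w0[x1, , drop = FALSE] * fx
    out[, , iz] <- sx[, y0, drop = FALSE] * rep(1 - fy, each = length(xq)) +
                   sx[, y1, drop = FALSE] * rep(fy, each = length(xq))
  }
  out
}

#' @export
print.psf_kernel <- function(x, ...) {
  cat(sprintf("psf_kernel: %s samples, pitch (%g, %g, %g) nm, NA %g, ex/em %g/%g nm, expansion %gx\n",
              paste(dim(x$intensity), collapse = " x "),
              x$voxel_pitch[1], x$voxel_pitch[2], x$voxel_pitch[3],
              x$na, x$wavelength_ex, x$wavelength_em, x$expansion_factor))
  invisible(x)
}
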