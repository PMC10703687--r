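# Synthetic multi-channel receive arrays: helmet loop geometries, quasi-static
# loop-field sensitivities, channel noise covariance, optimal-combination SNR
# maps and SENSE retained-SNR (1/g) maps.

# rows-of-loops layouts per supported channel count (top row first; the last
# entry is the rim band covering the remainder of the helmet)
.helmet_layouts <- list(
  `8` = c(1, 3, 4),
  `32` = c(4, 6, 8, 14),
  `64` = c(8, 12, 16, 28),
  `96` = c(12, 18, 24, 42),
  `128` = c(16, 24, 32, 56)
)

#' Build a helmet receive-array geometry
#'
#' Loops are arranged in rows of increasing polar angle on an ellipsoidal
#' helmet surface (e.g. a 96-channel layout of 12/18/24 loops in the top
#' three rows with the remaining 42 in the rim band).  Loop radius shrinks
#' as channel count grows (roughly 4 cm diameter loops at 64-96 channels).
#' Deterministic for a given seed (the seed sets small per-row azimuthal
#' offsets).
#'
#' @param n_channels one of 8, 32, 64, 96, 128.
#' @param semi_axes_mm helmet ellipsoid semi-axes (x, y, z), mm.
#' @param seed integer seed.
#' @return object of class `coil_array_geometry`: `centers` (n x 3, mm),
#'   `radii` (mm), `normals` (n x 3, unit), `semi_axes_mm`, `n_channels`.
#' @export
build_helmet_array <- function(n_channels, semi_axes_mm = c(110, 125, 110),
                               seed = 1L) {
  key <- as.character(n_channels)
  if (!key %in% names(.helmet_layouts))
    stop(sprintf("unsupported channel count %s (supported: %s)", key,
                 paste(names(.helmet_layouts), collapse = ", ")))
  layout <- .helmet_layouts[[key]]
  set.seed(seed)
  thetas <- seq(0.32, 1.75, length.out = length(layout)) # rad, pole to rim
  # equal-area tiling with overlap: loop radius ~ sqrt(covered surface / n),
  # giving ~4 cm loops at 96 channels and ~6 cm at 32
  r_eff <- mean(semi_axes_mm)
  area <- 2 * pi * r_eff^2 * (1 - cos(max(thetas))) # covered cap area
  loop_r <- 1.15 * sqrt(area / (pi * n_channels))
  centers <- NULL; normals <- NULL
  for (k in seq_along(layout)) {
    nk <- layout[k]
    phi0 <- stats::runif(1, 0, 2 * pi)
    phis <- phi0 + 2 * pi * (seq_len(nk) - 1) / nk
    d <- cbind(sin(thetas[k]) * cos(phis),
               sin(thetas[k]) * sin(phis),
               cos(thetas[k]))
    ctr <- sweep(d, 2, semi_axes_mm, `*`)
    nrm <- sweep(d, 2, semi_axes_mm, `/`)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    centers <- rbind(centers, ctr)
    normals <- rbind(normals, nrm)
  }
  radii <- rep(loop_r, n_channels)
  structure(list(centers = centers, radii = radii, normals = normals,
                 semi_axes_mm = semi_axes_mm,
                 n_channels = as.integer(n_channels), seed = seed),
            class = "coil_array_geometry")
}

#' @export
print.coil_array_geometry <- function(x, ...) {
  cat(sprintf(
    "Helmet array: %d channels, loop radius %.1f-%.1f mm, ellipsoid %s mm\n",
    x$n_channels, min(x$radii), max(x$radii),
    paste(x$semi_axes_mm, collapse = " x ")))
  invisible(x)
}

# orthonormal in-plane basis for a unit normal
.loop_basis <- function(n) {
  a <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Quasi-static receive sensitivities of a loop array
#'
#' Evaluates each loop's Biot-Savart field on a voxel grid (unit current,
#' arbitrary units) and forms the complex receive sensitivity
#' `S = Bx - i By`.  The magnitude decays monotonically with distance along
#' the loop axis; phase varies with loop orientation.
#'
#' @param geom a [build_helmet_array()] geometry.
#' @param grid a list with `x`, `y`, `z` voxel-centre coordinate vectors
#'   (mm), or a `phantom` object (its grid is used).
#' @param n_segments loop discretization.
#' @param min_dist_mm voxels closer than this to a loop conductor are an
#'   error (field singularity).
#' @return object of class `sensitivity_set`: `values` (channels x voxels
#'   complex matrix), `dim`, `grid`.
#' @export
sensitivities <- function(geom, grid, n_segments = 24, min_dist_mm = 1) {
  stopifnot(inherits(geom, "coil_array_geometry"))
  if (inherits(grid, "phantom"))
    grid <- grid$grid
  gx <- grid$x; gy <- grid$y; gz <- grid$z
  dims <- c(length(gx), length(gy), length(gz))
  pts <- cbind(rep(gx, times = dims[2] * dims[3]),
               rep(rep(gy, each = dims[1]), times = dims[3]),
               rep(gz, each = dims[1] * dims[2]))
  nvox <- nrow(pts)
  nch <- geom$n_channels
  vals <- matrix(0 + 0i, nch, nvox)
  ang <- 2 * pi * (seq_len(n_segments) - 0.5) / n_segments
  for (ch in seq_len(nch)) {
    ctr <- geom$centers[ch, ]; rad <- geom$radii[ch]
    basis <- .loop_basis(geom$normals[ch, ])
    # segment midpoints and tangent elements of the discretized loop
    pm <- matrix(ctr, n_segments, 3, byrow = TRUE) +
      rad * (outer(cos(ang), basis$e1) + outer(sin(ang), basis$e2))
    dl <- rad * (2 * pi / n_segments) *
      (-outer(sin(ang), basis$e1) + outer(cos(ang), basis$e2))
    bx <- numeric(nvox); by <- numeric(nvox)
    for (s in seq_len(n_segments)) {
      rx <- pts[, 1] - pm[s, 1]
      ry <- pts[, 2] - pm[s, 2]
      rz <- pts[, 3] - pm[s, 3]
      r2 <- rx^2 + ry^2 + rz^2
      if (any(r2 < min_dist_mm^2))
        stop("grid voxel intersects a loop conductor; shrink the grid")
      inv_r3 <- 1 / (r2 * sqrt(r2))
      # dl x r, x and y components
      bx <- bx + (dl[s, 2] * rz - dl[s, 3] * ry) * inv_r3
      by <- by + (dl[s, 3] * rx - dl[s, 1] * rz) * inv_r3
    }
    vals[ch, ] <- complex(real = bx, imaginary = -by)
  }
  # scale to O(1) units
  vals <- vals / stats::median(Mod(vals[Mod(vals) > 0]))
  structure(list(values = vals, dim = dims, grid = grid),
            class = "sensitivity_set")
}

#' Channel noise covariance of an array
#'
#' `Psi = sigma^2 (I + coupling_scale * K)` with an overlap kernel
#' `K_ij = exp(-d_ij^2 / (2 rho^2))` on the inter-loop centre distances
#' (rho: twice the mean loop radius), eigenvalue-floored to stay positive
#' definite.
#'
#' @param geom a [build_helmet_array()] geometry.
#' @param coupling_scale off-diagonal coupling strength (0 = i.i.d.).
#' @param sigma per-channel noise standard deviation.
#' @return Hermitian positive-definite channels x channels matrix.
#' @export
noise_cov <- function(geom, coupling_scale = 0.25, sigma = 1) {
  stopifnot(inherits(geom, "coil_array_geometry"))
  d <- unname(as.matrix(stats::dist(geom$centers)))
  rho <- 2 * mean(geom$radii)
  k <- exp(-d^2 / (2 * rho^2))
  diag(k) <- 0
  psi <- sigma^2 * (diag(geom$n_channels) + coupling_scale * k)
  psi <- (psi + t(psi)) / 2
  ev <- eigen(psi, symmetric = TRUE)
  floor_ev <- 1e-6 * max(ev$values)
  if (min(ev$values) < floor_ev)
    psi <- ev$vectors %*% diag(pmax(ev$values, floor_ev)) %*% t(ev$vectors)
  psi
}

#' Optimal-combination SNR map
#'
#' Per voxel, the noise-covariance-weighted optimal (matched-filter) coil
#' combination yields `SNR = sqrt(S^H Psi^-1 S)` up to a global scale.
#'
#' @param s a [sensitivities()] set.
#' @param psi channel noise covariance.
#' @return array of relative SNR on the sensitivity grid.
#' @export
snr_map <- function(s, psi) {
  stopifnot(inherits(s, "sensitivity_set"))
  if (nrow(psi) != nrow(s$values)) stop("psi/sensitivity dimensions disagree")
  pis <- solve(psi, s$values)
  v <- sqrt(Re(colSums(Conj(s$values) * pis)))
  array(v, dim = s$dim)
}

#' EPI sampling pattern for parallel imaging
#'
#' @param r_pe in-plane (phase-encode) acceleration.
#' @param sms simultaneous-multislice factor.
#' @param caipi_shift integer CAIPI shift index: adjacent excited slices are
#'   shifted by `caipi_shift/sms` of the phase-encode FOV; must be < `sms`.
#' @return object of class `sampling_pattern`.
#' @export
sampling_pattern <- function(r_pe = 1L, sms = 1L, caipi_shift = 0L) {
  r_pe <- as.integer(r_pe); sms <- as.integer(sms)
  caipi_shift <- as.integer(caipi_shift)
  if (r_pe < 1 || sms < 1) stop("accelerations must be integers >= 1")
  if (caipi_shift < 0 || caipi_shift >= sms)
    stop("caipi_shift must be a non-negative integer < sms")
  structure(list(r_pe = r_pe, sms = sms, caipi_shift = caipi_shift),
            class = "sampling_pattern")
}

#' Retained-SNR (1/g) map for an accelerated acquisition
#'
#' SENSE noise-amplification algebra over each aliasing set A (in-plane
#' folding along y crossed with SMS slice collapsing, CAIPI-shifted):
#' `g_j = sqrt([(S_A^H Psi^-1 S_A)^-1]_jj [S_A^H Psi^-1 S_A]_jj) >= 1`.
#' Returns `1/g` in (0, 1]; rank-deficient sets give `1/g = 0` and set the
#' `rank_deficient` attribute.
#'
#' @param s a [sensitivities()] set; phase encode along the grid's y axis,
#'   slices along z.
#' @param psi channel noise covariance.
#' @param pat a [sampling_pattern()]; the grid's y extent must be divisible
#'   by `r_pe` and by `sms` (for the CAIPI shift), z by `sms`.
#' @return array of 1/g on the grid, attribute `rank_deficient` (count).
#' @export
retained_snr_map <- function(s, psi, pat) {
  stopifnot(inherits(s, "sensitivity_set"), inherits(pat, "sampling_pattern"))
  d <- s$dim
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  r <- pat$r_pe; sms <- pat$sms
  if (ny %% r != 0 || nz %% sms != 0 || (ny * pat$caipi_shift) %% sms != 0)
    stop("grid dimensions must be divisible by the accelerations")
  inv_g <- array(NA_real_, d)
  psi_chol <- chol(psi)
  # whiten once: g depends on S through Psi^-1 only (inverse lower-triangular
  # factor applied explicitly; backsolve would drop the imaginary part)
  inv_lt <- backsolve(psi_chol, diag(nrow(psi)), transpose = TRUE)
  sw <- inv_lt %*% s$values
  dim(sw) <- c(nrow(psi), d)
  n_bad <- 0L
  na <- r * sms
  dy <- ny %/% r
  shift <- (ny * pat$caipi_shift) %/% sms
  for (z0 in seq_len(nz %/% sms)) {
    zs <- z0 + (0:(sms - 1)) * (nz %/% sms)
    for (y0 in seq_len(dy)) {
      for (x in seq_len(nx)) {
        # aliasing set: for SMS slice m, the in-plane fold positions are
        # CAIPI-shifted by m*shift
        ys <- outer(y0 + (0:(r - 1)) * dy, (0:(sms - 1)) * shift, `+`)
        ys <- ((ys - 1) %% ny) + 1
        sa <- matrix(0 + 0i, nrow(psi), na)
        idx <- 1L
        coords <- matrix(0L, na, 3)
        for (m in seq_len(sms)) for (k in seq_len(r)) {
          sa[, idx] <- sw[, x, ys[k, m], zs[m]]
          coords[idx, ] <- c(x, ys[k, m], zs[m])
          idx <- idx + 1L
        }
        mmat <- crossprod(Conj(sa), sa)
        inv_m <- tryCatch(solve(mmat), error = function(e) NULL)
        if (is.null(inv_m) || any(!is.finite(Re(diag(inv_m))))) {
          n_bad <- n_bad + 1L
          vals <- rep(0, na)
        } else {
          g <- sqrt(pmax(Re(diag(inv_m)) * Re(diag(mmat)), 1))
          vals <- 1 / g
        }
        for (j in seq_len(na))
          inv_g[coords[j, 1], coords[j, 2], coords[j, 3]] <- vals[j]
      }
    }
  }
  structure(inv_g, rank_deficient = n_bad)
}

#' Central / peripheral split of a brain mask
#'
#' Voxels whose normalized distance from the mask centroid is below
#' `inner_frac` of the mask's maximal radius form the central ROI, the rest
#' the peripheral ROI.
#'
#' @param mask logical 3D array.
#' @param grid list of `x`, `y`, `z` coordinates (mm).
#' @param inner_frac central fraction of the radius (default 0.4).
#' @return list of logical arrays `central` and `peripheral`.
#' @export
roi_split <- function(mask, grid, inner_frac = 0.4) {
  d <- dim(mask)
  pts <- cbind(rep(grid$x, times = d[2] * d[3]),
               rep(rep(grid$y, each = d[1]), times = d[3]),
               rep(grid$z, each = d[1] * d[2]))
  inb <- as.vector(mask)
  ctr <- colMeans(pts[inb, , drop = FALSE])
  rr <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  rmax <- max(rr[inb])
  central <- array(inb & rr <= inner_frac * rmax, d)
  peripheral <- array(inb & rr > inner_frac * rmax, d)
  list(central = central, peripheral = peripheral)
}
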