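# Synthetic ground-truth specimens: bead fields on a coverslip,
# microtubule-like filament networks, and ER-like tubule/sheet networks.
# All generators are pure functions of their parameters and a seed.
# Coordinates are sample-space nm with the origin at the volume corner and
# z increasing away from the coverslip.

#' A set of point emitters (fluorescent beads)
#'
#' @param positions n x 3 matrix of (x, y, z) positions in nm.
#' @param brightness Expected photons per emitter per unit exposure.
#' @param diameter Physical emitter size (nm); 100 nm beads by default.
#' @param bounds Declared volume extents `c(x, y, z)` in nm.
#' @return Object of class `emitter_set`.
#' @export
emitter_set <- function(positions, brightness = 1000, diameter = 100,
                        bounds = NULL) {
  positions <- matrix(positions, ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  if (brightness <= 0) stop("brightness must be positive")
  if (!is.null(bounds)) {
    for (j in 1:3) {
      if (any(positions[, j] < 0 | positions[, j] > bounds[j]))
        stop("emitter positions outside the declared bounds")
    }
  }
  structure(list(positions = positions, brightness = brightness,
                 diameter = diameter, bounds = bounds),
            class = "emitter_set")
}

#' Random bead field with a minimum separation
#'
#' Draws `n` emitter positions uniformly in `bounds`, rejecting candidates
#' closer than `min_sep` to an accepted bead (dart throwing). Emulates
#' dilute 100 nm fluorescent beads dried on a coverslip; pass a thin z
#' extent (or `bounds[3] = 0`) for a coverslip preparation.
#'
#' @param n Number of beads (>= 1).
#' @param bounds Volume extents `c(x, y, z)` in nm.
#' @param min_sep Minimum pairwise distance (nm).
#' @param seed Integer seed; the same seed reproduces the same field.
#' @param brightness,diameter Passed to [emitter_set()].
#' @param margin Keep-out distance from the lateral volume faces (nm).
#' @param max_tries Rejection-sampling budget per bead before a packing
#'   error is raised.
#' @param snap_nm Optional lateral grid pitch (nm): accepted positions are
#'   snapped to multiples of it. Use the sample-space pixel size when the
#'   field is meant for PSF/FWHM characterization, so the measured width
#'   reflects the optics rather than sub-voxel rasterization spread.
#' @return An `emitter_set` with exactly `n` emitters.
#' @export
make_bead_field <- function(n, bounds, min_sep = 0, seed = 1,
                            brightness = 1000, diameter = 100,
                            margin = 0, max_tries = 5000, snap_nm = NULL) {
  stopifnot(n >= 1, min_sep >= 0, all(bounds >= 0))
  lo <- c(margin, margin, 0)
  hi <- c(bounds[1] - margin, bounds[2] - margin, bounds[3])
  if (any(hi < lo)) stop("margin larger than bounds")
  pos <- with_seed(seed, {
    p <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- lo + stats::runif(3) * (hi - lo)
        if (!is.null(snap_nm)) cand[1:2] <- round(cand[1:2] / snap_nm) * snap_nm
        if (i == 1) { ok <- TRUE }
        else {
          d2 <- colSums((t(p[seq_len(i - 1), , drop = FALSE]) - cand)^2)
          ok <- all(d2 >= min_sep^2)
        }
        if (ok) { p[i, ] <- cand; break }
      }
      if (!ok)
        stop(sprintf("packing error: could not place bead %d with min_sep %.0f nm",
                     i, min_sep))
    }
    p
  })
  emitter_set(pos, brightness = brightness, diameter = diameter,
              bounds = bounds)
}

#' A voxelized fluorophore-density phantom
#'
#' @param volume Nonnegative 3D density array `[y, x, z]`.
#' @param voxel Spacings `c(z, y, x)` in nm.
#' @param label One of `"beads"`, `"filaments"`, `"er_network"`, `"sheets"`.
#' @param z_coords Optional explicit z coordinate (nm) of each slice;
#'   defaults to `(0, dz, 2 dz, ...)`.
#' @return Object of class `density_phantom`.
#' @export
density_phantom <- function(volume, voxel,
                            label = c("beads", "filaments", "er_network", "sheets"),
                            z_coords = NULL) {
  label <- match.arg(label)
  voxel <- psf_voxel(voxel)
  if (length(dim(volume)) == 2) volume <- array(volume, dim = c(dim(volume), 1))
  if (any(!is.finite(volume)) || any(volume < 0))
    stop("phantom density must be finite and nonnegative")
  if (is.null(z_coords)) z_coords <- (seq_len(dim(volume)[3]) - 1) * voxel["z"]
  if (length(z_coords) != dim(volume)[3])
    stop("z_coords length must match the number of slices")
  structure(list(volume = volume, voxel = voxel, label = label,
                 z_coords = unname(z_coords)),
            class = "density_phantom")
}

#' Rasterize point emitters onto a density grid
#'
#' Deposits each emitter's brightness by trilinear interpolation onto the
#' voxel grid (total brightness is conserved for emitters inside the
#' grid; the sub-voxel emitter size is left to the PSF).
#'
#' @param em An [emitter_set()].
#' @param dims Grid dimensions `c(ny, nx, nz)`.
#' @param voxel Spacings `c(z, y, x)` in nm.
#' @param z_coords Optional slice z coordinates (nm).
#' @return A `density_phantom` labelled `"beads"`.
#' @export
rasterize_emitters <- function(em, dims, voxel, z_coords = NULL) {
  stopifnot(inherits(em, "emitter_set"))
  voxel <- psf_voxel(voxel)
  if (is.null(z_coords)) z_coords <- (seq_len(dims[3]) - 1) * voxel["z"]
  vol <- array(0, dim = dims)
  for (i in seq_len(nrow(em$positions))) {
    p <- em$positions[i, ]
    fy <- p["y"] / voxel["y"] + 1  # fractional voxel index
    fx <- p["x"] / voxel["x"] + 1
    if (dims[3] == 1) {
      fz <- 1
    } else {
      fz <- stats::approx(z_coords, seq_len(dims[3]), xout = p["z"],
                          rule = 2)$y
    }
    iy <- floor(fy); ix <- floor(fx); iz <- floor(fz)
    wy <- fy - iy; wx <- fx - ix; wz <- fz - iz
    for (dy in 0:1) for (dx in 0:1) for (dz in 0:1) {
      yy <- iy + dy; xx <- ix + dx; zz <- iz + dz
      if (yy >= 1 && yy <= dims[1] && xx >= 1 && xx <= dims[2] &&
          zz >= 1 && zz <= dims[3]) {
        w <- (if (dy) wy else 1 - wy) * (if (dx) wx else 1 - wx) *
          (if (dz) wz else 1 - wz)
        vol[yy, xx, zz] <- vol[yy, xx, zz] + em$brightness * w
      }
    }
  }
  density_phantom(vol, voxel, label = "beads", z_coords = z_coords)
}

# Deposit a truncated, renormalized 3D Gaussian blob of total mass `mass`
# at fractional voxel position (fy, fx, fz); sigma in voxel units per axis.
# Renormalizing the truncated kernel conserves mass exactly.
splat_gaussian <- function(vol, fy, fx, fz, sigma, mass, trunc = 3.5) {
  dims <- dim(vol)
  ry <- max(1, ceiling(trunc * sigma[1])); rx <- max(1, ceiling(trunc * sigma[2]))
  rz <- max(0, ceiling(trunc * sigma[3]))
  ys <- max(1, floor(fy) - ry):min(dims[1], floor(fy) + ry + 1)
  xs <- max(1, floor(fx) - rx):min(dims[2], floor(fx) + rx + 1)
  zs <- max(1, floor(fz) - rz):min(dims[3], floor(fz) + rz + 1)
  gy <- exp(-((ys - fy)^2) / (2 * sigma[1]^2))
  gx <- exp(-((xs - fx)^2) / (2 * sigma[2]^2))
  gz <- if (sigma[3] > 0) exp(-((zs - fz)^2) / (2 * sigma[3]^2)) else rep(1, length(zs))
  ker <- outer(gy, gx) %o% gz
  ker <- ker / sum(ker) * mass
  vol[ys, xs, zs] <- array(vol[ys, xs, zs], dim(ker)) + ker
  vol
}

#' Microtubule-like filament network
#'
#' Generates `n_filaments` persistent (worm-like-chain flavoured) 3D random
#' walks and rasterizes them with a Gaussian tube profile of fixed radius
#' and constant linear density. When two or more filaments are requested,
#' the first two are seeded ~115 nm apart laterally near the volume centre
#' so the network always contains a sub-diffraction crossing.
#'
#' @param n_filaments Number of filaments (0 gives an empty volume).
#' @param bounds Volume extents `c(x, y, z)` nm.
#' @param persistence_len Directional persistence length (nm).
#' @param seed Integer seed.
#' @param voxel Spacings `c(z, y, x)` nm.
#' @param radius Gaussian tube radius (sigma, nm).
#' @param linear_density Deposited mass per nm of arc length.
#' @param length_nm Arc length of each filament (nm).
#' @return A `density_phantom` labelled `"filaments"` with attribute
#'   `arc_length` (total generated arc length, nm).
#' @export
make_filament_network <- function(n_filaments, bounds, persistence_len = 2000,
                                  seed = 1,
                                  voxel = c(z = 264, y = 64.5, x = 64.5),
                                  radius = 60, linear_density = 10,
                                  length_nm = NULL) {
  stopifnot(persistence_len > 0, n_filaments >= 0)
  voxel <- psf_voxel(voxel)
  if (any(bounds <= 0)) stop("dimension error: degenerate bounds")
  dims <- c(ceiling(bounds[2] / voxel["y"]), ceiling(bounds[1] / voxel["x"]),
            max(1L, ceiling(bounds[3] / voxel["z"])))
  vol <- array(0, dim = dims)
  if (is.null(length_nm)) length_nm <- 0.8 * min(bounds[1:2])
  ds <- min(voxel["y"], voxel["x"]) / 2
  nstep <- max(2L, round(length_nm / ds))
  margin <- c(4 * radius, 4 * radius, 0)
  sig <- c(radius / voxel["y"], radius / voxel["x"],
           if (dims[3] > 1) radius / voxel["z"] else 0)

  total_len <- 0
  if (n_filaments > 0) {
    vol <- with_seed(seed, {
      ctr <- bounds / 2
      for (f in seq_len(n_filaments)) {
        p <- if (f == 1 && n_filaments >= 2) ctr + c(-57, -57, 0)
             else if (f == 2) ctr + c(57, 57, 0)
             else c(margin[1:2], 0) +
               stats::runif(3) * (bounds - 2 * c(margin[1:2], 0))
        p[3] <- min(max(p[3], 0), bounds[3])
        th <- stats::runif(1, 0, 2 * pi)
        d <- c(cos(th), sin(th), stats::runif(1, -0.1, 0.1))
        d <- d / sqrt(sum(d^2))
        for (s in seq_len(nstep)) {
          # persistent walk: white-noise kick scaled by sqrt(2 ds / Lp)
          d <- d + stats::rnorm(3, sd = sqrt(ds / persistence_len) * c(1, 1, 0.3))
          d <- d / sqrt(sum(d^2))
          p2 <- p + d * ds
          # reflect at the (margin-inset) faces to keep tube mass inside
          for (j in 1:2) {
            if (p2[j] < margin[j]) { p2[j] <- 2 * margin[j] - p2[j]; d[j] <- -d[j] }
            if (p2[j] > bounds[j] - margin[j]) {
              p2[j] <- 2 * (bounds[j] - margin[j]) - p2[j]; d[j] <- -d[j]
            }
          }
          if (p2[3] < 0) { p2[3] <- -p2[3]; d[3] <- -d[3] }
          if (p2[3] > bounds[3]) { p2[3] <- 2 * bounds[3] - p2[3]; d[3] <- -d[3] }
          p <- p2
          fz <- if (dims[3] > 1) p[3] / voxel["z"] + 1 else 1
          vol <- splat_gaussian(vol, p[2] / voxel["y"] + 1,
                                p[1] / voxel["x"] + 1, fz, sig,
                                mass = linear_density * ds)
          total_len <- total_len + ds
        }
      }
      vol
    })
    total_len <- n_filaments * nstep * ds
  }
  ph <- density_phantom(vol, voxel, label = "filaments")
  attr(ph, "arc_length") <- total_len
  ph
}

#' ER-like tubule and sheet network
#'
#' Builds a connected random network emulating the endoplasmic reticulum:
#' nodes scattered in the volume are joined into a spanning tree of
#' Gaussian-profile tubules, and a fraction of the deposited mass is
#' replaced by flat sheet patches with punched holes attached at nodes.
#' The density is saturated at the single-tubule peak level so that the
#' structure has a uniform plateau (one connected component above
#' half-maximum).
#'
#' @param bounds Volume extents `c(x, y, z)` nm.
#' @param tubule_radius Gaussian tubule radius (sigma, nm).
#' @param sheet_fraction Fraction (0..1) of nodes that carry a sheet patch.
#' @param seed Integer seed.
#' @param voxel Spacings `c(z, y, x)` nm.
#' @param n_nodes Number of network nodes.
#' @return A `density_phantom` labelled `"er_network"` (or `"sheets"` when
#'   `sheet_fraction = 1`).
#' @export
make_er_network <- function(bounds, tubule_radius = 75, sheet_fraction = 0.3,
                            seed = 1, voxel = c(z = 264, y = 64.5, x = 64.5),
                            n_nodes = 24) {
  stopifnot(sheet_fraction >= 0, sheet_fraction <= 1, tubule_radius > 0)
  voxel <- psf_voxel(voxel)
  if (any(bounds <= 0)) stop("dimension error: degenerate bounds")
  dims <- c(ceiling(bounds[2] / voxel["y"]), ceiling(bounds[1] / voxel["x"]),
            max(1L, ceiling(bounds[3] / voxel["z"])))
  margin <- 4 * tubule_radius
  sig <- c(tubule_radius / voxel["y"], tubule_radius / voxel["x"],
           if (dims[3] > 1) tubule_radius / voxel["z"] else 0)
  ds <- min(voxel["y"], voxel["x"]) / 2

  vol <- with_seed(seed, {
    v <- array(0, dim = dims)
    lo <- c(margin, margin, 0); hi <- c(bounds[1] - margin, bounds[2] - margin, bounds[3])
    nodes <- matrix(stats::runif(3 * n_nodes), ncol = 3)
    nodes <- sweep(sweep(nodes, 2, hi - lo, `*`), 2, lo, `+`)
    has_sheet <- stats::runif(n_nodes) < sheet_fraction
    # spanning tree: connect each node to its nearest predecessor
    for (i in 2:n_nodes) {
      prev <- nodes[seq_len(i - 1), , drop = FALSE]
      d2 <- colSums((t(prev) - nodes[i, ])^2)
      j <- which.min(d2)
      a <- nodes[j, ]; b <- nodes[i, ]
      npts <- max(2L, ceiling(sqrt(sum((b - a)^2)) / ds))
      for (t in seq(0, 1, length.out = npts)) {
        p <- a + t * (b - a)
        fz <- if (dims[3] > 1) p[3] / voxel["z"] + 1 else 1
        v <- splat_gaussian(v, p[2] / voxel["y"] + 1, p[1] / voxel["x"] + 1,
                            fz, sig, mass = ds)
      }
    }
    # sheet patches: flat discs with punched holes, at the node's z
    for (i in which(has_sheet)) {
      ctr <- nodes[i, ]
      rad <- stats::runif(1, 4, 7) * tubule_radius
      hole_r <- stats::runif(1, 0.8, 1.4) * tubule_radius
      hole_ang <- stats::runif(1, 0, 2 * pi)
      hole_ctr <- ctr[1:2] + 0.5 * rad * c(cos(hole_ang), sin(hole_ang))
      grd <- expand.grid(dx = seq(-rad, rad, by = ds), dy = seq(-rad, rad, by = ds))
      grd <- grd[grd$dx^2 + grd$dy^2 <= rad^2, ]
      for (r in seq_len(nrow(grd))) {
        p <- c(ctr[1] + grd$dx[r], ctr[2] + grd$dy[r], ctr[3])
        if (sum((p[1:2] - hole_ctr)^2) < hole_r^2) next  # punched hole
        if (p[1] < margin || p[1] > bounds[1] - margin ||
            p[2] < margin || p[2] > bounds[2] - margin) next
        fz <- if (dims[3] > 1) p[3] / voxel["z"] + 1 else 1
        v <- splat_gaussian(v, p[2] / voxel["y"] + 1, p[1] / voxel["x"] + 1,
                            fz, sig, mass = ds^2 / (2 * pi * tubule_radius))
      }
    }
    v
  })
  # saturate at the single-structure plateau so overlaps do not create
  # isolated above-half-max islands
  plateau <- stats::quantile(vol[vol > 0], 0.80)
  vol <- pmin(vol, plateau)
  density_phantom(vol, voxel,
                  label = if (sheet_fraction >= 1) "sheets" else "er_network")
}

#' Two-sheet axial test phantom
#'
#' Two laterally disjoint textured sheets, one at z = 0 and one at
#' `z_sep`, used to quantify optical sectioning: the out-of-focus plane
#' over the first sheet's footprint should stay dark in a well-sectioned
#' reconstruction. The first sheet occupies the left half of the field,
#' the second the right half, each with a smooth random texture and soft
#' edges.
#'
#' @param dims Lateral grid `c(ny, nx)`.
#' @param voxel Spacings `c(z, y, x)` nm (z is only a label here; the two
#'   slices sit at 0 and `z_sep`).
#' @param z_sep Axial separation of the sheets (nm; default 800).
#' @param seed Integer seed.
#' @return A `density_phantom` labelled `"sheets"` with slices at
#'   `c(0, z_sep)`.
#' @export
make_two_sheet_phantom <- function(dims = c(96, 96),
                                   voxel = c(z = 264, y = 64.5, x = 64.5),
                                   z_sep = 800, seed = 1) {
  voxel <- psf_voxel(voxel)
  smooth_field <- function(ny, nx) {
    f <- matrix(stats::runif(ny * nx), ny, nx)
    ky <- fft_freq(ny); kx <- fft_freq(nx)
    # feature scale a few hundred nm: near the diffraction limit, so the
    # widefield image of the texture is strongly low-pass filtered
    lp <- exp(-outer(ky^2, kx^2, `+`) / (2 * 0.15^2))
    g <- Re(ifft2(fft2(f) * lp))
    g <- g - min(g)
    g / max(g)
  }
  vol <- with_seed(seed, {
    ny <- dims[1]; nx <- dims[2]
    t1 <- 0.25 + 0.75 * smooth_field(ny, nx)
    t2 <- 0.25 + 0.75 * smooth_field(ny, nx)
    xfrac <- (seq_len(nx) - 0.5) / nx
    left <- matrix(rep(pmin(pmax((0.45 - xfrac) / 0.05, 0), 1), each = ny), ny, nx)
    right <- matrix(rep(pmin(pmax((xfrac - 0.55) / 0.05, 0), 1), each = ny), ny, nx)
    yfrac <- (seq_len(ny) - 0.5) / ny
    ywin <- matrix(rep(pmin(pmax((yfrac - 0.08) / 0.05, 0), 1) *
                       pmin(pmax((0.92 - yfrac) / 0.05, 0), 1), times = nx), ny, nx)
    array(c(t1 * left * ywin, t2 * right * ywin), dim = c(ny, nx, 2))
  })
  density_phantom(vol, voxel, label = "sheets", z_coords = c(0, z_sep))
}
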