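#' Generate a synthetic hippocampal gray-matter domain
#'
#' Builds a topologically correct curved-slab gray-matter mask inside a 3-D
#' voxel grid, with labelled source/sink boundary layers for the three
#' anatomical axes (anterior-posterior AP, proximal-distal PD, inner-outer
#' IO) and an analytic "true" coordinate parameterisation retained for
#' testing. The slab is a box in the AP/PD index plane whose mid-surface
#' undulates along IO; `curvature = 0` gives a rectangular slab whose true
#' coordinates are exact linear ramps.
#'
#' Coordinate conventions: voxel indices are 0-based in the documentation and
#' file formats (R arrays are addressed 1-based internally); native
#' coordinates are voxel centres at `(index + 0.5) * voxel_size` mm; all
#' normalised coordinates live in `[0, 1]`.
#'
#' @param grid_shape Integer length-3, voxels per axis (each `>= 8`).
#' @param voxel_size Isotropic voxel edge (mm), default 1.
#' @param curvature Relative mid-surface undulation amplitude in `[0, 1)`;
#'   default 0.3. Zero gives the rectangular slab.
#' @param thickness Slab thickness in voxels (default 5).
#' @param pad Margin (voxels) between slab and grid edge along AP/PD.
#' @param seed Integer seed for the (small, deterministic-given-seed) random
#'   phases of the undulation.
#' @returns An object of class `hipp_domain`: list with `mask` (logical
#'   array), `grid_shape`, `voxel_size`, `true_coords` (list of arrays `u`
#'   AP, `v` PD, `w` IO, `NA` outside the mask), `boundaries` (per axis, a
#'   list with logical arrays `source` and `sink`), `subfield` and `longaxis`
#'   (integer label arrays, levels [subfield_names()] / [longaxis_names()]),
#'   and `psi` (Laplace fields, filled by [solve_laplace()]).
#' @export
generate_domain <- function(grid_shape = c(32, 20, 14), voxel_size = 1,
                            curvature = 0.3, thickness = 5, pad = 2,
                            seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stop("grid_shape must give >= 8 voxels per axis")
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  i0 <- pad; i1 <- nx - 1 - pad            # 0-based slab extent, AP
  j0 <- pad; j1 <- ny - 1 - pad            # PD
  if (i1 - i0 < 4 || j1 - j0 < 4) stop("grid too small for the slab and pad")

  ii <- array(rep(0:(nx - 1), times = ny * nz), dim = grid_shape)
  jj <- array(rep(rep(0:(ny - 1), each = nx), times = nz), dim = grid_shape)
  kk <- array(rep(0:(nz - 1), each = nx * ny), dim = grid_shape)

  u <- (ii - i0) / (i1 - i0)
  v <- (jj - j0) / (j1 - j0)

  withr_seed(seed, {
    ph <- runif(2, -0.2, 0.2)
  })
  amp_max <- max((nz - thickness) / 2 - 0.5, 0)
  amp <- curvature * amp_max
  # align the mid-surface with the voxel lattice parity so a flat slab holds
  # exactly `thickness` layers
  zc0 <- floor((nz - 1) / 2) + (if (thickness %% 2 == 0) 0.5 else 0)
  zc <- zc0 + amp * sin(pi * (u + ph[1])) * cos(pi * (v + ph[2]))
  # w in [0, 1] spans exactly `thickness` voxel layers
  w <- (kk - (zc - (thickness - 1) / 2)) / (thickness - 1)

  inbox <- u >= 0 & u <= 1 & v >= 0 & v <= 1
  mask <- inbox & w >= -1e-9 & w <= 1 + 1e-9
  if (!is_six_connected(mask)) stop("generated GM mask is disconnected")

  # IO true coordinate rescaled per column so the extremal voxels map to 0/1
  wq <- array(NA_real_, grid_shape)
  wq[mask] <- w[mask]
  w_true <- normalise_io(wq, mask)

  boundaries <- list(
    AP = list(source = mask & ii == i0, sink = mask & ii == i1),
    PD = list(source = mask & jj == j0, sink = mask & jj == j1),
    IO = column_extremes(mask)
  )
  for (ax in names(boundaries)) {
    bl <- boundaries[[ax]]
    if (!any(bl$source) || !any(bl$sink))
      stop("missing boundary face for axis ", ax)
  }

  true_coords <- list(u = mask_na(u, mask), v = mask_na(v, mask), w = w_true)
  subfield <- mask_na(bin_coordinate(v, 5), mask)
  longaxis <- mask_na(bin_coordinate(u, 5), mask)

  structure(list(mask = mask, grid_shape = grid_shape,
                 voxel_size = voxel_size, true_coords = true_coords,
                 boundaries = boundaries, subfield = subfield,
                 longaxis = longaxis, psi = list(), seed = as.integer(seed),
                 curvature = curvature, thickness = thickness),
            class = "hipp_domain")
}

mask_na <- function(a, mask) { a[!mask] <- NA; a }

bin_coordinate <- function(x, n_bins) {
  pmin(pmax(floor(x * n_bins) + 1L, 1L), n_bins)
}

# per-(i,j) column lowest/highest GM voxel along k
column_extremes <- function(mask) {
  d <- dim(mask)
  src <- array(FALSE, d); snk <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ks <- which(mask[i, j, ])
    if (length(ks)) {
      src[i, j, ks[1]] <- TRUE
      snk[i, j, ks[length(ks)]] <- TRUE
    }
  }
  list(source = src, sink = snk)
}

# rescale IO coordinate per column to [0, 1]
normalise_io <- function(w, mask) {
  d <- dim(mask)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ks <- which(mask[i, j, ])
    if (length(ks) == 1) out[i, j, ks] <- 0.5
    else if (length(ks) > 1) {
      ww <- w[i, j, ks]
      out[i, j, ks] <- (ww - ww[1]) / (ww[length(ks)] - ww[1])
    }
  }
  out
}

#' Check 6-connectivity of a voxel mask
#' @param mask Logical 3-D array.
#' @returns `TRUE` if all `TRUE` voxels form one face-connected component.
#' @export
is_six_connected <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(FALSE)
  d <- dim(mask)
  lab <- array(FALSE, d)
  queue <- idx[1]
  lab[queue] <- TRUE
  strides <- c(1L, d[1], d[1] * d[2])
  coords <- arrayInd(idx, d)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    ci <- arrayInd(cur, d)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      ni <- ci
      ni[, ax] <- ni[, ax] + s
      ok <- ni[, ax] >= 1 & ni[, ax] <= d[ax]
      if (!any(ok)) next
      lin <- (ni[ok, 1] - 1L) + (ni[ok, 2] - 1L) * strides[2] +
        (ni[ok, 3] - 1L) * strides[3] + 1L
      new <- lin[mask[lin] & !lab[lin]]
      if (length(new)) { lab[new] <- TRUE; queue <- c(queue, new) }
    }
    queue <- unique(queue)
  }
  sum(lab) == length(idx)
}

#' @export
print.hipp_domain <- function(x, ...) {
  cat("<hipp_domain> grid ", paste(x$grid_shape, collapse = "x"),
      ", ", sum(x$mask), " GM voxels, voxel ", x$voxel_size, " mm, curvature ",
      x$curvature, "\n", sep = "")
  if (length(x$psi)) cat("  Laplace fields solved: ",
                         paste(names(x$psi), collapse = ", "), "\n", sep = "")
  invisible(x)
}
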