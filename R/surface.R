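#' Trilinear interpolation on a masked scalar array
#'
#' Interpolates at continuous 0-based voxel-index coordinates (voxel centres
#' at integer indices). `NA` corners (off-mask) are dropped and the remaining
#' weights renormalised; points with no valid corner give `NA`.
#'
#' @param arr 3-D array (`NA` off-mask).
#' @param pts Matrix n x 3 of 0-based continuous indices.
#' @returns Numeric vector of length n.
#' @keywords internal
trilinear <- function(arr, pts) {
  d <- dim(arr)
  p <- pmin(pmax(pts, 0), matrix(rep(d - 1, each = nrow(pts)), ncol = 3))
  f0 <- floor(p)
  fr <- p - f0
  f0 <- f0 + 1L                       # to 1-based
  f1 <- pmin(f0 + 1L, matrix(rep(d, each = nrow(pts)), ncol = 3))
  num <- numeric(nrow(pts))
  den <- numeric(nrow(pts))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) f1[, 1] else f0[, 1]
    iy <- if (cy) f1[, 2] else f0[, 2]
    iz <- if (cz) f1[, 3] else f0[, 3]
    w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
      (if (cy) fr[, 2] else 1 - fr[, 2]) *
      (if (cz) fr[, 3] else 1 - fr[, 3])
    v <- arr[cbind(ix, iy, iz)]
    ok <- !is.na(v) & w > 0
    num[ok] <- num[ok] + w[ok] * v[ok]
    den[ok] <- den[ok] + w[ok]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# vectorised trilinear lookup of a grid x 3 vector field
trilinear_vec <- function(vf, pts) {
  cbind(trilinear(vf[, , , 1], pts), trilinear(vf[, , , 2], pts),
        trilinear(vf[, , , 3], pts))
}

#' Build the midthickness surface of a solved domain
#'
#' Constructs a regular unfolded grid (AP x PD in `[0,1]^2`) and maps each
#' grid point to native space: the nearest gray-matter voxel in Laplace
#' coordinates seeds an inner-outer streamline (RK4 through the normalised
#' IO gradient, step 0.25 voxel) which is walked to the `psi_IO = 0.5` level.
#' Subfield labels are fixed proximal-distal bands and long-axis labels fixed
#' anterior-posterior bands (equal widths by default). Per-vertex native and
#' unfolded areas are computed from the triangulated mesh; unfolded areas are
#' scaled so both areas total the native surface area, making the
#' gyrification ratio 1 under a distortion-free mapping.
#'
#' @param domain A domain with all three `psi` fields solved
#'   ([solve_laplace_all()]).
#' @param n_ap,n_pd Unfolded grid size (defaults 121 x 60, i.e. 7260
#'   vertices).
#' @param subfield_edges,longaxis_edges Band edges in `[0,1]` (length 6).
#' @returns Object of class `hipp_surface`: `vertices` tibble (`vertex`,
#'   `ap`, `pd`, `x`, `y`, `z` native mm, `subfield`, `longaxis`,
#'   `native_area`, `unfolded_area`, `valid`), `faces` integer matrix (m x 3),
#'   `n_ap`, `n_pd`, `voxel_size`.
#' @export
build_midthickness_surface <- function(domain, n_ap = 121, n_pd = 60,
                                       subfield_edges = seq(0, 1, 0.2),
                                       longaxis_edges = seq(0, 1, 0.2)) {
  stopifnot(inherits(domain, "hipp_domain"))
  if (!all(c("AP", "PD", "IO") %in% names(domain$psi)))
    stop("solve all three Laplace fields first (solve_laplace_all)")
  psi <- domain$psi
  mask <- domain$mask
  h <- domain$voxel_size
  idx <- which(mask)
  vox <- arrayInd(idx, domain$grid_shape) - 1L   # 0-based voxel indices
  pap <- psi$AP[idx]; ppd <- psi$PD[idx]; pio <- psi$IO[idx]

  grid <- tidyr::expand_grid(ap = seq(0, 1, length.out = n_ap),
                             pd = seq(0, 1, length.out = n_pd))
  # nearest GM voxel in Laplace-coordinate space, chunked for memory
  seed_idx <- integer(nrow(grid))
  chunk <- 500L
  for (s in seq(1, nrow(grid), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(grid))
    dmat <- outer(grid$ap[s:e], pap, `-`)^2 + outer(grid$pd[s:e], ppd, `-`)^2 +
      outer(rep(0.5, e - s + 1L), pio, `-`)^2
    seed_idx[s:e] <- max.col(-dmat, ties.method = "first")
  }
  pos <- vox[seed_idx, , drop = FALSE] * 1.0

  # index-space gradients of the three coordinate fields
  gfields <- lapply(psi, gradient_field, mask = mask, voxel_size = 1)
  # walk the IO streamline to the midthickness level, then refine all three
  # coordinates jointly (quasi-Newton on the interpolated fields)
  walked <- walk_to_level(pos, psi$IO, gfields$IO, level = 0.5, step = 0.25)
  ref <- refine_vertex_positions(walked$pos, psi, gfields,
                                 targets = cbind(grid$ap, grid$pd, 0.5))
  valid <- walked$ok & ref$ok

  vts <- tibble::tibble(
    vertex = seq_len(nrow(grid)), ap = grid$ap, pd = grid$pd,
    x = (ref$pos[, 1] + 0.5) * h, y = (ref$pos[, 2] + 0.5) * h,
    z = (ref$pos[, 3] + 0.5) * h,
    subfield = factor(subfield_names()[band_label(grid$pd, subfield_edges)],
                      levels = subfield_names()),
    longaxis = factor(longaxis_names()[band_label(grid$ap, longaxis_edges)],
                      levels = longaxis_names()),
    valid = valid)

  faces <- grid_faces(n_ap, n_pd)
  nat <- vertex_areas(as.matrix(vts[, c("x", "y", "z")]), faces, nrow(vts))
  unf2 <- cbind(vts$ap, vts$pd, 0)
  unf <- vertex_areas(unf2, faces, nrow(vts))
  unf <- unf * sum(nat, na.rm = TRUE) / sum(unf, na.rm = TRUE)
  vts$native_area <- nat
  vts$unfolded_area <- unf

  structure(list(vertices = vts, faces = faces, n_ap = n_ap, n_pd = n_pd,
                 voxel_size = h),
            class = "hipp_surface")
}

band_label <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

grid_faces <- function(n_ap, n_pd) {
  # vertices ordered pd-fastest (expand_grid ap x pd)
  vid <- function(i, j) (i - 1L) * n_pd + j   # i in 1..n_ap, j in 1..n_pd
  f <- matrix(0L, 2L * (n_ap - 1L) * (n_pd - 1L), 3L)
  r <- 1L
  for (i in seq_len(n_ap - 1L)) for (j in seq_len(n_pd - 1L)) {
    a <- vid(i, j); b <- vid(i + 1L, j); cc <- vid(i + 1L, j + 1L); dd <- vid(i, j + 1L)
    f[r, ] <- c(a, b, cc); f[r + 1L, ] <- c(a, cc, dd)
    r <- r + 2L
  }
  f
}

vertex_areas <- function(xyz, faces, n_vertices) {
  p1 <- xyz[faces[, 1], , drop = FALSE]
  p2 <- xyz[faces[, 2], , drop = FALSE]
  p3 <- xyz[faces[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  acc <- numeric(n_vertices)
  for (c3 in 1:3) {
    t <- tapply(fa, faces[, c3], sum)
    acc[as.integer(names(t))] <- acc[as.integer(names(t))] + t / 3
  }
  acc
}

# damped quasi-Newton refinement of vertex positions: drive the three
# interpolated coordinate fields to their unfolded-grid targets using the
# per-axis gradient directions (diagonal Jacobian approximation)
refine_vertex_positions <- function(pos, psi, gfields, targets,
                                    n_iter = 30L, damping = 0.8, tol = 5e-3) {
  axes <- c("AP", "PD", "IO")
  cur <- pos
  for (it in seq_len(n_iter)) {
    upd <- matrix(0, nrow(cur), 3)
    err <- numeric(nrow(cur))
    for (a in seq_along(axes)) {
      val <- trilinear(psi[[axes[a]]], cur)
      g <- trilinear_vec(gfields[[axes[a]]], cur)
      gn2 <- rowSums(g^2)
      resid <- targets[, a] - val
      ok <- is.finite(resid) & is.finite(gn2) & gn2 > 1e-12
      upd[ok, ] <- upd[ok, ] + resid[ok] * g[ok, , drop = FALSE] / gn2[ok]
      err <- pmax(err, abs(ifelse(is.finite(resid), resid, Inf)))
    }
    if (max(err) < tol / 10) break
    cur <- cur + damping * upd
  }
  final_err <- numeric(nrow(cur))
  for (a in seq_along(axes)) {
    val <- trilinear(psi[[axes[a]]], cur)
    final_err <- pmax(final_err, abs(targets[, a] - val))
  }
  # boundary grid points (targets 0/1) sit on clamped field plateaus; accept
  # a looser criterion there
  on_edge <- targets[, 1] %in% c(0, 1) | targets[, 2] %in% c(0, 1)
  ok <- is.finite(final_err) & (final_err < tol | (on_edge & final_err < 0.05))
  list(pos = cur, ok = ok, err = final_err)
}

# walk each point along +/- the normalised IO gradient until psi crosses
# `level`; returns refined positions (linear interpolation of the crossing)
walk_to_level <- function(pos, psi, gvf, level = 0.5, step = 0.25,
                          max_steps = 400L) {
  n <- nrow(pos)
  cur <- pos
  val <- trilinear(psi, cur)
  ok <- !is.na(val)
  done <- !ok
  for (it in seq_len(max_steps)) {
    if (all(done)) break
    act <- which(!done)
    dir_sign <- sign(level - val[act])
    dir_sign[dir_sign == 0] <- 1
    g <- rk4_direction(cur[act, , drop = FALSE], gvf, step)
    nxt <- cur[act, , drop = FALSE] + g * dir_sign * step
    nval <- trilinear(psi, nxt)
    crossed <- !is.na(nval) & (nval - level) * (val[act] - level) <= 0
    lost <- is.na(nval)
    # linear interpolation of the crossing point
    ci <- act[crossed]
    if (length(ci)) {
      frac <- (level - val[ci]) / (nval[crossed] - val[ci])
      frac[!is.finite(frac)] <- 0
      cur[ci, ] <- cur[ci, , drop = FALSE] +
        g[crossed, , drop = FALSE] * dir_sign[crossed] * step * frac
      val[ci] <- level
      done[ci] <- TRUE
    }
    li <- act[lost & !crossed]
    if (length(li)) { done[li] <- TRUE; ok[li] <- FALSE }
    mv <- act[!crossed & !lost]
    if (length(mv)) {
      sel <- !crossed & !lost
      cur[mv, ] <- nxt[sel, , drop = FALSE]
      val[mv] <- nval[sel]
    }
  }
  ok[!done] <- FALSE
  list(pos = cur, ok = ok)
}

# RK4 direction through the normalised vector field (classic 4-stage average)
rk4_direction <- function(pts, gvf, step) {
  normalise_rows <- function(m) {
    n <- sqrt(rowSums(m^2))
    n[!is.finite(n) | n < 1e-12] <- NA
    m / n
  }
  k1 <- normalise_rows(trilinear_vec(gvf, pts))
  k1[is.na(k1)] <- 0
  k2 <- normalise_rows(trilinear_vec(gvf, pts + 0.5 * step * k1))
  k2[is.na(k2)] <- 0
  k3 <- normalise_rows(trilinear_vec(gvf, pts + 0.5 * step * k2))
  k3[is.na(k3)] <- 0
  k4 <- normalise_rows(trilinear_vec(gvf, pts + step * k3))
  k4[is.na(k4)] <- 0
  d <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
  n <- sqrt(rowSums(d^2))
  n[n < 1e-12] <- 1
  d / n
}

#' Sample a volume onto surface vertices (enclosing voxel)
#'
#' Each vertex takes the value of the voxel containing its native coordinate
#' (no interpolation). Vertices falling outside the mask are `NA`; vertices
#' outside the volume bounds raise an error.
#'
#' @param volume 3-D array on the domain grid (`NA` off-mask).
#' @param surface A [build_midthickness_surface()] result.
#' @returns Numeric vector, one value per vertex.
#' @export
sample_to_surface <- function(volume, surface) {
  h <- surface$voxel_size
  d <- dim(volume)
  vx <- floor(as.matrix(surface$vertices[, c("x", "y", "z")]) / h)  # 0-based
  if (any(vx < 0 | vx >= matrix(rep(d, each = nrow(vx)), ncol = 3), na.rm = TRUE))
    stop("vertex outside volume bounds")
  out <- volume[vx + 1L]
  out[!surface$vertices$valid] <- NA_real_
  out
}

#' Positional gradient maps on the unfolded surface
#'
#' The contrived anterior-posterior and proximal-distal positional gradients:
#' simply the unfolded AP and PD coordinates of each vertex, spanning
#' `[0, 1]`.
#'
#' @param surface A [build_midthickness_surface()] result.
#' @returns Tibble with columns `vertex`, `AP`, `PD`.
#' @export
positional_gradients <- function(surface) {
  tibble::tibble(vertex = surface$vertices$vertex,
                 AP = surface$vertices$ap, PD = surface$vertices$pd)
}

#' Macrostructural metrics: thickness, gyrification, subfield volume
#'
#' Thickness is the inner-outer streamline arc length through each vertex
#' (walked from the midthickness position to the `psi_IO = 0` and `1` levels,
#' plus one voxel for the two half-voxel caps beyond the boundary-layer
#' centres), in mm. Gyrification is the ratio of native to (area-matched)
#' unfolded vertex area. Volume is the gray-matter voxel count times voxel
#' volume per subfield label.
#'
#' @param domain A solved domain.
#' @param surface Its midthickness surface.
#' @param log_gyrification If `TRUE`, return log2 gyrification.
#' @returns List with `vertex` tibble (`vertex`, `thickness`,
#'   `gyrification`) and `volume` tibble (`subfield`, `volume_mm3`).
#' @export
macrostructure <- function(domain, surface, log_gyrification = FALSE) {
  h <- domain$voxel_size
  pos <- as.matrix(surface$vertices[, c("x", "y", "z")]) / h - 0.5  # index space
  gio <- gradient_field(domain$psi$IO, domain$mask, voxel_size = 1)
  len0 <- arc_length_to_level(pos, domain$psi$IO, gio, 0)
  len1 <- arc_length_to_level(pos, domain$psi$IO, gio, 1)
  thick <- (len0 + len1 + 1) * h
  thick[!surface$vertices$valid] <- NA_real_
  gyr <- surface$vertices$native_area / surface$vertices$unfolded_area
  if (log_gyrification) gyr <- log2(gyr)
  idx <- which(domain$mask)
  vol <- tibble::tibble(subfield = factor(subfield_names(),
                                          levels = subfield_names()),
                        volume_mm3 = as.numeric(
                          table(factor(domain$subfield[idx], levels = 1:5))) * h^3)
  list(vertex = tibble::tibble(vertex = surface$vertices$vertex,
                               thickness = thick, gyrification = gyr),
       volume = vol)
}

# arc length walked along the IO streamline from pts to the given psi level
arc_length_to_level <- function(pts, psi, gvf, level, step = 0.25,
                                max_steps = 400L) {
  n <- nrow(pts)
  cur <- pts
  val <- trilinear(psi, cur)
  len <- numeric(n)
  done <- is.na(val) | abs(val - level) < 1e-12
  for (it in seq_len(max_steps)) {
    if (all(done)) break
    act <- which(!done)
    dir_sign <- sign(level - val[act])
    dir_sign[dir_sign == 0] <- 1
    g <- rk4_direction(cur[act, , drop = FALSE], gvf, step)
    nxt <- cur[act, , drop = FALSE] + g * dir_sign * step
    nval <- trilinear(psi, nxt)
    crossed <- !is.na(nval) & (nval - level) * (val[act] - level) <= 0
    lost <- is.na(nval) | abs(nval - val[act]) < 1e-12
    ci <- act[crossed]
    if (length(ci)) {
      frac <- (level - val[ci]) / (nval[crossed] - val[ci])
      frac[!is.finite(frac)] <- 1
      len[ci] <- len[ci] + step * frac
      done[ci] <- TRUE
    }
    li <- act[lost & !crossed]
    if (length(li)) done[li] <- TRUE
    mv <- act[!crossed & !lost]
    if (length(mv)) {
      sel <- !crossed & !lost
      cur[mv, ] <- nxt[sel, , drop = FALSE]
      val[mv] <- nval[sel]
      len[mv] <- len[mv] + step
    }
  }
  len
}
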