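#' Solve Laplace's equation on the gray-matter mask
#'
#' Computes the harmonic coordinate field `psi` for one anatomical axis:
#' `psi = 0` on the axis' source boundary layer, `psi = 1` on its sink layer,
#' discrete 7-point Laplacian zero at interior GM voxels, and zero-flux
#' (Neumann) conditions on mask walls (out-of-mask neighbours are simply
#' omitted from the stencil). The sparse symmetric positive-definite system
#' is solved directly (Cholesky); the residual max-norm of the discrete
#' Laplacian is checked against `tol`.
#'
#' @param domain A [generate_domain()] result.
#' @param axis `"AP"`, `"PD"` or `"IO"`.
#' @param tol Residual max-norm tolerance (default 1e-6).
#' @returns The domain with `domain$psi[[axis]]` set (array, `NA` off-mask).
#' @export
solve_laplace <- function(domain, axis = c("AP", "PD", "IO"), tol = 1e-6) {
  stopifnot(inherits(domain, "hipp_domain"))
  axis <- match.arg(axis)
  mask <- domain$mask
  bnd <- domain$boundaries[[axis]]
  if (!any(bnd$source) || !any(bnd$sink)) stop("empty boundary face")
  if (any(bnd$source & bnd$sink)) stop("source and sink layers overlap")
  if (!is_six_connected(mask)) stop("disconnected GM mask")

  d <- dim(mask)
  fixed <- bnd$source | bnd$sink
  fixval <- array(0, d); fixval[bnd$sink] <- 1
  unk <- mask & !fixed
  uidx <- which(unk)
  nunk <- length(uidx)
  psi <- array(NA_real_, d)
  psi[bnd$source] <- 0; psi[bnd$sink] <- 1
  if (nunk > 0) {
    row_of <- array(0L, d); row_of[uidx] <- seq_len(nunk)
    ci <- arrayInd(uidx, d)
    ii <- list(); jj <- list(); xx <- list()
    deg <- numeric(nunk)
    rhs <- numeric(nunk)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      ni <- ci
      ni[, ax] <- ni[, ax] + s
      ok <- ni[, ax] >= 1 & ni[, ax] <= d[ax]
      lin <- rep(NA_integer_, nunk)
      lin[ok] <- (ni[ok, 1] - 1L) + (ni[ok, 2] - 1L) * d[1] +
        (ni[ok, 3] - 1L) * d[1] * d[2] + 1L
      inmask <- ok & mask[ifelse(ok, lin, 1L)]
      deg <- deg + inmask
      nb_fixed <- inmask & fixed[ifelse(inmask, lin, 1L)]
      rhs <- rhs + ifelse(nb_fixed, fixval[ifelse(nb_fixed, lin, 1L)], 0)
      nb_unk <- which(inmask & !nb_fixed)
      if (length(nb_unk)) {
        ii[[length(ii) + 1L]] <- nb_unk
        jj[[length(jj) + 1L]] <- row_of[lin[nb_unk]]
        xx[[length(xx) + 1L]] <- rep(-1, length(nb_unk))
      }
    }
    A <- Matrix::sparseMatrix(i = c(unlist(ii), seq_len(nunk)),
                              j = c(unlist(jj), seq_len(nunk)),
                              x = c(unlist(xx), deg),
                              dims = c(nunk, nunk))
    sol <- as.numeric(Matrix::solve(A, rhs))
    psi[uidx] <- sol
  }
  res <- laplace_residual(psi, mask, fixed)
  if (res > tol)
    stop(sprintf("Laplace residual %.3g exceeds tolerance %.3g", res, tol))
  domain$psi[[axis]] <- psi
  attr(domain$psi[[axis]], "residual") <- res
  domain
}

# max-norm of the masked discrete Laplacian at non-fixed GM voxels
laplace_residual <- function(psi, mask, fixed) {
  d <- dim(mask)
  idx <- which(mask & !fixed)
  if (!length(idx)) return(0)
  ci <- arrayInd(idx, d)
  acc <- numeric(length(idx))
  deg <- numeric(length(idx))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    ni <- ci
    ni[, ax] <- ni[, ax] + s
    ok <- ni[, ax] >= 1 & ni[, ax] <= d[ax]
    lin <- rep(1L, length(idx))
    lin[ok] <- (ni[ok, 1] - 1L) + (ni[ok, 2] - 1L) * d[1] +
      (ni[ok, 3] - 1L) * d[1] * d[2] + 1L
    inmask <- ok & mask[lin]
    acc <- acc + ifelse(inmask, psi[lin], 0)
    deg <- deg + inmask
  }
  max(abs(acc - deg * psi[idx]))
}

#' Gradient vector field of a scalar field on a mask
#'
#' Central differences at interior voxels, one-sided differences at mask
#' edges, scaled by the voxel size; single-voxel-thick stretches (no
#' neighbour on either side along an axis) get a zero component and are
#' flagged.
#'
#' @param psi Scalar array (`NA` off-mask) — typically a Laplace field.
#' @param mask Logical array; defaults to `!is.na(psi)`.
#' @param voxel_size Voxel edge (mm).
#' @param provenance Provenance tag stored on the result.
#' @returns Array grid x 3 with attributes `provenance` and `degenerate`
#'   (logical array flagging voxels with at least one undefined component).
#' @export
gradient_field <- function(psi, mask = !is.na(psi), voxel_size = 1,
                           provenance = "gradient-of-psi") {
  g <- finite_diff_gradient(psi, mask, voxel_size)
  degen <- array(FALSE, dim(mask))
  degen[mask] <- is.na(g[, , , 1][mask]) | is.na(g[, , , 2][mask]) |
    is.na(g[, , , 3][mask])
  attr(g, "provenance") <- provenance
  attr(g, "degenerate") <- degen
  g
}

finite_diff_gradient <- function(psi, mask, voxel_size) {
  d <- dim(psi)
  out <- array(NA_real_, c(d, 3))
  idx <- which(mask)
  ci <- arrayInd(idx, d)
  for (ax in 1:3) {
    up <- ci; up[, ax] <- up[, ax] + 1L
    dn <- ci; dn[, ax] <- dn[, ax] - 1L
    ok_up <- up[, ax] <= d[ax]
    ok_dn <- dn[, ax] >= 1L
    lin_up <- rep(1L, length(idx)); lin_dn <- rep(1L, length(idx))
    lin_up[ok_up] <- lin_index(up[ok_up, , drop = FALSE], d)
    lin_dn[ok_dn] <- lin_index(dn[ok_dn, , drop = FALSE], d)
    has_up <- ok_up & mask[lin_up]
    has_dn <- ok_dn & mask[lin_dn]
    val <- rep(NA_real_, length(idx))
    both <- has_up & has_dn
    val[both] <- (psi[lin_up[both]] - psi[lin_dn[both]]) / (2 * voxel_size)
    fwd <- has_up & !has_dn
    val[fwd] <- (psi[lin_up[fwd]] - psi[idx[fwd]]) / voxel_size
    bwd <- !has_up & has_dn
    val[bwd] <- (psi[idx[bwd]] - psi[lin_dn[bwd]]) / voxel_size
    comp <- array(NA_real_, d)
    comp[idx] <- val
    out[, , , ax] <- comp
  }
  out
}

lin_index <- function(ci, d) {
  (ci[, 1] - 1L) + (ci[, 2] - 1L) * d[1] + (ci[, 3] - 1L) * d[1] * d[2] + 1L
}

#' Solve all three Laplace coordinate fields
#' @param domain A [generate_domain()] result.
#' @param tol Residual tolerance passed to [solve_laplace()].
#' @returns The domain with `psi$AP`, `psi$PD`, `psi$IO` set.
#' @export
solve_laplace_all <- function(domain, tol = 1e-6) {
  for (ax in c("AP", "PD", "IO")) domain <- solve_laplace(domain, ax, tol)
  domain
}
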