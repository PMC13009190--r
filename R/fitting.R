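#' Per-shell powder (direction) average
#'
#' Arithmetic mean and SD of the signal across gradient directions within
#' each shell, per voxel, with the b = 0 mean used for normalisation.
#' Shells with fewer than 6 directions (other than b = 0) are refused.
#'
#' @param signals 4-D signal array (grid x volumes) or a voxel x volume
#'   matrix.
#' @param scheme The [acquisition_scheme()].
#' @param mask Logical array (required when `signals` is 4-D).
#' @param normalise Divide by the per-voxel b = 0 mean (default `TRUE`).
#' @returns List with `mean` (voxel x shell matrix, shells in `scheme$bvalues`
#'   order), `sd` (same shape), `bvalues`, `s0` (per-voxel b = 0 mean).
#' @export
powder_average <- function(signals, scheme, mask = NULL, normalise = TRUE) {
  m <- if (length(dim(signals)) == 4) {
    if (is.null(mask)) stop("mask required for 4-D input")
    dwi_matrix(signals, mask)
  } else as.matrix(signals)
  if (ncol(m) != scheme$n_volumes) stop("signal/scheme volume mismatch")
  nb <- length(scheme$bvalues)
  if (any(scheme$n_dirs_per_shell[scheme$bvalues > 0] < 6))
    stop("refusing powder average: a nonzero shell has < 6 directions")
  mu <- matrix(NA_real_, nrow(m), nb)
  sdv <- matrix(NA_real_, nrow(m), nb)
  for (s in seq_len(nb)) {
    cols <- which(scheme$shell == s)
    if (!length(cols)) stop("empty shell")
    mu[, s] <- rowMeans(m[, cols, drop = FALSE])
    sdv[, s] <- apply(m[, cols, drop = FALSE], 1, sd)
  }
  b0 <- which(scheme$bvalues == 0)
  s0 <- if (length(b0)) mu[, b0[1]] else rep(1, nrow(m))
  if (normalise) {
    mu <- mu / s0
    sdv <- sdv / s0
  }
  list(mean = mu, sd = sdv, bvalues = scheme$bvalues, s0 = s0)
}

new_fit_result <- function(model, estimates, diagnostics, mask, grid_shape) {
  structure(list(model = model, estimates = estimates,
                 diagnostics = diagnostics, mask = mask,
                 grid_shape = grid_shape),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> model ", x$model, ", ", nrow(x$estimates), " voxels, ",
      sum(!x$diagnostics$converged), " failed\n", sep = "")
  invisible(x)
}

#' Turn a fitted metric into a 3-D volume
#' @param fit A `fit_result`.
#' @param metric Column name in `fit$estimates`.
#' @returns 3-D array (`NA` off-mask and at failed voxels).
#' @export
metric_volume <- function(fit, metric) {
  if (!metric %in% names(fit$estimates))
    stop("unknown metric: ", metric)
  arr <- array(NA_real_, fit$grid_shape)
  vals <- fit$estimates[[metric]]
  vals[!fit$diagnostics$converged] <- NA_real_
  arr[fit$estimates$voxel] <- vals
  arr
}

#' Fit the diffusion tensor by weighted linear least squares
#'
#' Log-linearised tensor fit restricted to the low-b shells (b <= `b_max`,
#' default 1.2 ms/um^2), with per-voxel weights equal to the squared signals.
#' Negative tensor eigenvalues are clamped to zero and flagged; voxels with
#' non-positive signals have those volumes excluded (flagged), and voxels
#' with fewer than 7 usable volumes fail.
#'
#' @param signals 4-D signal array or voxel x volume matrix.
#' @param scheme The [acquisition_scheme()].
#' @param mask Logical array (required for 4-D input).
#' @param b_max Largest shell used (default 1.2).
#' @returns A `fit_result` with per-voxel tensor components
#'   (`dxx..dyz`), `s0`, `md`, `fa`, `e1x..e1z` and diagnostics.
#' @export
fit_dti <- function(signals, scheme, mask = NULL, b_max = 1.2) {
  m <- if (length(dim(signals)) == 4) dwi_matrix(signals, mask) else as.matrix(signals)
  use <- which(scheme$b <= b_max + 1e-9)
  if (!any(scheme$b[use] == 0)) stop("scheme must contain b = 0 volumes")
  if (length(unique(scheme$b[use])) < 2)
    stop("need at least one nonzero shell at b <= b_max")
  g <- scheme$directions[use, , drop = FALSE]
  b <- scheme$b[use]
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  n_vox <- nrow(m)
  est <- matrix(NA_real_, n_vox, 12)
  diag_tbl <- tibble::tibble(voxel = integer(n_vox), residual_norm = NA_real_,
                             converged = FALSE, n_restarts = 0L,
                             clamped = FALSE, excluded_volumes = 0L)
  for (v in seq_len(n_vox)) {
    y <- m[v, use]
    pos <- is.finite(y) & y > 0
    diag_tbl$excluded_volumes[v] <- sum(!pos)
    if (sum(pos) < 7) next
    Xi <- X[pos, , drop = FALSE]
    yi <- log(y[pos])
    w <- y[pos]^2
    fit <- tryCatch(stats::lm.wfit(Xi, yi, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit))) next
    cf <- coef(fit)
    D <- tensor_from_6(cf[2:7])
    ed <- eigen(D, symmetric = TRUE)
    clamped <- any(ed$values < 0)
    lam <- pmax(ed$values, 0)
    Dc <- ed$vectors %*% diag(lam) %*% t(ed$vectors)
    tm <- tensor_metrics(Dc)
    est[v, ] <- c(Dc[1, 1], Dc[2, 2], Dc[3, 3], Dc[1, 2], Dc[1, 3], Dc[2, 3],
                  exp(cf[1]), tm$md, tm$fa, tm$e1)
    diag_tbl$residual_norm[v] <- sqrt(sum(fit$residuals^2 * w) / sum(w))
    diag_tbl$converged[v] <- TRUE
    diag_tbl$clamped[v] <- clamped
  }
  vox_idx <- if (is.null(mask)) seq_len(n_vox) else which(mask)
  diag_tbl$voxel <- vox_idx
  colnames(est) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz", "s0",
                     "md", "fa", "e1x", "e1y", "e1z")
  estimates <- dplyr::bind_cols(tibble::tibble(voxel = vox_idx),
                                tibble::as_tibble(est))
  gs <- if (is.null(mask)) c(n_vox, 1L, 1L) else dim(mask)
  new_fit_result("dti", estimates,
                 diag_tbl, mask %||% array(TRUE, gs), gs)
}

# seeded Latin-hypercube start points within bounds
lhs_starts <- function(n_starts, lower, upper, seed) {
  k <- length(lower)
  withr_seed(seed, {
    u <- lhs::randomLHS(n_starts, k)
  })
  sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
}

# bounded Levenberg-Marquardt from each start; best deviance wins, ties
# broken by first index. The nonlinear compartment inversions have several
# local minima (and, rarely, spurious exact roots), so the search launches
# deterministic Latin-hypercube batches until the best fit reaches the
# data's expected noise floor (`target_rms`, estimated by the caller from
# replicate scatter; ~0 for noiseless data) or `max_batches` is exhausted.
# Noise-floor-limited fits stop after the first batch; only fits stuck in a
# clearly suboptimal basin pay for more starts.
multi_start_lm <- function(starts, resid_fun, lower, upper, n_obs,
                           target_rms = 1e-3, retry_seed = 0L,
                           max_batches = 6L, maxiter = 100L) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-14,
                                     maxiter = maxiter)
  run <- function(st, best, offset) {
    for (s in seq_len(nrow(st))) {
      fit <- tryCatch(
        suppressWarnings(  # iteration-cap info under model misfit is expected
          minpack.lm::nls.lm(st[s, ], lower = lower, upper = upper,
                             fn = resid_fun, control = ctrl)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$deviance < best$value - 1e-15) {
        best <- list(par = fit$par, value = fit$deviance,
                     n_restarts = s + offset)
      }
    }
    best
  }
  best <- run(starts, NULL, 0L)
  goal <- max(3 * target_rms, 1e-10)
  b <- 1L
  n_done <- nrow(starts)
  while (!is.null(best) && sqrt(best$value / n_obs) > goal &&
         b < max_batches) {
    b <- b + 1L
    extra <- lhs_starts(max(nrow(starts), 4L), lower, upper,
                        retry_seed + 9973L * b)
    best <- run(extra, best, n_done)
    n_done <- n_done + nrow(extra)
  }
  best
}

#' Fit the NODDI model voxel-wise
#'
#' Bounded multi-start nonlinear least squares over `(f_iso, f_in, kappa)`
#' with the mean orientation fixed to the DTI principal eigenvector (or a
#' supplied field) and diffusivities fixed (`d_par` 1.7, `d_iso` 3.0
#' um^2/ms). Signals are normalised by the per-voxel b = 0 mean. Start points
#' are a seeded Latin hypercube over the bounds; the best residual wins (ties
#' by first index).
#'
#' @param signals 4-D array or voxel x volume matrix.
#' @param scheme The full multi-shell [acquisition_scheme()].
#' @param mask Logical array (for 4-D input).
#' @param mu_init Optional voxel x 3 matrix (or grid x 3 array) of mean
#'   orientations; defaults to the DTI principal eigenvector.
#' @param n_starts Multi-start count (default 5).
#' @param seed Seed for the start points.
#' @param kappa_max Upper bound for the concentration (default 64).
#' @param quad_order Gauss-Legendre order for the Watson integrals during
#'   fitting (default 48).
#' @returns A `fit_result` with per-voxel `f_iso`, `f_in` (fneurite_NODDI),
#'   `kappa`, `odi` and diagnostics.
#' @export
fit_noddi <- function(signals, scheme, mask = NULL, mu_init = NULL,
                      n_starts = 5, seed = 1L, kappa_max = 64,
                      quad_order = 48) {
  if (length(unique(scheme$bvalues)) < 3)
    stop("NODDI requires multiple nonzero shells")
  m <- if (length(dim(signals)) == 4) dwi_matrix(signals, mask) else as.matrix(signals)
  n_vox <- nrow(m)
  if (is.null(mu_init)) {
    dti <- fit_dti(m, scheme)
    mu_init <- as.matrix(dti$estimates[, c("e1x", "e1y", "e1z")])
  } else if (length(dim(mu_init)) == 4) {
    idx <- which(mask)
    mu_init <- cbind((mu_init[, , , 1])[idx], (mu_init[, , , 2])[idx],
                     (mu_init[, , , 3])[idx])
  }
  b0 <- scheme$b == 0
  s0 <- rowMeans(m[, b0, drop = FALSE])
  lower <- c(0, 0, 0); upper <- c(1, 1, kappa_max)
  starts <- lhs_starts(max(n_starts - 1, 0), lower, upper, seed)
  g <- scheme$directions
  b <- scheme$b
  est <- matrix(NA_real_, n_vox, 4)
  diag_tbl <- tibble::tibble(voxel = integer(n_vox), residual_norm = NA_real_,
                             converged = FALSE, n_restarts = 0L,
                             at_bound = FALSE)
  gl <- gauss_legendre(quad_order)
  n_b0 <- sum(b0)
  for (v in seq_len(n_vox)) {
    y <- m[v, ] / s0[v]
    mu <- mu_init[v, ]
    if (anyNA(mu) || sum(mu^2) < 1e-12) next
    # expected per-volume residual at the truth ~ noise SD, estimated from
    # the b = 0 replicates (0 for noiseless data)
    noise_rms <- if (n_b0 > 1) sd(y[b0]) else 0
    mu <- mu / sqrt(sum(mu^2))
    cosb <- as.vector(g %*% mu)
    obj <- function(p) noddi_resid_cpp(p, y, cosb, b, 1.7, 3.0,
                                       gl$nodes, gl$weights)
    # moment-based start: high-b mean signal reflects the stick fraction
    init0 <- c(0.05, min(max(mean(y[b >= 4]) * 2.5, 0.05), 0.95), 2)
    st <- rbind(init0, starts)
    fit <- multi_start_lm(st, obj, lower, upper, n_obs = length(y),
                          target_rms = noise_rms, retry_seed = seed + v,
                          max_batches = 2L)
    if (is.null(fit)) next
    p <- fit$par
    est[v, ] <- c(p[1], p[2], p[3], watson_odi(p[3]))
    diag_tbl$residual_norm[v] <- sqrt(fit$value)
    diag_tbl$converged[v] <- TRUE
    diag_tbl$n_restarts[v] <- fit$n_restarts
    diag_tbl$at_bound[v] <- any(abs(p - lower) < 1e-8) ||
      any(abs(p - upper) < 1e-8)
  }
  vox_idx <- if (is.null(mask)) seq_len(n_vox) else which(mask)
  diag_tbl$voxel <- vox_idx
  estimates <- tibble::tibble(voxel = vox_idx, f_iso = est[, 1],
                              f_in = est[, 2], kappa = est[, 3],
                              odi = est[, 4])
  gs <- if (is.null(mask)) c(n_vox, 1L, 1L) else dim(mask)
  new_fit_result("noddi", estimates, diag_tbl, mask %||% array(TRUE, gs), gs)
}

#' Fit the SANDI model voxel-wise
#'
#' Powder-averages the signal per shell (b = 0 normalised), then bounded
#' multi-start nonlinear least squares over
#' `(f_ec, f_in, r_s, d_in, d_ec)` with the intra-soma diffusivity fixed at
#' 3.0 um^2/ms. Requires at least 5 nonzero shells (the soma radius is not
#' identifiable from fewer). Derived fraction maps `fneurite`, `fsoma`,
#' `fextracellular` and `r_s` (Rsoma) are emitted.
#'
#' @inheritParams fit_noddi
#' @param n_starts Multi-start count (default 5).
#' @returns A `fit_result` with per-voxel `f_ec`, `f_in`, `r_s`, `d_in`,
#'   `d_ec`, `fneurite`, `fsoma`, `fextracellular` and diagnostics.
#' @export
fit_sandi <- function(signals, scheme, mask = NULL, n_starts = 5, seed = 1L) {
  nz <- scheme$bvalues[scheme$bvalues > 0]
  if (length(nz) < 5)
    stop("SANDI requires >= 5 nonzero shells")
  pa <- powder_average(signals, scheme, mask)
  sel <- which(pa$bvalues > 0)
  bshell <- pa$bvalues[sel]
  ydata <- pa$mean[, sel, drop = FALSE]
  n_vox <- nrow(ydata)
  lower <- c(0, 0, 1, 0.1, 0.1)
  upper <- c(1, 1, 12, 3, 3)
  starts <- lhs_starts(max(n_starts - 1, 0), lower, upper, seed)
  # precompute shell-level sphere signals on a fine radius grid (GPD series
  # is smooth in r_s; interpolation error << fit tolerance)
  r_grid <- seq(lower[3], upper[3], by = 0.02)
  sph_grid <- vapply(bshell, function(bb)
    sphere_signal_gpd(r_grid, 3.0, bb, scheme$delta, scheme$Delta),
    numeric(length(r_grid)))
  est <- matrix(NA_real_, n_vox, 8)
  diag_tbl <- tibble::tibble(voxel = integer(n_vox), residual_norm = NA_real_,
                             converged = FALSE, n_restarts = 0L,
                             at_bound = FALSE)
  n_dirs <- scheme$n_dirs_per_shell[sel]
  for (v in seq_len(n_vox)) {
    y <- ydata[v, ]
    if (anyNA(y)) next
    # standard error of each shell mean from the within-shell direction
    # scatter: the residual RMS a correct fit should reach
    sem <- pa$sd[v, sel] / sqrt(n_dirs)
    noise_rms <- sqrt(mean(sem^2))
    obj <- function(p) sandi_resid_cpp(p, y, bshell, r_grid, sph_grid)
    init0 <- c(0.4, 0.4, 6, 1.5, 1.0)
    st <- rbind(init0, starts)
    fit <- multi_start_lm(st, obj, lower, upper, n_obs = length(y),
                          target_rms = noise_rms, retry_seed = seed + v)
    if (is.null(fit)) next
    p <- fit$par
    der <- sandi_derived_fractions(p[1], p[2])
    est[v, ] <- c(p, der$fneurite, der$fsoma, der$fextracellular)
    diag_tbl$residual_norm[v] <- sqrt(fit$value)
    diag_tbl$converged[v] <- TRUE
    diag_tbl$n_restarts[v] <- fit$n_restarts
    diag_tbl$at_bound[v] <- any(abs(p - lower) < 1e-8) ||
      any(abs(p - upper) < 1e-8)
  }
  vox_idx <- if (is.null(mask)) seq_len(n_vox) else which(mask)
  diag_tbl$voxel <- vox_idx
  estimates <- tibble::tibble(voxel = vox_idx, f_ec = est[, 1],
                              f_in = est[, 2], r_s = est[, 3],
                              d_in = est[, 4], d_ec = est[, 5],
                              fneurite = est[, 6], fsoma = est[, 7],
                              fextracellular = est[, 8])
  gs <- if (is.null(mask)) c(n_vox, 1L, 1L) else dim(mask)
  new_fit_result("sandi", estimates, diag_tbl, mask %||% array(TRUE, gs), gs)
}
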