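#' Diffusion tensor signal (b-matrix form)
#'
#' Evaluates the single-tensor signal `S = S0 * exp(-<B, D>_F)` where `B` is
#' the b-matrix of a volume (`b * g g'`) and `<.,.>_F` the Frobenius inner
#' product.
#'
#' @param D Symmetric 3x3 diffusion tensor (um^2/ms).
#' @param scheme An [acquisition_scheme()].
#' @param volume_index Volume index (1-based); vectorised.
#' @param S0 Unattenuated signal (default 1).
#' @returns Numeric signal value(s).
#' @export
dti_signal <- function(D, scheme, volume_index = seq_len(scheme$n_volumes),
                       S0 = 1) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  g <- scheme$directions[volume_index, , drop = FALSE]
  b <- scheme$b[volume_index]
  # <B, D>_F with B = b g g' equals b * g' D g
  quad <- rowSums((g %*% D) * g)
  S0 * exp(-b * quad)
}

#' Tensor-derived scalar metrics
#'
#' Eigendecomposition summaries of a diffusion tensor: mean diffusivity (the
#' eigenvalue mean), fractional anisotropy (the normalised eigenvalue
#' standard deviation) and the principal eigenvector, sign-canonicalised so
#' its first nonzero component is positive.
#'
#' @param D Symmetric 3x3 tensor.
#' @returns A list with `md`, `fa`, `e1` (unit 3-vector), `evals`.
#' @export
tensor_metrics <- function(D) {
  D <- as.matrix(D)
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  l <- e$values
  md <- mean(l)
  if (all(abs(l) < .Machine$double.eps * 10)) {
    fa <- 0
  } else {
    fa <- sqrt(3 / 2) * sqrt(sum((l - md)^2)) / sqrt(sum(l^2))
  }
  e1 <- canonical_sign(e$vectors[, 1])
  list(md = md, fa = fa, e1 = e1, evals = l)
}

canonical_sign <- function(v) {
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  v
}

#' Orientation dispersion index of a Watson distribution
#'
#' `ODI = (2/pi) * atan(1/kappa)`, mapping the Watson concentration to
#' `[0, 1]`; 0 means perfectly parallel sticks (`kappa -> Inf`), 1 means an
#' isotropic orientation distribution (`kappa = 0`, by limit convention).
#'
#' @param kappa Watson concentration parameter(s), `>= 0` (may be `Inf`).
#' @returns ODI value(s) in `[0, 1]`.
#' @export
watson_odi <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  ifelse(is.infinite(kappa), 0, (2 / pi) * atan2(1, kappa))
}

#' Inverse of [watson_odi()]
#' @param odi ODI value(s) in `[0, 1]`.
#' @returns Watson concentration(s).
#' @export
odi_to_kappa <- function(odi) {
  stopifnot(all(odi >= 0 & odi <= 1))
  ifelse(odi == 0, Inf, 1 / tan(pi * odi / 2))
}

# Gauss-Legendre nodes/weights on [-1, 1], cached per order.
gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(order = 64) {
  key <- as.character(order)
  if (is.null(gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(order, -1, 1)
    gl_cache[[key]] <- list(nodes = gl$x, weights = gl$w)
  }
  gl_cache[[key]]
}

#' Watson-averaged stick attenuation
#'
#' Expected stick attenuation `E[exp(-b d_par (g.n)^2)]` with stick
#' orientations `n` following a Watson distribution of concentration `kappa`
#' about mean direction `mu`. Computed by exact reduction of the spherical
#' integral of the rank-2 quadratic form to a one-dimensional Gauss-Legendre
#' quadrature with a Bessel-I0 kernel.
#'
#' @param cosbeta Cosine(s) of the angle between gradient and `mu`.
#' @param bd Product(s) `b * d_par` (dimensionless attenuation strength).
#' @param kappa Watson concentration(s); `Inf` gives the coherent stick.
#' @param quad_order Gauss-Legendre order (default 64).
#' @returns Attenuation value(s) in `(0, 1]`.
#' @export
watson_stick <- function(cosbeta, bd, kappa, quad_order = 64) {
  n <- max(length(cosbeta), length(bd), length(kappa))
  gl <- gauss_legendre(quad_order)
  watson_stick_cpp(rep_len(cosbeta, n), rep_len(bd, n), rep_len(kappa, n),
                   gl$nodes, gl$weights)
}

#' NODDI three-compartment signal
#'
#' Watson-dispersed stick (intraneurite) + tortuosity-constrained zeppelin
#' (extraneurite) + isotropic CSF ball, relative to `S0 = 1`:
#' `S = (1 - f_iso) * (f_in * S_in + (1 - f_in) * S_en) + f_iso * S_iso`.
#' The extraneurite perpendicular diffusivity follows the standard tortuosity
#' constraint `d_perp = d_par * (1 - f_in)`. Parallel diffusivity is fixed at
#' 1.7 um^2/ms and CSF diffusivity at 3.0 um^2/ms by default.
#'
#' @param f_iso CSF signal fraction in `[0, 1]`.
#' @param f_in Intraneurite fraction of the non-CSF signal, in `[0, 1]`.
#' @param kappa Watson concentration (`>= 0`, may be `Inf`).
#' @param mu Unit 3-vector mean orientation.
#' @param scheme An [acquisition_scheme()].
#' @param volume_index Volume indices (default all volumes).
#' @param d_par Intrinsic parallel diffusivity (um^2/ms).
#' @param d_iso CSF diffusivity (um^2/ms).
#' @param quad_order Gauss-Legendre order for the Watson integrals.
#' @returns Signal value(s) in `(0, 1]`.
#' @export
noddi_signal <- function(f_iso, f_in, kappa, mu, scheme,
                         volume_index = seq_len(scheme$n_volumes),
                         d_par = 1.7, d_iso = 3.0, quad_order = 64) {
  stopifnot(f_iso >= 0, f_iso <= 1, f_in >= 0, f_in <= 1, kappa >= 0)
  mu <- mu / sqrt(sum(mu^2))
  g <- scheme$directions[volume_index, , drop = FALSE]
  b <- scheme$b[volume_index]
  cosb <- as.vector(g %*% mu)
  s_in <- watson_stick(cosb, b * d_par, kappa, quad_order)
  d_perp <- d_par * (1 - f_in)
  s_en <- exp(-b * d_perp) * watson_stick(cosb, b * (d_par - d_perp), kappa, quad_order)
  s_iso <- exp(-b * d_iso)
  (1 - f_iso) * (f_in * s_in + (1 - f_in) * s_en) + f_iso * s_iso
}

# Roots of 2x cos x + (x^2 - 2) sin x = 0, the stationary points of the
# first-order spherical Bessel function j1; used by the GPD sphere signal.
j1prime_roots <- local({
  roots <- NULL
  function(n = 20) {
    if (is.null(roots) || length(roots) < n) {
      f <- function(x) 2 * x * cos(x) + (x^2 - 2) * sin(x)
      r <- numeric(n)
      lo <- 1e-6
      for (m in seq_len(n)) {
        hi <- (m + 0.6) * pi
        # bracket each root between successive extrema of the oscillation
        grid <- seq(lo + 1e-8, hi, length.out = 400)
        fg <- f(grid)
        idx <- which(diff(sign(fg)) != 0)[1]
        r[m] <- stats::uniroot(f, c(grid[idx], grid[idx + 1]), tol = 1e-12)$root
        lo <- r[m]
      }
      roots <<- r
    }
    roots[seq_len(n)]
  }
})

#' Restricted-diffusion sphere signal (GPD approximation)
#'
#' Gaussian-phase-distribution signal of water diffusing inside an
#' impermeable sphere under a pulsed-gradient spin-echo experiment
#' (Murday-Cotts/Balinov series over the stationary points of the first-order
#' spherical Bessel function).
#'
#' @param r_s Sphere radius (um), `> 0`; vectorised.
#' @param d_is Intra-sphere diffusivity (um^2/ms), `> 0`.
#' @param b b-value(s) (ms/um^2).
#' @param delta Gradient pulse duration (ms).
#' @param Delta Pulse separation (ms); `delta < Delta`.
#' @param n_terms Number of series terms (default 30). A warning is raised if
#'   the last retained term contributes more than `tol` to the log-signal.
#' @param tol Truncation tolerance on the log-signal (default 1e-7).
#' @returns Signal value(s) in `(0, 1]`.
#' @export
sphere_signal_gpd <- function(r_s, d_is = 3.0, b, delta = 7, Delta = 24,
                              n_terms = 30, tol = 1e-7) {
  if (any(r_s <= 0)) stop("r_s must be positive")
  if (d_is <= 0) stop("d_is must be positive")
  if (!(delta < Delta)) stop("delta must be smaller than Delta")
  n <- max(length(r_s), length(b))
  r_s <- rep_len(r_s, n); b <- rep_len(b, n)
  x <- j1prime_roots(n_terms)                     # dimensionless roots
  gamg2 <- b / (delta^2 * (Delta - delta / 3))    # (gamma g)^2, 1/(ms^2 um^2)
  logS <- numeric(n)
  last_term <- numeric(n)
  for (i in seq_len(n)) {
    alpha2 <- (x / r_s[i])^2                      # 1/um^2
    a <- alpha2 * d_is                            # 1/ms
    bracket <- 2 * delta / a -
      (2 + exp(-a * (Delta - delta)) - 2 * exp(-a * delta) -
         2 * exp(-a * Delta) + exp(-a * (Delta + delta))) / a^2
    terms <- bracket / (alpha2 * (alpha2 * r_s[i]^2 - 2))
    logS[i] <- -2 * gamg2[i] * sum(terms)
    last_term[i] <- abs(2 * gamg2[i] * terms[n_terms])
  }
  if (any(last_term > tol))
    warning("GPD series truncation error above tolerance; increase n_terms")
  exp(logS)
}

#' Powder-averaged stick attenuation (closed form)
#'
#' Direction average of `exp(-b d (g.n)^2)` over the sphere:
#' `sqrt(pi / (4 b d)) * erf(sqrt(b d))`, with limit 1 as `b d -> 0`.
#'
#' @param bd Product(s) `b * d_in`.
#' @returns Attenuation value(s) in `(0, 1]`.
#' @export
stick_powder <- function(bd) {
  out <- rep(1, length(bd))
  pos <- bd > 1e-12
  x <- sqrt(bd[pos])
  out[pos] <- sqrt(pi) / (2 * x) * pracma::erf(x)
  out
}

#' SANDI direction-averaged signal
#'
#' Powder-averaged three-compartment soma-and-neurite signal:
#' `S(b) = (1 - f_ec) * (f_in * S_in + (1 - f_in) * S_is) + f_ec * S_ec`,
#' where `S_in` is the powder-averaged stick, `S_is` the GPD sphere signal of
#' radius `r_s` with intra-soma diffusivity fixed at 3.0 um^2/ms, and `S_ec`
#' an isotropic Gaussian ball `exp(-b d_ec)`.
#'
#' @param f_ec Extracellular signal fraction in `[0, 1]`.
#' @param f_in Intraneurite fraction of the cellular signal, in `[0, 1]`.
#' @param r_s Soma radius (um).
#' @param d_in Intraneurite diffusivity (um^2/ms).
#' @param d_ec Extracellular diffusivity (um^2/ms).
#' @param b b-value(s) (ms/um^2); vectorised.
#' @param delta,Delta Pulse timings (ms).
#' @param d_is Intra-soma diffusivity (um^2/ms), fixed at 3.0 by convention.
#' @returns Direction-averaged signal value(s) in `(0, 1]`.
#' @export
sandi_powder_signal <- function(f_ec, f_in, r_s, d_in, d_ec, b,
                                delta = 7, Delta = 24, d_is = 3.0) {
  stopifnot(f_ec >= 0, f_ec <= 1, f_in >= 0, f_in <= 1, r_s > 0)
  s_in <- stick_powder(b * d_in)
  s_is <- sphere_signal_gpd(r_s, d_is, b, delta, Delta)
  s_ec <- exp(-b * d_ec)
  (1 - f_ec) * (f_in * s_in + (1 - f_in) * s_is) + f_ec * s_ec
}

#' SANDI derived signal-fraction maps
#'
#' Converts raw SANDI fractions to the reported maps:
#' `fneurite = (1 - f_ec) * f_in`, `fsoma = (1 - f_ec) * (1 - f_in)`,
#' `fextracellular = f_ec`; the three sum to 1 by construction.
#'
#' @param f_ec,f_in Raw SANDI fractions (vectorised).
#' @returns A tibble with columns `fneurite`, `fsoma`, `fextracellular`.
#' @export
sandi_derived_fractions <- function(f_ec, f_in) {
  tibble::tibble(fneurite = (1 - f_ec) * f_in,
                 fsoma = (1 - f_ec) * (1 - f_in),
                 fextracellular = f_ec)
}
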