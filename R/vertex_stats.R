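#' Vertex-wise age-contrast t-map
#'
#' Fits, at every surface vertex, the linear model
#' `value ~ age + sex + age:sex` across participants (hemisphere-averaged
#' maps) and extracts the t-statistic of the age coefficient,
#' `t = beta_age / SE(beta_age)`. Vertices with missing data are fit on
#' complete cases; zero-variance or exact-fit vertices are masked (the latter
#' flagged).
#'
#' @param maps Participant x vertex matrix of metric values.
#' @param cohort Data frame with one row per participant (matching `maps`
#'   rows): columns `age` and `sex`.
#' @param min_n Minimum participants per vertex (default 5).
#' @param metric Metric name carried in the result.
#' @returns Object of class `vertex_stat_map`: tibble `stats` (`vertex`, `t`,
#'   `beta_age`, `se`, `df`, `n`), logical `valid`, `metric` name attribute.
#' @export
vertex_glm_tmap <- function(maps, cohort, min_n = 5, metric = "metric") {
  stopifnot(nrow(maps) == nrow(cohort))
  if (nrow(cohort) < min_n) stop("need at least ", min_n, " participants")
  X <- model.matrix(~ age * sex, data = cohort)
  age_col <- which(colnames(X) == "age")
  n_vtx <- ncol(maps)
  tval <- beta <- se <- rep(NA_real_, n_vtx)
  dfres <- nobs <- rep(NA_integer_, n_vtx)
  exact <- rep(FALSE, n_vtx)
  complete <- !is.na(maps)
  all_complete <- which(colSums(complete) == nrow(maps))
  # vectorised fit for complete vertices (shared design)
  if (length(all_complete)) {
    qrX <- qr(X)
    Y <- maps[, all_complete, drop = FALSE]
    cf <- qr.coef(qrX, Y)
    res <- Y - X %*% cf
    df <- nrow(X) - ncol(X)
    sigma2 <- colSums(res^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se_a <- sqrt(sigma2 * XtXinv[age_col, age_col])
    beta[all_complete] <- cf[age_col, ]
    se[all_complete] <- se_a
    tval[all_complete] <- cf[age_col, ] / se_a
    dfres[all_complete] <- df
    nobs[all_complete] <- nrow(X)
    exact[all_complete] <- sigma2 < .Machine$double.eps * 100
  }
  partial <- setdiff(which(colSums(complete) >= min_n), all_complete)
  for (v in partial) {
    ok <- complete[, v]
    Xi <- X[ok, , drop = FALSE]
    if (qr(Xi)$rank < ncol(Xi)) next
    fit <- stats::lm.fit(Xi, maps[ok, v])
    df <- sum(ok) - ncol(Xi)
    if (df < 1) next
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(qr.R(qr(Xi)))
    beta[v] <- coef(fit)[age_col]
    se[v] <- sqrt(sigma2 * XtXinv[age_col, age_col])
    tval[v] <- beta[v] / se[v]
    dfres[v] <- df
    nobs[v] <- sum(ok)
    exact[v] <- sigma2 < .Machine$double.eps * 100
  }
  tval[exact] <- NA_real_
  valid <- is.finite(tval)
  structure(list(stats = tibble::tibble(vertex = seq_len(n_vtx), t = tval,
                                        beta_age = beta, se = se, df = dfres,
                                        n = nobs),
                 valid = valid, exact_fit = exact, metric = metric),
            class = "vertex_stat_map")
}

#' @export
print.vertex_stat_map <- function(x, ...) {
  cat("<vertex_stat_map> ", x$metric, ": ", sum(x$valid), "/",
      length(x$valid), " valid vertices, mean |t| = ",
      round(mean(abs(x$stats$t[x$valid])), 3), "\n", sep = "")
  invisible(x)
}

#' Correlate an age-contrast map with the positional gradients
#'
#' Absolute Pearson correlations of a vertex t-map with the anterior-
#' posterior and proximal-distal positional gradients, plus the mean absolute
#' t-statistic over valid vertices (the study's effect-size summary).
#'
#' @param tmap A [vertex_glm_tmap()] result (or numeric vector of t-values).
#' @param gradients A [positional_gradients()] tibble.
#' @returns One-row tibble: `metric`, `r_ap`, `r_pd`, `mean_abs_t`, `n`.
#' @export
gradient_correlation <- function(tmap, gradients) {
  tv <- if (inherits(tmap, "vertex_stat_map")) tmap$stats$t else tmap
  metric <- if (inherits(tmap, "vertex_stat_map")) tmap$metric else "metric"
  ok <- is.finite(tv)
  if (sum(ok) < 3) stop("fewer than 3 valid vertices")
  if (sd(tv[ok]) == 0)
    stop("constant t-map: gradient correlation undefined")
  tibble::tibble(metric = metric,
                 r_ap = abs(cor(tv[ok], gradients$AP[ok])),
                 r_pd = abs(cor(tv[ok], gradients$PD[ok])),
                 mean_abs_t = mean(abs(tv[ok])), n = sum(ok))
}

#' Spatial permutation (spin) test between two surface maps
#'
#' Tests the Pearson correlation of two per-vertex maps against a null that
#' preserves spatial autocorrelation: map B is rigidly transformed on the
#' unfolded rectangular grid (toroidal translations, optionally with axis
#' flips), the correlation recomputed for each of `n_perm` seeded random
#' transformations, and the two-sided p-value computed with the finite-sample
#' correction `p = (1 + #{|R_null| >= |R_obs|}) / (n_perm + 1)`.
#'
#' @param map_a,map_b Numeric vectors over the unfolded grid vertices.
#' @param surface The surface defining the grid (`n_ap` x `n_pd`), or a list
#'   with `n_ap`, `n_pd`.
#' @param n_perm Number of permutations (default 2500).
#' @param seed Integer seed.
#' @param flips Include the four axis-flip combinations (default `TRUE`).
#' @returns Object of class `spin_test_result` (also a one-row tibble):
#'   `r`, `p`, `n_perm`, with the null distribution in attribute `null`.
#' @export
spin_test <- function(map_a, map_b, surface, n_perm = 2500, seed = 1L,
                      flips = TRUE) {
  n_ap <- surface$n_ap; n_pd <- surface$n_pd
  if (length(map_a) != n_ap * n_pd || length(map_b) != n_ap * n_pd)
    stop("maps must live on the surface grid")
  if (n_perm < 100) stop("use at least 100 permutations")
  if (n_ap < 3 || n_pd < 3) stop("grid too small for distinct shifts")
  # vertices are pd-fastest (expand_grid ap x pd)
  A <- matrix(map_a, n_pd, n_ap)
  B <- matrix(map_b, n_pd, n_ap)
  obs <- cor(as.vector(A), as.vector(B), use = "complete.obs")
  withr_seed(seed, {
    di <- sample.int(n_pd, n_perm, replace = TRUE) - 1L
    dj <- sample.int(n_ap, n_perm, replace = TRUE) - 1L
    fl <- if (flips) matrix(sample(c(TRUE, FALSE), 2 * n_perm, replace = TRUE),
                            n_perm, 2) else matrix(FALSE, n_perm, 2)
  })
  rot_idx <- function(n, k) ((seq_len(n) - 1L + k) %% n) + 1L
  null <- vapply(seq_len(n_perm), function(k) {
    Bk <- B
    if (fl[k, 1]) Bk <- Bk[n_pd:1, , drop = FALSE]
    if (fl[k, 2]) Bk <- Bk[, n_ap:1, drop = FALSE]
    Bk <- Bk[rot_idx(n_pd, di[k]), rot_idx(n_ap, dj[k]), drop = FALSE]
    suppressWarnings(cor(as.vector(A), as.vector(Bk), use = "complete.obs"))
  }, 0)
  null <- null[is.finite(null)]
  p <- (1 + sum(abs(null) >= abs(obs))) / (length(null) + 1)
  out <- tibble::tibble(r = obs, p = p, n_perm = length(null), seed = seed)
  attr(out, "null") <- null
  class(out) <- c("spin_test_result", class(out))
  out
}

#' Correlate age-contrast maps with a battery of reference maps
#'
#' All-pairs Pearson correlations between vertex t-maps and reference surface
#' maps (e.g. quantitative R1, histological stains, PET synaptic density),
#' with spin-test p-values and Benjamini-Hochberg adjustment across the whole
#' matrix.
#'
#' @param tmaps Named list of [vertex_glm_tmap()] results or numeric vectors.
#' @param reference_maps Named list of numeric vectors on the same grid.
#' @param surface The shared surface.
#' @param n_perm Spin-test permutations (default 2500).
#' @param seed Integer seed.
#' @returns Tibble, one row per (tmap, reference): `metric`, `reference`,
#'   `r`, `p`, `p_adj`.
#' @export
reference_map_battery <- function(tmaps, reference_maps, surface,
                                  n_perm = 2500, seed = 1L) {
  res <- purrr::imap_dfr(tmaps, function(tm, mname) {
    tv <- if (inherits(tm, "vertex_stat_map")) tm$stats$t else tm
    if (length(tv) != surface$n_ap * surface$n_pd) stop("shape mismatch")
    purrr::imap_dfr(reference_maps, function(rm, rname) {
      st <- spin_test(tv, rm, surface, n_perm = n_perm,
                      seed = seed + utf8_sum(paste(mname, rname)))
      tibble::tibble(metric = mname, reference = rname, r = st$r, p = st$p)
    })
  })
  res$p_adj <- fdr_bh(res$p)
  res
}

# deterministic small integer from a string (seed offsets per map pair)
utf8_sum <- function(s) sum(utf8ToInt(s)) %% 10000L

#' Synthetic reference surface maps
#'
#' Gaussian random fields on the unfolded grid with controlled spatial
#' autocorrelation, generated by Fourier-domain filtering of seeded white
#' noise. These are synthetic stand-ins for the reference maps a real
#' analysis would take from histology/PET/post-mortem MRI resources
#' (quantitative R1, Bielschowsky and Merker stains, SV2A PET, calretinin,
#' calbindin and parvalbumin immunoreactivity); they reproduce only their
#' smoothness, not their anatomy.
#'
#' @param surface The surface defining the grid.
#' @param names Map names (default the seven-stand-in battery).
#' @param smoothness Gaussian kernel SD in grid cells (default 5).
#' @param seed Integer seed.
#' @returns Named list of per-vertex numeric vectors (z-scored).
#' @export
synthetic_reference_maps <- function(surface,
                                     names = c("qr1", "bielschowsky",
                                               "merker", "sv2a", "calretinin",
                                               "calbindin", "parvalbumin"),
                                     smoothness = 5, seed = 42L) {
  n_ap <- surface$n_ap; n_pd <- surface$n_pd
  out <- list()
  withr_seed(seed, {
    for (nm in names) {
      z <- matrix(rnorm(n_ap * n_pd), n_pd, n_ap)
      sm <- gaussian_field_filter(z, smoothness)
      out[[nm]] <- as.vector((sm - mean(sm)) / sd(sm))
    }
  })
  out
}

# periodic Gaussian smoothing via FFT
gaussian_field_filter <- function(z, sigma) {
  n1 <- nrow(z); n2 <- ncol(z)
  f1 <- c(0:floor(n1 / 2), -((ceiling(n1 / 2) - 1):1)) / n1
  f2 <- c(0:floor(n2 / 2), -((ceiling(n2 / 2) - 1):1)) / n2
  K <- exp(-2 * pi^2 * sigma^2 * outer(f1^2, f2^2, `+`))
  Re(stats::fft(stats::fft(z) * K, inverse = TRUE)) / (n1 * n2)
}
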