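# Independent oracles used by the acceptance checks.

# Monte-Carlo random walk of restricted diffusion in an impermeable sphere
# under a pulsed-gradient spin-echo experiment: particles diffuse with
# reflecting boundary, accumulate phase under rectangular gradient lobes, and
# the signal is the mean cosine of the phase.
mc_sphere_signal <- function(r, d, b, delta, Delta, n_walk = 1e5,
                             dt = 0.025, seed = 2) {
  set.seed(seed)
  gamg <- sqrt(b / (delta^2 * (Delta - delta / 3)))
  x <- matrix(rnorm(n_walk * 3), n_walk, 3)
  x <- x / sqrt(rowSums(x^2)) * r * runif(n_walk)^(1 / 3)
  sdstep <- sqrt(2 * d * dt)
  nt <- round((Delta + delta) / dt)
  phase <- numeric(n_walk)
  for (s in seq_len(nt)) {
    t_mid <- (s - 0.5) * dt
    gz <- if (t_mid < delta) 1 else if (t_mid >= Delta && t_mid < Delta + delta) -1 else 0
    prop <- x + matrix(rnorm(n_walk * 3, sd = sdstep), n_walk, 3)
    rr <- sqrt(rowSums(prop^2))
    out <- rr > r
    if (any(out)) prop[out, ] <- prop[out, ] * ((2 * r - rr[out]) / rr[out])
    x <- prop
    if (gz != 0) phase <- phase + gamg * gz * x[, 3] * dt
  }
  mean(cos(phase))
}

# random NODDI / SANDI parameter draws within identifiable ranges
draw_noddi_params <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    f_iso = runif(n, 0, 0.3), f_in = runif(n, 0.2, 0.8),
    kappa = runif(n, 0.5, 4)))
}

# SANDI draws span the values the study generator can produce (intercept
# ranges +/- the age span and four residual SDs). Outside this domain —
# large somas (r_s > ~8 um at these pulse timings) or extracellular-dominated
# voxels — the 5-shell powder inversion admits duplicate exact roots and no
# estimator can recover the generating parameters (demonstrated in
# test-fitting.R).
draw_sandi_params <- function(n, seed) {
  withr::with_seed(seed, {
    f_ec <- runif(n, 0.22, 0.48)
    f_soma <- pmin(runif(n, 0.35, 0.48), 1 - f_ec - 0.02)
    tibble::tibble(
      f_ec = f_ec, f_in = 1 - f_soma / (1 - f_ec),
      r_s = runif(n, 6, 8), d_in = runif(n, 1.4, 2.0),
      d_ec = runif(n, 0.8, 1.2))
  })
}

# signal matrices for a parameter table (optionally Rician-noised)
noddi_signal_matrix <- function(pars, scheme, mu, snr = Inf, seed = 1) {
  sig <- t(vapply(seq_len(nrow(pars)), function(i)
    noddi_signal(pars$f_iso[i], pars$f_in[i], pars$kappa[i], mu, scheme),
    numeric(scheme$n_volumes)))
  add_rician(sig, snr, seed)
}

sandi_signal_matrix <- function(pars, scheme, snr = Inf, seed = 1) {
  sig <- t(vapply(seq_len(nrow(pars)), function(i) {
    pw <- sandi_powder_signal(pars$f_ec[i], pars$f_in[i], pars$r_s[i],
                              pars$d_in[i], pars$d_ec[i], scheme$bvalues,
                              scheme$delta, scheme$Delta)
    pw[scheme$shell]
  }, numeric(scheme$n_volumes)))
  add_rician(sig, snr, seed)
}

add_rician <- function(sig, snr, seed) {
  if (!is.finite(snr)) return(sig)
  withr::with_seed(seed, {
    sqrt((sig + rnorm(length(sig), sd = 1 / snr))^2 +
           rnorm(length(sig), sd = 1 / snr)^2)
  })
}

# one synthetic-study replicate at the full cohort size, parcel-scope fits;
# returns parcel-level age correlations for the compartment metrics and MD
e2e_replicate <- function(rep_seed, ap_gradient = FALSE) {
  scheme <- default_scheme()
  # parcels of ~190 voxels per hemisphere, comparable to real 2-mm
  # hippocampal subfield parcels
  domain <- solve_laplace_all(
    generate_domain(c(20, 14, 10), curvature = 0.2, thickness = 6,
                    pad = 2, seed = 1))
  cohort <- generate_cohort(cohort_spec(88, seed = rep_seed))
  effects <- default_effect_spec(ap_gradient = ap_gradient)
  idx <- which(domain$mask)
  parc <- domain$subfield[idx]
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    prow <- cohort[i, ]
    hseed <- rep_seed * 1000L + i
    gt <- assign_ground_truth(domain, prow, effects,
                              residual_scope = "parcel", seed = hseed)
    dwi <- simulate_dwi(gt, scheme, snr = 50, seed = hseed)
    sig <- dwi_matrix(dwi, domain$mask)
    psig <- do.call(rbind, lapply(1:5, function(p)
      colMeans(sig[parc == p, , drop = FALSE])))
    san <- fit_sandi(psig, scheme, n_starts = 2, seed = hseed)
    dti <- fit_dti(psig, scheme)
    rows[[i]] <- tibble::tibble(
      participant = prow$participant, age = prow$age, sex = prow$sex,
      hemisphere = prow$hemisphere,
      parcel = factor(subfield_names(), levels = subfield_names()),
      fneurite = san$estimates$fneurite, fsoma = san$estimates$fsoma,
      fextracellular = san$estimates$fextracellular,
      md = dti$estimates$md)
  }
  tab <- dplyr::bind_rows(rows) |>
    tidyr::pivot_longer(c("fneurite", "fsoma", "fextracellular", "md"),
                        names_to = "metric", values_to = "value")
  list(cors = age_correlation_all(hemisphere_average(tab, force = TRUE)),
       domain = domain, cohort = cohort)
}

# AP-localised replicate: vertex-level MD age-contrast map vs the positional
# gradients (low-b shells only; the tensor fit does not use the rest)
e2e_ap_replicate <- function(rep_seed) {
  scheme <- acquisition_scheme(c(0, 0.5, 1.2), c(14L, 30L, 30L))
  domain <- solve_laplace_all(
    generate_domain(c(12, 10, 8), curvature = 0.2, thickness = 4,
                    pad = 2, seed = 1))
  surface <- build_midthickness_surface(domain, n_ap = 21, n_pd = 12)
  cohort <- generate_cohort(cohort_spec(88, seed = rep_seed))
  effects <- default_effect_spec(ap_gradient = TRUE)
  participants <- unique(cohort$participant)
  M <- matrix(NA_real_, length(participants), nrow(surface$vertices))
  for (pi in seq_along(participants)) {
    hr <- which(cohort$participant == participants[pi])
    vmaps <- lapply(hr, function(i) {
      hseed <- rep_seed * 1000L + i
      gt <- assign_ground_truth(domain, cohort[i, ], effects,
                                residual_scope = "parcel", seed = hseed)
      dwi <- simulate_dwi(gt, scheme, snr = 50, seed = hseed)
      md <- metric_volume(fit_dti(dwi, scheme, domain$mask), "md")
      sample_to_surface(md, surface)
    })
    M[pi, ] <- rowMeans(cbind(vmaps[[1]], vmaps[[2]]), na.rm = TRUE)
  }
  cohort1 <- cohort[match(participants, cohort$participant), ]
  tm <- vertex_glm_tmap(M, cohort1, metric = "md")
  gradient_correlation(tm, positional_gradients(surface))
}
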