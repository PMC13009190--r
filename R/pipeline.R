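#' Pipeline run configuration
#'
#' Collects every knob of the simulate-fit-geometry-sample-statistics
#' pipeline, with an explicit seed for each stochastic stage. The
#' configuration serialises losslessly to JSON (see [write_manifest()]).
#'
#' `demo_config()` is the reduced-scale profile (12 participants, small
#' domain, 200 permutations, parcel-scope compartment fits);
#' `full_config()` is the full-scale study profile (88 participants, 2500
#' permutations).
#'
#' @param n_participants Cohort size.
#' @param grid_shape Domain grid (voxels).
#' @param curvature,thickness Domain shape parameters ([generate_domain()]).
#' @param snr b = 0 signal-to-noise ratio of the simulated scans.
#' @param n_ap,n_pd Unfolded surface grid.
#' @param n_perm Spin-test permutations.
#' @param fit_scope `"parcel"` (fit compartment models on parcel-mean
#'   signals; fast) or `"voxel"` (fit every voxel).
#' @param residual_sd_scale,ap_gradient Passed to [default_effect_spec()].
#' @param age_distribution Passed to [cohort_spec()].
#' @param n_starts Multi-start count for the nonlinear fits.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @returns A list of class `run_config`.
#' @export
run_config <- function(n_participants = 88, grid_shape = c(32, 20, 14),
                       curvature = 0.3, thickness = 5, snr = 50,
                       n_ap = 121, n_pd = 60, n_perm = 2500,
                       fit_scope = c("parcel", "voxel"),
                       residual_sd_scale = 1, ap_gradient = FALSE,
                       age_distribution = "uniform", n_starts = 5,
                       seed = 1L, out_dir = NULL) {
  structure(list(n_participants = n_participants, grid_shape = grid_shape,
                 curvature = curvature, thickness = thickness, snr = snr,
                 n_ap = n_ap, n_pd = n_pd, n_perm = n_perm,
                 fit_scope = match.arg(fit_scope),
                 residual_sd_scale = residual_sd_scale,
                 ap_gradient = ap_gradient,
                 age_distribution = age_distribution,
                 n_starts = n_starts, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param ... Overrides passed to [run_config()].
#' @export
demo_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 12, grid_shape = c(20, 14, 9), curvature = 0.3,
         n_ap = 41, n_pd = 20, n_perm = 200, fit_scope = "parcel"),
    list(...))
  do.call(run_config, args)
}

#' @rdname run_config
#' @export
full_config <- function(...) {
  do.call(run_config, utils::modifyList(list(n_participants = 88,
                                             n_perm = 2500), list(...)))
}

#' Run the full synthetic-study pipeline
#'
#' Executes the stages in dependency order: cohort and domain generation,
#' Laplace coordinate solution, surface construction, per-hemisphere DWI
#' simulation, DTI/NODDI/SANDI fitting, cosine-similarity orientation maps,
#' surface sampling and parcel averaging, hemisphere handling, parcel-level
#' age statistics (Pearson ladder, interaction F-tests with FDR) and
#' vertex-level statistics (age-contrast t-maps, positional-gradient
#' correlations, spin-test reference battery against synthetic reference
#' maps). If `config$out_dir` is set, tables and a JSON manifest are written
#' there.
#'
#' @param config A [run_config()].
#' @param metrics Which metrics to analyse (default the study's micro- and
#'   macrostructural set).
#' @returns A list of class `pipeline_result`: `cohort`, `surface` (geometry),
#'   `metric_table` (per-hemisphere), `table_avg` (hemisphere-averaged,
#'   subfield parcels), `table_longaxis`, `age_correlations`,
#'   `interaction_tests`, `tmaps`, `gradient_correlations`,
#'   `reference_battery`, `config`.
#' @export
run_pipeline <- function(config = demo_config(),
                         metrics = c("md", "fa", "fneurite_noddi", "odi",
                                     "fneurite", "fsoma", "fextracellular",
                                     "r_s", "long_axis", "tangential",
                                     "radial", "thickness", "gyrification")) {
  stopifnot(inherits(config, "run_config"))
  scheme <- default_scheme()
  cohort <- generate_cohort(cohort_spec(
    n_participants = config$n_participants,
    age_distribution = config$age_distribution, seed = config$seed))
  effects <- default_effect_spec(residual_sd_scale = config$residual_sd_scale,
                                 ap_gradient = config$ap_gradient)
  domain <- generate_domain(config$grid_shape, curvature = config$curvature,
                            thickness = config$thickness, seed = config$seed)
  domain <- solve_laplace_all(domain)
  surface <- build_midthickness_surface(domain, config$n_ap, config$n_pd)
  grads <- lapply(domain$psi, gradient_field, mask = domain$mask,
                  voxel_size = domain$voxel_size)
  mac <- macrostructure(domain, surface)

  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    prow <- cohort[i, ]
    hseed <- config$seed + 13L * i
    gt <- assign_ground_truth(domain, prow, effects, seed = hseed)
    dwi <- simulate_dwi(gt, scheme, snr = config$snr, seed = hseed + 1L)
    maps <- fit_metric_maps(dwi, scheme, domain, grads, config, hseed)
    maps$thickness <- NULL  # per-vertex macrostructure handled below
    vertex_vals <- lapply(maps, sample_to_surface, surface = surface)
    # all participants share the synthetic domain; emulate per-scan anatomy /
    # segmentation variability (no age trend) so macrostructure has nonzero
    # between-participant variance, as in a real cohort
    withr_seed(hseed + 2L, {
      n_vtx <- nrow(surface$vertices)
      vertex_vals$thickness <- mac$vertex$thickness *
        exp(rnorm(1, 0, 0.04)) + rnorm(n_vtx, 0, 0.02)
      vertex_vals$gyrification <- mac$vertex$gyrification *
        exp(rnorm(1, 0, 0.04)) + rnorm(n_vtx, 0, 0.02)
    })
    vertex_vals <- vertex_vals[intersect(metrics, names(vertex_vals))]
    rows[[i]] <- list(
      sub = metric_table(vertex_vals, surface, prow, "subfield"),
      ap = metric_table(vertex_vals, surface, prow, "longaxis"),
      vertex = vertex_vals)
  }
  tab_sub <- purrr::map_dfr(rows, "sub")
  tab_ap <- purrr::map_dfr(rows, "ap")

  hemi_tests <- interaction_f_tests(tab_sub, "age:hemisphere")
  table_avg <- hemisphere_average(tab_sub, hemi_tests)
  table_ap_avg <- hemisphere_average(tab_ap, force = TRUE)
  age_cor <- age_correlation_all(table_avg)
  fam_tests <- dplyr::bind_rows(
    dplyr::mutate(interaction_f_tests(table_avg, "age:sex"),
                  family = "age:sex"),
    dplyr::mutate(interaction_f_tests(table_avg, "age:parcel"),
                  family = "age:parcel"),
    dplyr::mutate(hemi_tests, family = "age:hemisphere"))

  # hemisphere-averaged per-participant vertex maps -> t-maps
  participants <- unique(cohort$participant)
  cohort1 <- cohort[match(participants, cohort$participant), ]
  tmaps <- list()
  use_metrics <- intersect(metrics, names(rows[[1]]$vertex))
  for (m in use_metrics) {
    M <- matrix(NA_real_, length(participants), config$n_ap * config$n_pd)
    for (pi in seq_along(participants)) {
      hr <- which(cohort$participant == participants[pi])
      vals <- rowMeans(cbind(rows[[hr[1]]]$vertex[[m]],
                             rows[[hr[2]]]$vertex[[m]]), na.rm = TRUE)
      M[pi, ] <- vals
    }
    if (all(apply(M, 2, function(x) sd(x, na.rm = TRUE) == 0 ||
                  all(is.na(x))))) next
    tmaps[[m]] <- vertex_glm_tmap(M, cohort1, metric = m)
  }
  pg <- positional_gradients(surface)
  grad_cor <- purrr::map_dfr(tmaps, gradient_correlation, gradients = pg)
  refs <- synthetic_reference_maps(surface, seed = config$seed + 7L)
  battery <- reference_map_battery(tmaps, refs, surface,
                                   n_perm = config$n_perm,
                                   seed = config$seed + 11L)

  result <- structure(
    list(cohort = cohort, domain = domain, surface = surface,
         metric_table = tab_sub, metric_table_longaxis = tab_ap,
         table_avg = table_avg, table_longaxis = table_ap_avg,
         age_correlations = age_cor, interaction_tests = fam_tests,
         tmaps = tmaps, gradient_correlations = grad_cor,
         reference_battery = battery, reference_maps = refs,
         macrostructure = mac, config = config),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

# per-hemisphere metric volumes from one simulated scan
fit_metric_maps <- function(dwi, scheme, domain, grads, config, seed) {
  mask <- domain$mask
  dti <- fit_dti(dwi, scheme, mask)
  maps <- list(md = metric_volume(dti, "md"), fa = metric_volume(dti, "fa"))
  peaks <- primary_peak(tensor_field = dti_tensor_array(dti), mask = mask)
  cs <- cosine_similarity_maps(peaks, grads, mask)
  maps <- c(maps, cs)
  if (config$fit_scope == "voxel") {
    nod <- fit_noddi(dwi, scheme, mask, n_starts = config$n_starts,
                     seed = seed)
    san <- fit_sandi(dwi, scheme, mask, n_starts = config$n_starts,
                     seed = seed)
    maps$fneurite_noddi <- metric_volume(nod, "f_in")
    maps$odi <- metric_volume(nod, "odi")
    for (m in c("fneurite", "fsoma", "fextracellular", "r_s"))
      maps[[m]] <- metric_volume(san, m)
  } else {
    sig <- dwi_matrix(dwi, mask)
    idx <- which(mask)
    parc <- domain$subfield[idx]
    psig <- do.call(rbind, lapply(1:5, function(p)
      colMeans(sig[parc == p, , drop = FALSE])))
    nod <- fit_noddi(psig, scheme, n_starts = config$n_starts, seed = seed)
    san <- fit_sandi(psig, scheme, n_starts = config$n_starts, seed = seed)
    to_vol <- function(vals) {
      arr <- array(NA_real_, domain$grid_shape)
      arr[idx] <- vals[parc]
      arr
    }
    maps$fneurite_noddi <- to_vol(nod$estimates$f_in)
    maps$odi <- to_vol(nod$estimates$odi)
    for (m in c("fneurite", "fsoma", "fextracellular", "r_s"))
      maps[[m]] <- to_vol(san$estimates[[m]])
  }
  maps
}

dti_tensor_array <- function(dti) {
  arr <- array(NA_real_, c(dti$grid_shape, 6))
  cols <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  for (c6 in 1:6) {
    sl <- array(NA_real_, dti$grid_shape)
    vals <- dti$estimates[[cols[c6]]]
    vals[!dti$diagnostics$converged] <- NA_real_
    sl[dti$estimates$voxel] <- vals
    arr[, , , c6] <- sl
  }
  arr
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_tsv(result$cohort, file.path(dir, "cohort.tsv"))
  write_table_tsv(result$metric_table, file.path(dir, "metrics_subfield.tsv"))
  write_table_tsv(result$metric_table_longaxis,
                  file.path(dir, "metrics_longaxis.tsv"))
  write_table_tsv(result$age_correlations,
                  file.path(dir, "age_correlations.tsv"))
  write_table_tsv(result$interaction_tests,
                  file.path(dir, "interaction_f_tests.tsv"))
  write_table_tsv(result$gradient_correlations,
                  file.path(dir, "gradient_correlations.tsv"))
  write_table_tsv(result$reference_battery,
                  file.path(dir, "reference_battery.tsv"))
  write_surface_tsv(result$surface, file.path(dir, "midthickness.tsv"),
                    maps = lapply(result$tmaps, function(t) t$stats$t))
  cfg <- result$config
  class(cfg) <- NULL
  write_manifest(list(config = cfg,
                      package_version = as.character(utils::packageVersion("hippdiff")),
                      r_version = R.version.string,
                      timestamp = format(Sys.time(), tz = "UTC")),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> n =", nrow(x$cohort) / 2, "participants,",
      length(x$tmaps), "age-contrast maps,",
      nrow(x$age_correlations), "parcel correlations\n")
  invisible(x)
}

#' Write a markdown report of a pipeline run
#'
#' Renders the study-style panels from a completed run into `<run_dir>`:
#' age-scatter panels per metric (with regression lines and R annotations),
#' the gradient-correlation summary and the reference-battery heatmaps, plus
#' a markdown file linking them with the headline numbers. Metrics missing
#' from the run are noted and skipped.
#'
#' @param result A [run_pipeline()] result.
#' @param run_dir Output directory (defaults to the config's `out_dir`).
#' @returns Path of the markdown report, invisibly.
#' @export
make_report <- function(result, run_dir = result$config$out_dir) {
  if (is.null(run_dir)) stop("no output directory")
  if (!nrow(result$age_correlations)) stop("empty results")
  dir.create(file.path(run_dir, "figures"), showWarnings = FALSE,
             recursive = TRUE)
  lines <- c("# Synthetic hippocampal microstructure run", "",
             sprintf("Participants: %d; metrics: %d; spin permutations: %d",
                     nrow(result$cohort) / 2,
                     length(unique(result$age_correlations$metric)),
                     result$config$n_perm), "", "## Age correlations", "")
  for (m in unique(result$age_correlations$metric)) {
    fp <- file.path(run_dir, "figures", paste0("age_", gsub("[^a-z0-9_]", "_", m), ".png"))
    p <- plot_age_scatter(result$table_avg, m, result$age_correlations)
    ggplot2::ggsave(fp, p, width = 7, height = 5, dpi = 120)
    lines <- c(lines, sprintf("![age scatter %s](figures/%s)", m, basename(fp)))
  }
  missing <- setdiff(unique(result$metric_table$metric),
                     unique(result$age_correlations$metric))
  if (length(missing))
    lines <- c(lines, "", sprintf("Panels omitted (no results): %s",
                                  paste(missing, collapse = ", ")))
  gc_path <- file.path(run_dir, "figures", "gradient_correlations.png")
  gcp <- ggplot2::ggplot(result$gradient_correlations,
                         ggplot2::aes(x = .data$r_ap, y = .data$r_pd,
                                      size = .data$mean_abs_t)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(ggplot2::aes(label = .data$metric), size = 2.5,
                       vjust = -1) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "|R| with AP gradient", y = "|R| with PD gradient",
                  size = "mean |t|") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(gc_path, gcp, width = 6, height = 5, dpi = 120)
  b1 <- file.path(run_dir, "figures", "battery_r.png")
  b2 <- file.path(run_dir, "figures", "battery_p.png")
  ggplot2::ggsave(b1, plot_reference_battery(result$reference_battery, "r"),
                  width = 7, height = 5, dpi = 120)
  ggplot2::ggsave(b2, plot_reference_battery(result$reference_battery, "p"),
                  width = 7, height = 5, dpi = 120)
  lines <- c(lines, "", "## Gradient correlations",
             "![gradients](figures/gradient_correlations.png)", "",
             "## Reference battery (synthetic stand-in maps)",
             "![battery R](figures/battery_r.png)",
             "![battery p](figures/battery_p.png)")
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
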