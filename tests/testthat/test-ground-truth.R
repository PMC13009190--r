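test_that("derived signal fractions live on the simplex", {
  gt <- slab_ground_truth()
  idx <- which(gt$mask)
  total <- gt$fneurite[idx] + gt$fsoma[idx] + gt$fextracellular[idx]
  expect_lt(max(abs(total - 1)), 1e-9)
  expect_true(all(gt$r_s[idx] > 0))
  expect_true(all(gt$kappa[idx] >= 0))
  mu_norm <- sqrt(gt$mu[, , , 1]^2 + gt$mu[, , , 2]^2 + gt$mu[, , , 3]^2)
  expect_lt(max(abs(mu_norm[idx] - 1)), 1e-9)
})

test_that("zero slopes and zero residual give parcel-constant fields", {
  dom <- solved_slab()
  eff <- effect_spec(subfield_names(), "f_ec", intercept = 0.3) |>
    dplyr::bind_rows(effect_spec(subfield_names(), "f_soma", intercept = 0.4),
                     effect_spec(subfield_names(), "r_s", intercept = 6),
                     effect_spec(subfield_names(), "kappa", intercept = 1),
                     effect_spec(subfield_names(), "d_in", intercept = 1.7),
                     effect_spec(subfield_names(), "d_ec", intercept = 1))
  prow <- generate_cohort(cohort_spec(n_participants = 1, seed = 1))[1, ]
  gt <- assign_ground_truth(dom, prow, eff, seed = 1)
  idx <- which(gt$mask)
  for (p in c("f_ec", "f_soma", "r_s")) {
    vals <- tapply(gt[[p]][idx], dom$subfield[idx], function(x) diff(range(x)))
    expect_equal(max(vals), 0, info = p)
  }
})

test_that("injected age slope produces the expected mean difference", {
  # slope +0.005/yr over an 11-year span => 0.055 difference
  dom <- solved_slab()
  eff <- default_effect_spec(residual_sd_scale = 0)
  eff$slope_age[eff$parameter == "f_soma"] <- 0.005
  eff$slope_age_sex[eff$parameter == "f_soma"] <- 0
  young <- tibble::tibble(participant = "a", age = 8, sex = factor("F"),
                          hemisphere = factor("L"))
  old <- dplyr::mutate(young, age = 19)
  g_young <- assign_ground_truth(dom, young, eff, seed = 1)
  g_old <- assign_ground_truth(dom, old, eff, seed = 1)
  idx <- which(dom$mask)
  expect_equal(mean(g_old$fsoma[idx]) - mean(g_young$fsoma[idx]), 0.005 * 11,
               tolerance = 1e-12)
})

test_that("fitted per-parcel age slope matches the injected slope", {
  # OLS oracle on the generated parcel-mean table, residual SD = 0
  dom <- solved_slab()
  eff <- default_effect_spec(residual_sd_scale = 0)
  cohort <- generate_cohort(cohort_spec(n_participants = 12, seed = 2))
  cohort <- cohort[cohort$hemisphere == "L", ]
  tabs <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    gt <- assign_ground_truth(dom, cohort[i, ], eff, seed = 100 + i)
    ground_truth_parcel_means(gt, dom, parameters = "fextracellular")
  })
  for (p in subfield_names()) {
    d <- dplyr::filter(tabs, parcel == p)
    cf <- coef(lm(value ~ age * sex, data = d))
    # fextracellular = f_ec: age slope -0.008 for the reference sex (F) and
    # the injected +0.0025 age-by-sex interaction for males
    expect_lt(abs(cf[["age"]] - (-0.008)), 1e-10)
    expect_lt(abs(cf[["age:sexM"]] - 0.0025), 1e-10)
  }
})

test_that("values are clipped to bounds and the clipping is logged", {
  dom <- solved_slab()
  eff <- default_effect_spec(residual_sd_scale = 0)
  eff$intercept[eff$parameter == "f_ec"] <- 0.99
  eff$slope_age[eff$parameter == "f_ec"] <- 0.05  # pushes above 1 at age 19
  prow <- tibble::tibble(participant = "a", age = 19, sex = factor("M"),
                         hemisphere = factor("L"))
  gt <- assign_ground_truth(dom, prow, eff, seed = 1)
  expect_gt(gt$n_clipped, 0)
  expect_true(all(gt$f_ec[which(gt$mask)] <= 1))
})

test_that("incomplete effect specs are rejected", {
  dom <- solved_slab()
  eff <- default_effect_spec()[-1, ]  # drop one (parcel, parameter) row
  prow <- generate_cohort(cohort_spec(n_participants = 1, seed = 1))[1, ]
  expect_error(assign_ground_truth(dom, prow, eff), "cover")
})
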