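make_cohort1 <- function(n = 30, seed = 1) {
  ch <- generate_cohort(cohort_spec(n_participants = n, seed = seed))
  ch[ch$hemisphere == "L", ]
}

test_that("t-maps are invariant to affine rescaling of the DV", {
  ch <- make_cohort1(30, 2)
  set.seed(2)
  M <- matrix(rnorm(30 * 40), 30, 40) + outer(ch$age, rep(0.05, 40))
  t1 <- vertex_glm_tmap(M, ch)
  t2 <- vertex_glm_tmap(3.2 * M - 7, ch)
  expect_equal(t1$stats$t, t2$stats$t, tolerance = 1e-9)
})

test_that("an exact-fit DV is flagged and masked", {
  ch <- make_cohort1(20, 3)
  M <- matrix(rep(ch$age, 5), ncol = 5)  # DV == age at every vertex
  tm <- vertex_glm_tmap(M, ch)
  expect_true(all(tm$exact_fit))
  expect_true(all(!tm$valid))
  expect_error(vertex_glm_tmap(M[1:3, ], ch[1:3, ]), "participants")
})

test_that("null t-values follow the design's Student-t distribution", {
  ch <- make_cohort1(88, 4)
  set.seed(4)
  M <- matrix(rnorm(88 * 500), 88, 500)
  tm <- vertex_glm_tmap(M, ch)
  df <- unique(tm$stats$df)
  expect_equal(df, 84L)  # n - 4 coefficients
  ks <- suppressWarnings(stats::ks.test(tm$stats$t, "pt", df = df))
  expect_gt(ks$p.value, 0.01)
})

test_that("injected vertex slopes give the right t sign at 95% of vertices", {
  ch <- make_cohort1(88, 5)
  set.seed(5)
  slope <- 0.01
  M <- outer(ch$age - 13.5, rep(slope, 300)) +
    matrix(rnorm(88 * 300, sd = slope * 5), 88, 300)
  tm <- vertex_glm_tmap(M, ch)
  expect_gte(mean(tm$stats$t > 0), 0.95)
})

test_that("vertices with missing data drop to complete-case fits", {
  ch <- make_cohort1(30, 6)
  set.seed(6)
  M <- matrix(rnorm(30 * 10), 30, 10)
  M[1:4, 3] <- NA
  tm <- vertex_glm_tmap(M, ch)
  expect_equal(tm$stats$n[3], 26L)
  expect_equal(tm$stats$df[3], 22L)
  expect_true(tm$valid[3])
})

test_that("gradient correlation anchors hold", {
  grid <- tidyr::expand_grid(ap = seq(0, 1, length.out = 21),
                             pd = seq(0, 1, length.out = 10))
  pg <- tibble::tibble(vertex = seq_len(nrow(grid)), AP = grid$ap,
                       PD = grid$pd)
  gc1 <- gradient_correlation(pg$AP, pg)
  expect_equal(gc1$r_ap, 1)
  expect_equal(gc1$mean_abs_t, mean(pg$AP))
  expect_error(gradient_correlation(rep(2, nrow(pg)), pg), "constant")
  # PD ramp plus small noise correlates more with PD in every seed
  wins <- 0
  for (s in 1:50) {
    set.seed(s)
    tmap <- pg$PD + rnorm(nrow(pg), sd = 0.1)
    g <- gradient_correlation(tmap, pg)
    wins <- wins + (g$r_pd > g$r_ap)
  }
  expect_equal(wins, 50)
  # sign-flip invariance through the absolute value
  g1 <- gradient_correlation(pg$PD - 0.5, pg)
  g2 <- gradient_correlation(0.5 - pg$PD, pg)
  expect_equal(g1$r_pd, g2$r_pd)
})

test_that("spin test is deterministic and detects self-correlation", {
  srf <- list(n_ap = 40, n_pd = 20)
  refs <- synthetic_reference_maps(srf, names = "a", smoothness = 4,
                                   seed = 3)
  m <- refs$a
  s1 <- spin_test(m, m, srf, n_perm = 500, seed = 9)
  s2 <- spin_test(m, m, srf, n_perm = 500, seed = 9)
  expect_identical(s1$p, s2$p)
  expect_equal(s1$r, 1)
  expect_lt(s1$p, 0.01)
  expect_length(attr(s1, "null"), 500)
  expect_error(spin_test(m[-1], m, srf, 500), "grid")
  expect_error(spin_test(m, m, srf, n_perm = 50), "100 permutations")
})

test_that("spin-test p-values are valid under an exchangeable null", {
  srf <- list(n_ap = 24, n_pd = 12)
  set.seed(11)
  n_rep <- 200
  ps <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(24 * 12)
    b <- rnorm(24 * 12)
    ps[i] <- spin_test(a, b, srf, n_perm = 199, seed = i)$p
  }
  hits <- sum(ps < 0.05)
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("reference battery reports attenuation-consistent correlations", {
  srf <- list(n_ap = 40, n_pd = 20)
  base <- synthetic_reference_maps(srf, names = "x", smoothness = 4,
                                   seed = 21)$x
  # reference = z(map) + noise at known mixing; expected R = 1/sqrt(1+s2)
  s <- 0.8
  rs <- vapply(1:200, function(i) {
    set.seed(i)
    ref <- base + rnorm(length(base), sd = s)
    cor(base, ref)
  }, 0)
  expect_lt(abs(mean(rs) - 1 / sqrt(1 + s^2)), 0.05)
  # battery output shape and FDR property
  refs <- synthetic_reference_maps(srf, names = c("r1", "r2"), seed = 22)
  bat <- reference_map_battery(list(m1 = base, m2 = -base), refs, srf,
                               n_perm = 199, seed = 5)
  expect_equal(nrow(bat), 4L)
  expect_true(all(bat$p_adj >= bat$p))
  self <- reference_map_battery(list(m = base), list(ref = base), srf,
                                n_perm = 199, seed = 5)
  expect_equal(self$r, 1)
  expect_lt(self$p, 0.02)
})

test_that("synthetic reference maps are smooth, standardised and seeded", {
  srf <- list(n_ap = 40, n_pd = 20)
  a <- synthetic_reference_maps(srf, seed = 7)
  b <- synthetic_reference_maps(srf, seed = 7)
  expect_identical(a, b)
  expect_length(a, 7)
  for (m in a) {
    expect_equal(mean(m), 0, tolerance = 1e-12)
    expect_equal(sd(m), 1, tolerance = 1e-12)
  }
  # smoothness: neighbouring vertices correlate strongly
  M <- matrix(a$qr1, 20, 40)
  expect_gt(cor(as.vector(M[-1, ]), as.vector(M[-20, ])), 0.8)
})
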