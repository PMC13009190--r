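test_that("tensor signal honours the b-matrix closed forms", {
  sch <- small_scheme()
  D <- diag(c(3, 3, 3))
  b0 <- which(sch$b == 0)[1]
  expect_equal(dti_signal(D, sch, b0, S0 = 5), 5)        # B = 0
  b1 <- which(abs(sch$b - 1.2) < 1e-9)[1]
  expect_equal(dti_signal(D, sch, b1), exp(-1.2 * 3))    # isotropic
  # stick tensor, gradient perpendicular to the principal axis
  stick <- diag(c(0, 0, 1.7))
  perp <- acquisition_scheme(c(0, 1), c(1, 1),
                             directions = matrix(c(0, 0, 1, 1, 0, 0), 2, 3,
                                                 byrow = TRUE))
  expect_equal(dti_signal(stick, perp, 2), 1)
})

test_that("tensor metrics match the eigenvalue formulas", {
  expect_equal(tensor_metrics(diag(c(0.7, 0.7, 0.7)))$fa, 0)
  expect_equal(tensor_metrics(diag(c(0.7, 0.7, 0.7)))$md, 0.7)
  expect_equal(tensor_metrics(diag(c(1, 0, 0)))$fa, 1)
  expect_equal(tensor_metrics(matrix(0, 3, 3))$fa, 0)
  # independent evaluation of the normalised eigenvalue-variance formula
  l <- c(1.7, 0.2, 0.2)
  md <- mean(l)
  fa_direct <- sqrt(3 * sum((l - md)^2) / (2 * sum(l^2)))
  tm <- tensor_metrics(diag(l))
  expect_equal(tm$md, 0.7)
  expect_equal(tm$fa, fa_direct, tolerance = 1e-12)
  expect_equal(abs(tm$e1), c(1, 0, 0))
})

test_that("orientation dispersion index follows the arctangent convention", {
  expect_equal(watson_odi(Inf), 0)
  expect_equal(watson_odi(1), 0.5)
  expect_equal(watson_odi(0), 1)
  expect_error(watson_odi(-1), "non-negative")
  k <- c(0.1, 1, 5, 50)
  expect_true(all(diff(watson_odi(k)) < 0))         # monotone decreasing
  expect_equal(odi_to_kappa(watson_odi(2.3)), 2.3)  # inverse
})

test_that("NODDI closed-form anchors hold", {
  sch <- small_scheme()
  b1 <- which(abs(sch$b - 1.2) < 1e-9)[1]
  # pure CSF
  expect_equal(noddi_signal(1, 0.5, 1, c(0, 0, 1), sch, b1), exp(-1.2 * 3))
  # coherent stick, orthogonal gradient
  perp <- acquisition_scheme(c(0, 1), c(1, 1),
                             directions = matrix(c(0, 0, 1, 1, 0, 0), 2, 3,
                                                 byrow = TRUE))
  expect_equal(noddi_signal(0, 1, Inf, c(0, 0, 1), perp, 2), 1)
})

test_that("uniform dispersion equals the analytic powder-averaged stick", {
  # Monte-Carlo spherical quadrature oracle, 1e6 samples
  set.seed(11)
  n <- matrix(rnorm(3e6), 1e6, 3)
  n <- n / sqrt(rowSums(n^2))
  g <- c(0.3, -0.5, sqrt(1 - 0.09 - 0.25))
  bd <- 6 * 1.7
  mc <- mean(exp(-bd * (n %*% g)^2))
  analytic <- stick_powder(bd)
  expect_equal(analytic, sqrt(pi / (4 * bd)) * pracma::erf(sqrt(bd)))
  expect_equal(watson_stick(sum(g * c(0, 0, 1)), bd, 0), analytic,
               tolerance = 1e-8)
  expect_equal(mc, analytic, tolerance = 2e-3)
})

test_that("coherent-limit NODDI equals the stick tensor signal", {
  sch <- small_scheme()
  mu <- c(1, 2, 2) / 3
  noddi <- noddi_signal(0, 1, Inf, mu, sch)
  stick_tensor <- 1.7 * (mu %o% mu)
  dti <- dti_signal(stick_tensor, sch)
  expect_lt(max(abs(noddi - dti)), 1e-6)
})

test_that("SANDI powder signal anchors hold", {
  expect_equal(sandi_powder_signal(0.4, 0.35, 7, 1.7, 1.0, b = 0), 1)
  expect_equal(sandi_powder_signal(1, 0.35, 7, 1.7, 2.0, b = 1), exp(-2))
  # stick term cross-checked against Gauss-Legendre sphere quadrature
  gl <- pracma::gaussLegendre(200, -1, 1)
  for (bd in c(6 * 1.7, 2.4 * 1)) {
    quad <- sum(gl$w * exp(-bd * gl$x^2)) / 2
    expect_equal(stick_powder(bd), quad, tolerance = 1e-10)
  }
})

test_that("GPD sphere signal limits and monotonicity hold", {
  expect_equal(sphere_signal_gpd(1e-4, 3, b = 6), 1, tolerance = 1e-6)
  expect_equal(sphere_signal_gpd(8, 3, b = 0), 1)
  r <- seq(1, 12, by = 0.5)
  s <- sphere_signal_gpd(r, 3, b = 3)
  expect_true(all(diff(s) <= 1e-12))   # non-increasing in radius
  expect_true(all(s > 0 & s <= 1))
  expect_error(sphere_signal_gpd(-1, 3, b = 1), "positive")
  expect_warning(sphere_signal_gpd(12, 3, b = 6, n_terms = 5), "truncation")
})

test_that("mixed signals are convex combinations within (0, 1]", {
  sch <- small_scheme()
  set.seed(2)
  for (i in 1:20) {
    s <- noddi_signal(runif(1), runif(1), runif(1, 0, 10),
                      rnorm(3), sch)
    expect_true(all(s > 0 & s <= 1 + 1e-12))
    sp <- sandi_powder_signal(runif(1), runif(1), runif(1, 1, 12),
                              runif(1, 0.1, 3), runif(1, 0.1, 3),
                              b = sch$bvalues)
    expect_true(all(sp > 0 & sp <= 1 + 1e-12))
  }
})

test_that("signal-fraction identities hold exactly", {
  f_ec <- c(0.2, 0.5); f_in <- c(0.3, 0.9)
  d <- sandi_derived_fractions(f_ec, f_in)
  expect_equal(d$fneurite, (1 - f_ec) * f_in)
  expect_equal(d$fsoma, (1 - f_ec) * (1 - f_in))
  expect_equal(d$fneurite + d$fsoma + d$fextracellular, c(1, 1))
})

test_that("powder-average of the oriented model matches the closed form", {
  # direction average of a dispersed stick over a dense scheme equals the
  # powder stick irrespective of kappa when kappa = 0; for finite kappa use
  # spherical quadrature of the oriented signal as the oracle
  gl <- pracma::gaussLegendre(64, -1, 1)
  kappa <- 2; bd <- 4
  # azimuthal symmetry about mu: average over gradient polar angle only
  vals <- sapply(gl$x, function(ct) watson_stick(ct, bd, kappa))
  quad_avg <- sum(gl$w * vals) / 2
  expect_equal(quad_avg, stick_powder(bd), tolerance = 1e-4)
})
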