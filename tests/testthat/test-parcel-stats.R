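# small synthetic metric table builder
make_table <- function(n = 20, seed = 1, slope = 0, hemi_effect = 0) {
  withr::with_seed(seed, {
    cohort <- generate_cohort(cohort_spec(n_participants = n, seed = seed))
    purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      r <- cohort[i, ]
      he <- if (r$hemisphere == "R") hemi_effect else 0
      tibble::tibble(participant = r$participant, age = r$age, sex = r$sex,
                     hemisphere = r$hemisphere,
                     parcel = factor(subfield_names(),
                                     levels = subfield_names()),
                     metric = "m",
                     value = 0.3 + slope * (r$age - 13.5) +
                       he * (r$age - 13.5) + rnorm(5, sd = 0.02))
    })
  })
}

test_that("hemisphere averaging arithmetic is exact", {
  tab <- make_table(6, seed = 2)
  # identical L/R values stay unchanged
  sym <- tab |> dplyr::group_by(participant, parcel) |>
    dplyr::mutate(value = value[1]) |> dplyr::ungroup()
  avg <- hemisphere_average(sym)
  expect_equal(sort(avg$value),
               sort(sym$value[sym$hemisphere == "L"]))
  # L = 0, R = 1 -> 0.5
  lr <- sym
  lr$value <- ifelse(lr$hemisphere == "L", 0, 1)
  expect_true(all(hemisphere_average(lr)$value == 0.5))
})

test_that("significant hemisphere interaction blocks averaging", {
  tab <- make_table(6, seed = 3)
  fake <- tibble::tibble(metric = "m", p_adj = 0.001)
  expect_message(out <- hemisphere_average(tab, fake), "separate")
  expect_setequal(as.character(unique(out$hemisphere)), c("L", "R"))
  forced <- hemisphere_average(tab, fake, force = TRUE)
  expect_equal(as.character(unique(forced$hemisphere)), "both")
})

test_that("participants missing a hemisphere are excluded with a message", {
  tab <- make_table(4, seed = 4)
  tab <- tab[!(tab$participant == tab$participant[1] &
                 tab$hemisphere == "R"), ]
  expect_message(out <- hemisphere_average(tab), "missing hemisphere")
  expect_equal(length(unique(out$participant)), 3L)
})

test_that("exactly linear data give R = 1 and the ladder works", {
  tab <- tibble::tibble(participant = sprintf("s%02d", 1:10),
                        age = seq(8, 19, length.out = 10),
                        sex = factor("F"), hemisphere = factor("both"),
                        parcel = "CA1", metric = "m",
                        value = 2 + 0.1 * seq(8, 19, length.out = 10))
  res <- age_correlation(tab, "CA1", "m")
  expect_equal(res$r, 1)
  expect_equal(res$asterisk, "***")
  expect_error(age_correlation(dplyr::mutate(tab, value = 1), "CA1", "m"),
               "zero variance")
  expect_error(age_correlation(tab[1:2, ], "CA1", "m"), "3 participants")
})

test_that("permuted values give nominal type-I at the 0.01 minimum alpha", {
  # permutation type-I oracle: value independent of age, n = 88
  set.seed(10)
  n_rep <- 400
  hits <- 0
  ages <- generate_cohort(cohort_spec(88, seed = 1))
  ages <- ages$age[ages$hemisphere == "L"]
  for (i in seq_len(n_rep)) {
    v <- rnorm(88)
    p <- cor.test(ages, v)$p.value
    hits <- hits + (p < 0.01)
  }
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.01)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("injected slopes yield the right correlation sign", {
  set.seed(12)
  wins <- 0
  for (i in 1:100) {
    ages <- runif(88, 8, 19)
    v <- 0.3 + 0.008 * (ages - 13.5) + rnorm(88, sd = 0.02)
    wins <- wins + (cor(ages, v) > 0)
  }
  expect_gte(wins, 99)
})

test_that("nested F matches hand-computed SSE arithmetic to 1e-10", {
  # 8-row worked example, two groups x numeric covariate
  d <- tibble::tibble(
    value = c(1.0, 2.1, 2.9, 4.2, 2.0, 4.1, 6.2, 8.1),
    age = c(1, 2, 3, 4, 1, 2, 3, 4),
    sex = factor(rep(c("F", "M"), each = 4)))
  ft <- nested_f_test(d, c("age", "sex", "age:sex"), c("age", "sex"))
  # hand arithmetic: residual sums of squares from explicit projections
  X_full <- model.matrix(~ age + sex + age:sex, d)
  X_red <- model.matrix(~ age + sex, d)
  sse <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% d$value)
    sum((d$value - X %*% beta)^2)
  }
  sse_f <- sse(X_full); sse_r <- sse(X_red)
  F_hand <- ((sse_r - sse_f) / 1) / (sse_f / 4)
  expect_equal(ft$F, F_hand, tolerance = 1e-10)
  expect_equal(ft$df1, 1L)
  expect_equal(ft$df2, 4L)
  expect_equal(ft$p, pf(F_hand, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("degenerate nested models are handled explicitly", {
  d <- tibble::tibble(value = c(2, 4, 9, 11), age = c(1, 2, 3, 4),
                      sex = factor(c("F", "F", "M", "M")))
  expect_warning(ft <- nested_f_test(d, c("age", "sex"), "age"),
                 "infinite")
  expect_equal(ft$F, Inf)
  expect_error(nested_f_test(d, c("age"), c("age")), "identical degrees")
  expect_error(nested_f_test(d, c("age"), c("sex")), "subset")
})

test_that("study-shaped design reproduces the F(1,424)/F(4,424) dfs", {
  tab <- make_table(88, seed = 5)
  avg <- hemisphere_average(tab)
  fs <- interaction_f_tests(avg, "age:sex")
  expect_equal(fs$df1, 1L)
  expect_equal(fs$df2, 424L)
  fp <- interaction_f_tests(avg, "age:parcel")
  expect_equal(fp$df1, 4L)
  expect_equal(fp$df2, 424L)
})

test_that("BH adjustment matches the hand-applied step-up", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.99)
  # step-up by hand: p_(i) * m / i, cumulative minimum from the largest
  m <- 6
  hand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(fdr_bh(p), pmin(hand, 1))
  expect_equal(fdr_bh(0.03), 0.03)           # single test: adjusted = raw
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))  # all equal stay equal
  pr <- runif(20)
  expect_true(all(fdr_bh(pr) >= pr))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("parcel statistics are invariant to row order", {
  tab <- make_table(20, seed = 6, slope = 0.005)
  avg <- hemisphere_average(tab)
  shuffled <- avg[sample(nrow(avg)), ]
  a <- age_correlation_all(avg) |> dplyr::arrange(parcel)
  b <- age_correlation_all(shuffled) |> dplyr::arrange(parcel)
  expect_equal(a, b)
  fa <- interaction_f_tests(avg, "age:sex")
  fb <- interaction_f_tests(shuffled, "age:sex")
  expect_equal(fa$F, fb$F)
})

test_that("the Bonferroni per-test alpha for 5 subfields is 0.01", {
  expect_equal(bonferroni_alpha(5, 0.05), 0.01)
})
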