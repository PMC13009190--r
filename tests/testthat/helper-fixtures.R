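# Shared fixtures, built once per test file and memoised.

# reduced-direction 6-shell scheme: same shells as the default protocol,
# fewer directions per shell (keeps nonlinear fits fast in unit tests)
small_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- acquisition_scheme(c(0, 0.5, 1.2, 2.4, 4, 6),
                                   c(6L, 12L, 12L, 16L, 16L, 16L))
    cache
  }
})

# rectangular slab with all Laplace fields solved
solved_slab <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- solve_laplace_all(
        generate_domain(c(20, 14, 10), curvature = 0, thickness = 5, seed = 1))
    cache
  }
})

# curved domain with all Laplace fields solved
solved_curved <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- solve_laplace_all(
        generate_domain(c(24, 16, 12), curvature = 0.5, thickness = 5,
                        seed = 3))
    cache
  }
})

# one-participant ground truth on the slab, no residuals
slab_ground_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prow <- generate_cohort(cohort_spec(n_participants = 1, seed = 5))[1, ]
      cache <<- assign_ground_truth(solved_slab(), prow,
                                    default_effect_spec(residual_sd_scale = 0),
                                    seed = 5)
    }
    cache
  }
})

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
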