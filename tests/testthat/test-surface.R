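test_that("slab midthickness is the exact mid-plane", {
  dom <- solved_slab()
  srf <- build_midthickness_surface(dom, n_ap = 21, n_pd = 12)
  v <- srf$vertices
  expect_true(all(v$valid))
  mid <- unique(round(v$z, 6))
  expect_length(mid, 1)
  # psi_IO interpolates to 0.5 at every vertex
  pio <- hippdiff:::trilinear(dom$psi$IO,
                              as.matrix(v[, c("x", "y", "z")]) - 0.5)
  expect_lt(max(abs(pio - 0.5)), 1e-3)
})

test_that("the default unfolded grid has 7260 vertices fully labelled", {
  dom <- solved_slab()
  srf <- build_midthickness_surface(dom)
  expect_equal(nrow(srf$vertices), 7260L)
  expect_equal(srf$n_ap * srf$n_pd, 7260L)
  expect_false(anyNA(srf$vertices$subfield))
  expect_false(anyNA(srf$vertices$longaxis))
  expect_setequal(levels(srf$vertices$subfield), subfield_names())
  expect_setequal(levels(srf$vertices$longaxis), longaxis_names())
  # exactly one subfield and one long-axis label per vertex (factor columns)
  expect_equal(length(srf$vertices$subfield), 7260L)
})

test_that("surface sampling uses the enclosing voxel", {
  dom <- solved_slab()
  srf <- build_midthickness_surface(dom, n_ap = 21, n_pd = 12)
  # constant volume
  vol <- array(3.5, dom$grid_shape); vol[!dom$mask] <- NA
  expect_true(all(sample_to_surface(vol, srf) == 3.5, na.rm = TRUE))
  # checkerboard: value equals parity of floor-divided coordinates
  d <- dom$grid_shape
  idx <- arrayInd(seq_len(prod(d)), d)
  chk <- array((idx[, 1] + idx[, 2] + idx[, 3]) %% 2, d)
  got <- sample_to_surface(chk, srf)
  vx <- floor(as.matrix(srf$vertices[, c("x", "y", "z")]) / srf$voxel_size)
  manual <- chk[vx + 1L]
  expect_equal(got, manual)
})

test_that("slab thickness and gyrification match the analytic values", {
  dom <- solved_slab()
  srf <- build_midthickness_surface(dom, n_ap = 21, n_pd = 12)
  mac <- macrostructure(dom, srf)
  # slab of 5 voxel layers at 1 mm -> thickness 5 mm (one-step tolerance)
  expect_lt(max(abs(mac$vertex$thickness - 5), na.rm = TRUE), 0.3)
  # undistorted mapping -> gyrification 1
  expect_lt(max(abs(mac$vertex$gyrification - 1), na.rm = TRUE), 0.02)
  # log option
  mac_log <- macrostructure(dom, srf, log_gyrification = TRUE)
  expect_lt(max(abs(mac_log$vertex$gyrification), na.rm = TRUE), 0.03)
})

test_that("subfield volumes sum exactly to the GM volume", {
  for (dom in list(solved_slab(), solved_curved())) {
    srf <- build_midthickness_surface(dom, n_ap = 21, n_pd = 12)
    mac <- macrostructure(dom, srf)
    expect_equal(sum(mac$volume$volume_mm3),
                 sum(dom$mask) * dom$voxel_size^3)
  }
})

test_that("positional gradients are the unfolded coordinates", {
  dom <- solved_slab()
  srf <- build_midthickness_surface(dom, n_ap = 21, n_pd = 12)
  pg <- positional_gradients(srf)
  expect_equal(range(pg$AP), c(0, 1))
  expect_equal(range(pg$PD), c(0, 1))
  expect_equal(cor(pg$AP, pg$AP), 1)
  expect_equal(cor(pg$AP, pg$PD), 0)  # orthogonal grid coordinates
})

test_that("curved-domain vertices still sit on the midthickness level", {
  dom <- solved_curved()
  srf <- build_midthickness_surface(dom, n_ap = 21, n_pd = 12)
  v <- srf$vertices[srf$vertices$valid, ]
  pio <- hippdiff:::trilinear(dom$psi$IO,
                              as.matrix(v[, c("x", "y", "z")]) - 0.5)
  expect_lt(max(abs(pio - 0.5)), 5e-3)
  expect_gt(mean(srf$vertices$valid), 0.98)
})

test_that("surface TSV round trip preserves vertices", {
  dom <- solved_slab()
  srf <- build_midthickness_surface(dom, n_ap = 11, n_pd = 8)
  path <- file.path(withr::local_tempdir(), "surf.tsv")
  write_surface_tsv(srf, path, maps = list(depth = srf$vertices$z))
  back <- read_table_tsv(path)
  expect_equal(nrow(back), nrow(srf$vertices))
  expect_equal(back$x, srf$vertices$x, tolerance = 1e-9)
  expect_equal(back$depth, srf$vertices$z, tolerance = 1e-9)
})
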