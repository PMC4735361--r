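test_that("region ordering is a deterministic lobe-blocked permutation", {
  f <- ico6()
  rg <- region_geometry(f$mesh, f$atlas)
  ord <- order_regions(f$atlas, rg)
  expect_setequal(ord, included_regions(f$atlas))
  expect_identical(ord, order_regions(f$atlas, rg))
  # lobes appear as contiguous blocks
  lob <- f$atlas$lobes[match(ord, f$atlas$region_ids)]
  expect_equal(length(rle(as.character(lob))$values), 3)
})

test_that("collinear equally spaced centroids chain left to right", {
  # 4 strip regions on a long thin sheet: one lobe, collinear centroids
  sh <- make_sheet(41, 3, 8, 0.4)
  at <- make_strip_atlas(sh, 4)
  rg <- region_geometry(sh, at)
  ord <- order_regions(at, rg)
  # a greedy nearest-centroid chain on a line walks from its start to one
  # end, then sweeps the other side: at most one direction change
  xs <- rg$centroid[match(ord, rg$region_ids), 1]
  sgn <- sign(diff(xs))
  expect_lte(sum(diff(sgn) != 0), 1)
  expect_true(all(sgn != 0))
})

test_that("asymmetry matrix is the exact skew part", {
  T_min <- matrix(c(0, 5, 7, 0), 2, byrow = TRUE)
  A <- asymmetry_matrix(T_min)
  expect_equal(A, matrix(c(0, -2, 2, 0), 2, byrow = TRUE))
  expect_equal(A + t(A), matrix(0, 2, 2))
  # symmetric input -> zero
  Tsym <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(asymmetry_matrix(Tsym), matrix(0, 2, 2))
  expect_error(asymmetry_matrix(matrix(1:6, 2)), "square")
  expect_error(asymmetry_matrix(matrix(c(1, 2, 2, 1), 2)), "diagonal")
})

test_that("normalised asymmetry divides off-diagonals and rejects zero times", {
  T_min <- matrix(c(0, 5, 7, 0), 2, byrow = TRUE)
  N <- normalized_asymmetry(asymmetry_matrix(T_min), T_min)
  expect_equal(N, matrix(c(0, -2 / 5, 2 / 7, 0), 2, byrow = TRUE))
  expect_error(normalized_asymmetry(asymmetry_matrix(T_min),
                                    matrix(c(0, 0, 7, 0), 2, byrow = TRUE)),
               "not positive")
})

test_that("global asymmetry index: means over off-diagonals, odd in its input", {
  T_min <- matrix(c(0, 5, 7, 0), 2, byrow = TRUE)
  N <- normalized_asymmetry(asymmetry_matrix(T_min), T_min)
  g <- global_asymmetry_index(N)
  expect_equal(g$col_means, c(2 / 7, -2 / 5))
  expect_equal(g$signs, c(1, -1))
  gn <- global_asymmetry_index(-N)
  expect_equal(gn$col_means, -g$col_means)
  expect_equal(gn$signs, -g$signs)
  z <- global_asymmetry_index(matrix(0, 3, 3))
  expect_equal(z$col_means, rep(0, 3))
  expect_equal(z$signs, rep(0, 3))
})

test_that("combined display matrix stacks |left| below and |right| above", {
  L <- matrix(c(0, -2, 2, 0), 2, byrow = TRUE)
  R <- matrix(c(0, -3, 3, 0), 2, byrow = TRUE)
  G <- combine_hemispheres(L, R)
  expect_equal(G, matrix(c(0, 3, 2, 0), 2, byrow = TRUE))
  expect_true(all(G >= 0))
  expect_equal(combine_hemispheres(matrix(0, 3, 3), matrix(0, 3, 3)),
               matrix(0, 3, 3))
  expect_error(combine_hemispheres(L, matrix(1, 2, 2)), "skew")
})

test_that("residence and retention follow the column-sum definition", {
  T_min <- matrix(c(0, 10, 20, 0), 2, byrow = TRUE)
  T_max <- matrix(c(0, 13, 26, 0), 2, byrow = TRUE)
  rr <- residence_and_retention(T_min, T_max)
  expect_equal(rr$D, matrix(c(0, 3, 6, 0), 2, byrow = TRUE))
  expect_equal(unname(rr$retention), c(6, 3))
  expect_equal(residence_and_retention(T_min, T_min)$retention, c(0, 0),
               ignore_attr = TRUE)
  # constant column d over k regions gives (k-1) d
  k <- 5; d <- 2.5
  D1 <- matrix(d, k, k); diag(D1) <- 0
  rr2 <- residence_and_retention(matrix(0, k, k), D1)
  expect_equal(unname(rr2$retention), rep((k - 1) * d, k))
  expect_error(residence_and_retention(T_max, T_min), "T_max < T_min")
})

test_that("pearson implements the printed formula and matches stats::cor", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(pearson(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x), -1, tolerance = 1e-12)
  y <- c(2.2, 1.9, 3.8, 4.1, 9.0, 11.5)
  expect_equal(pearson(x, y), stats::cor(x, y), tolerance = 1e-12)
  expect_error(pearson(x, rep(1, 6)), "constant")
  expect_error(pearson(1:2, 1:2), "3 observations")
})

test_that("pair datasets enumerate all ordered off-diagonal pairs", {
  mats <- ico6_protocol()
  rg <- region_geometry(ico6()$mesh, ico6()$atlas)
  pd <- pair_dataset(mats$T_min, rg, mats$region_order)
  expect_equal(nrow(pd), 6 * 5)
  expect_true(all(pd$distance_mm > 0))
  expect_true(all(pd$start != pd$arrival))
})

test_that("QoI operators are scale-equivariant in time", {
  mats <- ico6_protocol()
  rg <- region_geometry(ico6()$mesh, ico6()$atlas)
  b1 <- qoi_bundle(mats, rg)
  mats2 <- mats
  cc <- 3.7
  mats2$T_min <- cc * mats$T_min; mats2$T_max <- cc * mats$T_max
  b2 <- qoi_bundle(mats2, rg)
  expect_equal(b2$Asym, cc * b1$Asym, tolerance = 1e-12)
  expect_equal(b2$D, cc * b1$D, tolerance = 1e-12)
  expect_equal(b2$retention, cc * b1$retention, tolerance = 1e-12)
  expect_equal(b2$AsymNorm, b1$AsymNorm, tolerance = 1e-12)
  expect_equal(b2$asym_index, b1$asym_index)
  expect_equal(b2$pearson_min, b1$pearson_min, tolerance = 1e-12)
})

test_that("sphere protocol is nearly symmetric in the normalised index", {
  b <- qoi_bundle(ico6_protocol(), region_geometry(ico6()$mesh, ico6()$atlas))
  expect_lt(max(abs(b$col_means)), 0.02)
})

test_that("retention correlates with region area when one region is enlarged", {
  # merge two adjacent cube-face regions into one double-size region
  f <- ico6()
  lab <- f$atlas$labels
  lab[lab == 3L] <- 1L                        # +y absorbed into +x (adjacent)
  ids <- c(1, 2, 4, 5, 6)
  at <- region_atlas(lab,
                     region_names = stats::setNames(c("xy", "-x", "-y", "+z", "-z"), ids),
                     lobes = stats::setNames(rep(c("lx", "ly", "lz"), c(2, 1, 2)), ids))
  mats <- run_protocol(f$mesh, at, model_params())
  rg <- region_geometry(f$mesh, at)
  b <- qoi_bundle(mats, rg)
  expect_gt(b$pearson_area_retention, 0.5)
})
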