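test_that("sheet generator produces the expected grid, counts and areas", {
  cases <- list(list(2, 2, 1, 1, 4, 2, 1),
                list(3, 2, 2, 1, 6, 4, 2),
                list(11, 11, 10, 10, 121, 200, 100))
  for (cs in cases) {
    m <- make_sheet(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(n_vertices(m), cs[[5]])
    expect_equal(n_triangles(m), cs[[6]])
    expect_equal(mesh_area(m), cs[[7]], tolerance = 1e-12)
  }
  expect_error(make_sheet(1, 2, 1, 1), "nx")
  expect_error(make_sheet(3, 3, -1, 1), "positive")
})

test_that("icosphere counts follow subdivision and the area converges to 4 pi r^2", {
  m0 <- make_icosphere(0)
  expect_equal(n_vertices(m0), 12)
  expect_equal(n_triangles(m0), 20)
  m1 <- make_icosphere(1)
  expect_equal(n_vertices(m1), 42)      # V + E = 12 + 30
  expect_equal(n_triangles(m1), 80)     # 4 F
  m4 <- make_icosphere(4, 1)
  expect_lt(abs(mesh_area(m4) - 4 * pi) / (4 * pi), 0.005)
  m2 <- make_icosphere(2, 7)
  expect_equal(mesh_area(m2) / mesh_area(make_icosphere(2, 1)), 49, tolerance = 1e-9)
})

test_that("icospheres are closed consistently oriented manifolds at all levels", {
  for (s in 0:4) expect_true(is_closed_manifold(make_icosphere(s, 1)))
  # an open sheet is not closed
  expect_false(is_closed_manifold(make_sheet(3, 3, 1, 1)))
})

test_that("mesh validation names the offending triangle", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(surface_mesh(v, rbind(c(1, 2, 100))), "outside")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "repeated")
  # degenerate (collinear) triangle
  v2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(surface_mesh(v2, rbind(c(1, 2, 3))), "degenerate")
  # permissive load, then explicit validation
  m <- surface_mesh(v, rbind(c(1, 2, 99)), validate = FALSE)
  expect_error(validate_mesh(m), "99")
})

test_that("OFF and PLY round-trips are lossless", {
  m <- make_icosphere(1, 3.7)
  for (fmt in c("off", "ply")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, f, fmt)
    m2 <- read_mesh(f)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-12)
    expect_identical(m2$triangles, m$triangles)
    unlink(f)
  }
})

test_that("OFF reader reports malformed content", {
  f <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "0 1 0", "1 1 0", "3 0 1 99"), f)
  expect_error(read_mesh(f), "outside")
  writeLines(c("NOT_OFF", "1 1 1"), f)
  expect_error(read_mesh(f, format = "off"), "header")
  unlink(f)
  expect_error(read_mesh("no/such/file.off"), "not found")
})

test_that("the 2-triangle unit square written as OFF reads back correctly", {
  f <- tempfile(fileext = ".off")
  write_mesh(unit_square(), f)
  m <- read_mesh(f)
  expect_equal(n_vertices(m), 4)
  expect_equal(n_triangles(m), 2)
  expect_equal(mesh_area(m), 1, tolerance = 1e-12)
  unlink(f)
})

test_that("atlas CSV round-trip, vertex-count and lobe-table errors", {
  m <- unit_square()
  f <- tempfile(fileext = ".csv"); lt <- tempfile(fileext = ".csv")
  writeLines(c("vertex,region", "0,0", "1,0", "2,1", "3,1"), f)
  writeLines(c("region,name,lobe,source_excluded",
               "0,alpha,front,0", "1,beta,back,1"), lt)
  a <- read_atlas(f, m, lt)
  expect_equal(sort(unique(a$labels)), c(0L, 1L))
  expect_equal(as.integer(table(a$labels)), c(2L, 2L))
  expect_equal(a$source_excluded, 1L)
  expect_equal(included_regions(a), 0L)
  # row-count mismatch
  writeLines(c("vertex,region", "0,0", "1,0", "2,1"), f)
  expect_error(read_atlas(f, m, lt), "3 rows")
  # lobe table missing region 1
  writeLines(c("vertex,region", "0,0", "1,0", "2,1", "3,1"), f)
  writeLines(c("region,name,lobe,source_excluded", "0,alpha,front,0"), lt)
  expect_error(read_atlas(f, m, lt), "region 1")
  # write_atlas round-trip
  a2 <- region_atlas(c(1, 1, 2, 2), lobes = stats::setNames(c("L", "L"), 1:2),
                     source_excluded = 2L)
  write_atlas(a2, f, lt)
  a3 <- read_atlas(f, m, lt)
  expect_identical(a3$labels, a2$labels)
  expect_identical(a3$source_excluded, a2$source_excluded)
  unlink(c(f, lt))
})

test_that("cube-face atlas labels by dominant axis with near-equal areas", {
  m <- make_icosphere(4, 1)
  a <- make_face_atlas(m)
  expect_equal(length(a$region_ids), 6)
  # vertex closest to (0,0,1) is labelled +z
  iz <- which.max(m$vertices[, 3])
  expect_equal(a$region_names[[as.character(a$labels[iz])]], "+z")
  rg <- region_geometry(m, a)
  expect_lt((max(rg$area) - min(rg$area)) / mean(rg$area), 0.02)
  # all regions non-empty at subdivision 1 already
  expect_true(all(tabulate(make_face_atlas(make_icosphere(1))$labels, 6) > 0))
})

test_that("seed atlas partitions into k non-empty lobe-assigned regions", {
  m <- make_icosphere(3, 10)
  a <- make_seed_atlas(m, 34)
  expect_equal(length(a$region_ids), 34)
  expect_true(all(tabulate(a$labels, 34) > 0))
  expect_true(all(nzchar(a$lobes)))
  expect_identical(a$labels, make_seed_atlas(m, 34)$labels)  # deterministic
})

test_that("region geometry: centroids, areas and distances", {
  m <- make_icosphere(3, 1)
  one <- region_atlas(rep(1L, n_vertices(m)),
                      lobes = stats::setNames("all", 1))
  rg <- region_geometry(m, one)
  expect_lt(max(abs(rg$centroid)), 1e-6)            # symmetry
  expect_equal(sum(rg$area), mesh_area(m), tolerance = 1e-9)
  # flat unit square as one region
  sq <- unit_square()
  rg2 <- region_geometry(sq, region_atlas(rep(1L, 4), lobes = stats::setNames("all", 1)))
  expect_equal(as.numeric(rg2$centroid), c(0.5, 0.5, 0), tolerance = 1e-12)
  # two half-sheets: centroid distance 0.5
  sh <- make_sheet(5, 5, 1, 1)
  halves <- region_atlas(ifelse(sh$vertices[, 1] < 0.5, 1L, 2L),
                         lobes = stats::setNames(c("a", "a"), 1:2))
  rg3 <- region_geometry(sh, halves)
  # majority-rule triangle assignment shifts each centroid by O(h)
  expect_lt(abs(rg3$centroid_distance[1, 2] - 0.5), 0.03)
  expect_equal(rg3$centroid_distance[1, 1], 0)
  expect_equal(rg3$centroid_distance, t(rg3$centroid_distance))
})

test_that("region areas partition the mesh and distances are rigid-motion invariant", {
  f <- ico6()
  rg <- region_geometry(f$mesh, f$atlas)
  expect_equal(sum(rg$area), mesh_area(f$mesh), tolerance = 1e-9)
  # rigid motion: rotate + translate
  th <- 0.73
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- surface_mesh(sweep(f$mesh$vertices %*% t(R), 2, c(3, -7, 11), `+`),
                     f$mesh$triangles)
  rg2 <- region_geometry(m2, f$atlas)
  expect_lt(max(abs(rg2$centroid_distance - rg$centroid_distance)), 1e-9)
  expect_lt(max(abs(rg2$area - rg$area)), 1e-9 * mean(rg$area))
})

test_that("duct generator: degenerate straight case, positive areas, orientation", {
  d <- make_duct(3, 15, 180, h = 0.5)
  expect_equal(mesh_area(d), 3 * 30, tolerance = 1e-9)
  for (b in c(30, 90, 150)) {
    db <- make_duct(3, 15, b, h = 0.5)
    expect_true(all(triangle_areas(db) > 0))
    # consistent orientation: no duplicated directed edge
    de <- rbind(db$triangles[, 1:2], db$triangles[, 2:3], db$triangles[, c(3, 1)])
    expect_equal(anyDuplicated(paste(de[, 1], de[, 2])), 0L)
  }
  expect_error(make_duct(-1, 5, 90), "positive")
  expect_error(make_duct(1, 5, 200), "bend_angle")
})
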