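KAPPA <- 2.41798793102
P0 <- 2 * sqrt(2)

test_that("single-atom self-overlap matches the closed form and grid oracle", {
  sh <- build_shape(conformer(matrix(0, 1L, 3L)), radii = 1.7)
  alpha <- KAPPA / 1.7^2
  closed <- P0^2 * (pi / (2 * alpha))^1.5
  expect_equal(sh$vself, closed, tolerance = 1e-12)
  expect_equal(sh$vself, grid_overlap(sh, sh), tolerance = 0.01)
})

test_that("shapes are built from heavy atoms only and are translation invariant", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0))
  sh <- build_shape(conformer(coords), elements = c("C", "H", "O"))
  expect_equal(nrow(sh$centers), 2L)

  sh2 <- build_shape(conformer(coords + 5), elements = c("C", "H", "O"))
  expect_equal(sh$vself, sh2$vself, tolerance = 1e-12)

  expect_error(build_shape(conformer(matrix(0, 1L, 3L)), elements = "H"),
               "heavy")
})

test_that("overlap volume matches grid integration on multi-atom shapes", {
  set.seed(5)
  a <- build_shape(conformer(matrix(stats::rnorm(9), 3L, 3L)),
                   radii = c(1.7, 1.55, 1.52))
  b <- build_shape(conformer(matrix(stats::rnorm(9, 0.5), 3L, 3L)),
                   radii = c(1.8, 1.7, 1.47))
  pose <- pose3d(neighborpref:::rodrigues_matrix(c(0.2, 0.1, -0.3)),
                 c(0.5, -0.2, 0.1))
  va <- overlap_volume(a, b, pose)
  # grid oracle on the posed copy
  b_posed <- build_shape(conformer(neighborpref:::apply_pose(b$centers, pose)),
                         radii = c(1.8, 1.7, 1.47))
  expect_equal(va, grid_overlap(a, b_posed), tolerance = 0.01)

  # far-separated shapes have negligible overlap
  far <- build_shape(conformer(matrix(stats::rnorm(9) + 100, 3L, 3L)),
                     radii = rep(1.7, 3L))
  expect_lt(overlap_volume(a, far), 1e-12 * a$vself)
})

test_that("shape tanimoto is 1 for self, 0 at distance, symmetric under pose inversion", {
  set.seed(6)
  a <- random_shape(4L)
  b <- random_shape(5L)
  expect_equal(shape_tanimoto(a, a), 1.0, tolerance = 1e-12)
  far <- build_shape(conformer(matrix(stats::rnorm(12, 500), 4L, 3L)),
                     radii = rep(1.7, 4L))
  expect_lt(shape_tanimoto(a, far), 1e-9)
  pose <- pose3d(neighborpref:::rodrigues_matrix(c(1, 0.5, 0)), c(1, 2, 3))
  expect_equal(shape_tanimoto(a, b, pose),
               shape_tanimoto(b, a, pose_inverse(pose)), tolerance = 1e-9)
})

test_that("monotone decay: two single atoms lose similarity with separation", {
  s0 <- build_shape(conformer(matrix(0, 1L, 3L)), radii = 1.7)
  sts <- vapply(seq(0, 5, by = 0.5), function(d) {
    sd <- build_shape(conformer(matrix(c(d, 0, 0), 1L, 3L)), radii = 1.7)
    shape_tanimoto(s0, sd)
  }, numeric(1))
  expect_true(all(diff(sts) < 0))
})

test_that("color atom typing follows the documented rule table", {
  # benzene: one ring feature at the centroid plus one hydrophobe
  cols <- assign_color_atoms(benzene_graph(), conformer(ring_coords(6L)))
  expect_equal(sum(cols$type == "ring"), 1L)
  expect_equal(sum(cols$type == "hydrophobe"), 1L)
  expect_equal(unlist(cols[cols$type == "ring", c("x", "y", "z")]),
               c(x = 0, y = 0, z = 0), tolerance = 1e-12)

  # water-like O with H: donor and acceptor at the O position
  water <- molecular_graph("O", hcounts = 2L)
  cw <- assign_color_atoms(water, conformer(matrix(1, 1L, 3L)))
  expect_setequal(cw$type, c("donor", "acceptor"))

  # carboxylate oxygen: anion (and acceptor)
  carbox <- molecular_graph(c("C", "O", "O"), charges = c(0L, 0L, -1L),
                            hcounts = c(3L, 0L, 0L),
                            bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L),
                                               order = c(2L, 1L)))
  cc <- assign_color_atoms(carbox, conformer(matrix(stats::rnorm(9), 3L, 3L)))
  expect_equal(sum(cc$type == "anion"), 1L)

  # quaternary ammonium: cation, not acceptor
  quat <- molecular_graph(c("N", "C", "C", "C", "C"),
                          charges = c(1L, 0L, 0L, 0L, 0L),
                          hcounts = c(0L, 3L, 3L, 3L, 3L),
                          bonds = data.frame(i = 1L, j = 2:5, order = 1L))
  cq <- assign_color_atoms(quat, conformer(matrix(stats::rnorm(15), 5L, 3L)))
  expect_true("cation" %in% cq$type)
  expect_false("acceptor" %in% cq$type)

  # feature-less: lone silicon
  si <- molecular_graph("Si", hcounts = 4L)
  expect_equal(nrow(assign_color_atoms(si, conformer(matrix(0, 1L, 3L)))), 0L)
})

test_that("color tanimoto sums same-type overlaps only", {
  d1 <- data.frame(type = "donor", x = 0, y = 0, z = 0, radius = 1,
                   stringsAsFactors = FALSE)
  a1 <- data.frame(type = "acceptor", x = 0, y = 0, z = 0, radius = 1,
                   stringsAsFactors = FALSE)
  expect_equal(color_tanimoto(d1, d1), 1.0, tolerance = 1e-12)
  expect_equal(as.numeric(color_tanimoto(d1, a1)), 0.0)

  empty <- d1[0L, ]
  res <- color_tanimoto(empty, empty)
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "degenerate"))
})

test_that("combo tanimoto is the plain sum with range validation", {
  expect_equal(combo_tanimoto(1, 1), 2)
  expect_equal(combo_tanimoto(0.8, 0.5), 1.3)
  expect_equal(combo_tanimoto(0, 0), 0)
  expect_error(combo_tanimoto(1.2, 0.5), "\\[0, 1\\]")
  expect_error(combo_tanimoto(0.5, -0.1), "\\[0, 1\\]")
})

test_that("ST-optimization recovers rigid transforms and beats the identity start", {
  set.seed(7)
  for (rep in 1:5) {
    xyz <- matrix(stats::rnorm(15, sd = 1.5), 5L, 3L)
    a <- build_shape(conformer(xyz), radii = rep(1.7, 5L))
    b <- build_shape(conformer(random_rigid_transform(xyz)),
                     radii = rep(1.7, 5L))
    sim <- optimize_st(a, b)
    expect_gte(sim$st, 0.99)
    # maximization cannot do worse than the centroid-aligned start
    ctr_pose <- pose3d(diag(3), colMeans(a$centers) - colMeans(b$centers))
    expect_gte(sim$st + 1e-9, shape_tanimoto(a, b, ctr_pose))
  }

  # two single atoms anywhere superpose exactly
  s1 <- build_shape(conformer(matrix(c(12, -3, 7), 1L, 3L)), radii = 1.7)
  s2 <- build_shape(conformer(matrix(c(-5, 0, 1), 1L, 3L)), radii = 1.7)
  expect_equal(optimize_st(s1, s2)$st, 1.0, tolerance = 1e-6)
})

test_that("similarity scores are invariant under rigid transforms of either input", {
  set.seed(8)
  xyz_a <- matrix(stats::rnorm(12, sd = 1.5), 4L, 3L)
  xyz_b <- matrix(stats::rnorm(15, sd = 1.5), 5L, 3L)
  a <- build_shape(conformer(xyz_a), radii = rep(1.7, 4L))
  b <- build_shape(conformer(xyz_b), radii = rep(1.7, 5L))
  st0 <- optimize_st(a, b)$st
  for (rep in 1:5) {
    bt <- build_shape(conformer(random_rigid_transform(xyz_b)),
                      radii = rep(1.7, 5L))
    expect_equal(optimize_st(a, bt)$st, st0, tolerance = 1e-3)
    at <- build_shape(conformer(random_rigid_transform(xyz_a)),
                      radii = rep(1.7, 4L))
    expect_equal(optimize_st(at, b)$st, st0, tolerance = 1e-3)
  }
})

test_that("self-similarity includes color features at the optimized pose", {
  g <- druglike_graph()
  coords <- cbind(ring_coords(6L), deparse.level = 0)
  coords <- rbind(coords, c(2.5, 0, 0.3), c(3.4, 0.8, 0.3), c(3.2, -1.1, 0.6))
  cf <- conformer(coords)
  x <- list(shape = build_shape(cf, elements = g$atoms$element),
            colors = assign_color_atoms(g, cf))
  sim <- optimize_st(x, x)
  expect_gte(sim$st, 1 - 1e-6)
  expect_gte(sim$ct, 1 - 1e-6)
  expect_equal(sim$combo, sim$st + sim$ct)
})

test_that("diverse ordering is greedy maximin with id tie-breaks", {
  # one conformer: itself
  c1 <- conformer(ring_coords(6L), id = 1L)
  expect_equal(diverse_order(list(c1), rep("C", 6L))[[1L]]$id, 1L)

  # duplicates after the seed are ordered by id
  c2 <- conformer(ring_coords(6L), id = 2L)
  c3 <- conformer(ring_coords(6L), id = 3L)
  ord <- diverse_order(list(c1, c3, c2), rep("C", 6L))
  expect_equal(vapply(ord, function(x) x$id, integer(1)), c(1L, 2L, 3L))

  # three conformers where #3 is farthest from #1: order 1, 3, 2
  base <- matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0), 3L, 3L, byrow = TRUE)
  near <- base; near[3L, ] <- near[3L, ] + c(0.8, 0.8, 0)
  farc <- matrix(c(0, 0, 0, 0, 1.5, 0, -2, 0, 2), 3L, 3L, byrow = TRUE)
  cfs <- list(conformer(base, 1L), conformer(near, 2L), conformer(farc, 3L))
  el <- rep("C", 3L)
  # oracle: brute-force check that (1,3,2) is the greedy maximin order
  shapes <- lapply(cfs, build_shape, elements = el)
  d12 <- 1 - optimize_st(shapes[[1]], shapes[[2]])$st
  d13 <- 1 - optimize_st(shapes[[1]], shapes[[3]])$st
  expect_gt(d13, d12)
  ord2 <- vapply(diverse_order(cfs, el), function(x) x$id, integer(1))
  expect_equal(ord2, c(1L, 3L, 2L))
})
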