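test_that("a single off-center atom lands in exactly one cell", {
  pose <- toy_structure(matrix(c(0.2, 0.2, 0.2), ncol = 3))
  g <- build_density_grid(pose, spacing = 1, padding = 1)
  expect_equal(sum(g$counts), 1L)
  expect_equal(sum(g$counts > 0), 1L)
  expect_equal(g$n_ligand_atoms_binned, 1L)
  # hand-binned: origin = -0.8, atom at 0.2 -> cell floor((0.2+0.8)/1)+1 = 2
  expect_equal(unname(which(g$counts > 0, arr.ind = TRUE)[1, ]), c(2L, 2L, 2L))
})

test_that("counting is linear and conservative", {
  set.seed(5)
  xyz <- matrix(runif(150, 0, 10), ncol = 3)
  pose <- toy_structure(xyz)
  g1 <- build_density_grid(pose)
  g2 <- build_density_grid(list(pose, pose))
  expect_equal(g2$counts, 2L * g1$counts)
  expect_equal(sum(g1$counts), 50L)  # conservation: all 50 atoms binned
  # hydrogens are excluded from the density
  poseH <- toy_structure(xyz, elements = rep(c("C", "H"), 25))
  expect_equal(sum(build_density_grid(poseH)$counts), 25L)
})

test_that("atoms on the upper grid boundary are kept (no atom loss)", {
  # padding 0 makes the max-coordinate atom sit exactly on the boundary
  pose <- toy_structure(matrix(c(0, 0, 0, 3, 2, 1), ncol = 3, byrow = TRUE))
  g <- build_density_grid(pose, spacing = 1, padding = 0)
  expect_equal(sum(g$counts), 2L)
})

test_that("grid input validation", {
  expect_error(build_density_grid(list()), "At least one")
  pose <- toy_structure(matrix(rnorm(9), ncol = 3))
  expect_error(build_density_grid(pose, spacing = 0), "positive")
  expect_error(build_density_grid(pose, spacing = -1), "positive")
})

test_that("single interior occupied cell yields |core| 1 and |shell| 26/18/6", {
  pose <- toy_structure(matrix(c(0.5, 0.5, 0.5), ncol = 3))
  g <- build_density_grid(pose, spacing = 1, padding = 2)
  for (conn in c(26L, 18L, 6L)) {
    reg <- grid_regions(g, connectivity = conn)
    expect_equal(nrow(reg$core), 1L)
    expect_equal(nrow(reg$shell), conn)
  }
})

test_that("two adjacent occupied cells: core 2, shell excludes core", {
  pose <- toy_structure(matrix(c(0.5, 0.5, 0.5, 1.5, 0.5, 0.5),
                               ncol = 3, byrow = TRUE))
  g <- build_density_grid(pose, spacing = 1, padding = 2)
  reg <- grid_regions(g)
  expect_equal(nrow(reg$core), 2L)
  core_lin <- dockscreen:::linear_index(reg$core, g$dims)
  shell_lin <- dockscreen:::linear_index(reg$shell, g$dims)
  expect_length(intersect(core_lin, shell_lin), 0L)
  # enumeration oracle
  o <- oracle_regions(g$counts)
  expect_equal(sort_cells(reg$core), sort_cells(o$core))
  expect_equal(sort_cells(reg$shell), sort_cells(o$shell))
})

test_that("regions of an all-zero grid are empty", {
  g <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(3L, 3L, 3L),
                      counts = array(0L, dim = c(3, 3, 3)),
                      n_ligand_atoms_binned = 0L), class = "density_grid")
  reg <- grid_regions(g)
  expect_equal(nrow(reg$core), 0L)
  expect_equal(nrow(reg$shell), 0L)
})

test_that("steric score counts covered cells, not atoms", {
  pose <- toy_structure(matrix(c(0.2, 0.2, 0.2), ncol = 3))
  g <- build_density_grid(pose, spacing = 1, padding = 1)

  outside <- toy_structure(matrix(c(50, 50, 50), ncol = 3), id = "m_out")
  expect_equal(steric_score(g, outside)$score, 0L)

  # occupied cell spans [0.2, 1.2) per axis (origin -0.8, spacing 1)
  inside1 <- toy_structure(matrix(c(0.3, 0.3, 0.3), ncol = 3), id = "m_in")
  expect_equal(steric_score(g, inside1)$score, 1L)

  # three atoms in the same occupied cell still score 1
  inside3 <- toy_structure(matrix(c(0.3, 0.3, 0.3,
                                    0.25, 0.5, 0.2,
                                    0.4, 1.0, 1.1), ncol = 3, byrow = TRUE))
  expect_equal(steric_score(g, inside3)$score, 1L)

  # region from a different grid is rejected
  other <- build_density_grid(toy_structure(matrix(rnorm(60, sd = 4),
                                                   ncol = 3)))
  expect_error(steric_score(g, inside1, grid_regions(other)$core),
               "not derived")
})

test_that("steric score and regions match exhaustive enumeration on random cases", {
  set.seed(101)
  for (rep in 1:20) {
    n_lig <- sample(5:40, 1)
    spacing <- sample(c(1, 1.5), 1)
    lig <- toy_structure(matrix(runif(3 * n_lig, 0, 9), ncol = 3))
    g <- build_density_grid(lig, spacing = spacing, padding = 2)
    conn <- sample(c(6L, 18L, 26L), 1)
    reg <- grid_regions(g, connectivity = conn)
    o <- oracle_regions(g$counts, connectivity = conn)
    expect_equal(sort_cells(reg$core), sort_cells(o$core))
    expect_equal(sort_cells(reg$shell), sort_cells(o$shell))

    rec_xyz <- matrix(runif(3 * 20, -3, 13), ncol = 3)
    rec <- toy_structure(rec_xyz, id = "rec")
    got <- steric_score(g, rec, reg$core)$score
    want <- oracle_steric_score(o$core, rec_xyz, g$origin, spacing, g$dims)
    expect_equal(got, want)
  }
})

test_that("steric score is monotone in receptor atoms and translation-covariant", {
  set.seed(19)
  lig <- toy_structure(matrix(runif(90, 0, 8), ncol = 3))
  g <- build_density_grid(lig)
  core <- grid_regions(g)$core
  rec_xyz <- matrix(runif(90, -2, 10), ncol = 3)
  s_half <- steric_score(g, toy_structure(rec_xyz[1:15, ]), core)$score
  s_full <- steric_score(g, toy_structure(rec_xyz), core)$score
  expect_gte(s_full, s_half)

  # integer-spacing shift of everything leaves the score unchanged
  v <- c(3, -2, 5)  # multiple of spacing 1
  lig2 <- toy_structure(sweep(cbind(lig$x, lig$y, lig$z), 2, v, `+`))
  g2 <- build_density_grid(lig2)
  rec2 <- toy_structure(sweep(rec_xyz, 2, v, `+`))
  expect_equal(steric_score(g2, rec2, grid_regions(g2)$core)$score, s_full)
})

test_that("derive_box centers on the core centroid with margin-padded extents", {
  pose <- toy_structure(matrix(c(0.5, 0.5, 0.5), ncol = 3))
  g <- build_density_grid(pose, spacing = 1, padding = 2)
  b <- derive_box(g, margin = 2)
  expect_s3_class(b, "box_spec")
  # atom at 0.5 occupies the cell [0.5, 1.5) (origin -1.5), center 1.0
  expect_equal(b$center, c(1, 1, 1))
  expect_equal(b$size, c(5, 5, 5))  # one cell + 2 A per side

  # symmetric two-cell core: center at the midpoint; margin 0 covers core
  pose2 <- toy_structure(matrix(c(0.5, 0.5, 0.5, 2.5, 0.5, 0.5),
                                ncol = 3, byrow = TRUE))
  g2 <- build_density_grid(pose2, spacing = 1, padding = 2)
  b2 <- derive_box(g2, margin = 0)
  expect_equal(b2$center, c(2, 1, 1))  # cell centers 1.0 and 3.0 on x
  expect_equal(b2$size, c(3, 1, 1))

  g0 <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(2L, 2L, 2L),
                       counts = array(0L, dim = c(2, 2, 2)),
                       n_ligand_atoms_binned = 0L), class = "density_grid")
  expect_error(derive_box(g0), "no occupied cells")
})
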