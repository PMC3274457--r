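test_that("pentahedron restraints bracket the true geometry", {
  pent <- fix_pentahedron()
  expect_equal(nrow(pent$restraints), 10)
  d <- sqrt(colSums((t(pent$xyz)[, pent$restraints$resid_a] -
                     t(pent$xyz)[, pent$restraints$resid_b])^2))
  expect_true(all(pent$restraints$lower < d & d < pent$restraints$upper))
  expect_equal(pent$restraints$upper - pent$restraints$lower,
               rep(0.02, 10), tolerance = 1e-12)
  # the points are in general position (not coplanar)
  expect_gt(min(abs(eigen(cov(pent$xyz))$values)), 1e-3)
})

test_that("dense clusters are fully triangulated and seed-deterministic", {
  x1 <- fix_dense_cluster(20, seed = 7)
  x2 <- fix_dense_cluster(20, seed = 7)
  expect_identical(x1, x2)
  expect_false(identical(x1, fix_dense_cluster(20, seed = 8)))
  expect_true(all(dist(x1) < 2.8))
  rs <- fix_triangulated_cloud(x1, cutoff = 3)
  expect_equal(nrow(rs), choose(20, 2))
  expect_true(all(rs$lower == 2 & rs$upper == 5))
  expect_error(fix_triangulated_cloud(x1 * 100, cutoff = 3), "closer")
})

test_that("ideal barrels realise the requested radius law", {
  rfun <- function(z) 4 + 0.3 * cos(z)
  bar <- fix_ideal_barrel(n_points = 200, height = 12, radius_fn = rfun,
                          seed = 9, jitter_sd = 0)
  r <- sqrt(bar$xyz[, 1]^2 + bar$xyz[, 2]^2)
  expect_equal(r, rfun(bar$xyz[, 3]), tolerance = 1e-9)
  expect_equal(range(bar$xyz[, 3]), c(-6, 6))
  expect_setequal(unique(bar$atoms$elety), c("N", "CA", "C", "O"))
  expect_error(fix_ideal_barrel(radius_fn = function(z) z), "positive")
})

test_that("ring-arranged barrels place symmetric full rings at cell centres", {
  rfun <- function(z) 4 + 0.3 * cos(z)
  bar <- fix_ideal_barrel(n_points = 240, height = 12, radius_fn = rfun,
                          seed = 9, jitter_sd = 0, arrangement = "rings",
                          ring_spacing = 0.5)
  z <- round(bar$xyz[, 3], 9)
  lev <- sort(unique(z))
  # 24 cell-centred levels on [-6, 6], symmetric about 0
  expect_length(lev, 24)
  expect_equal(lev, -rev(lev))
  expect_equal(diff(lev), rep(0.5, 23))
  expect_equal(max(lev), 6 - 0.25)
  # each level is a full uniform ring of equal size obeying the law
  counts <- table(z)
  expect_true(all(counts == counts[[1]]))
  r <- sqrt(bar$xyz[, 1]^2 + bar$xyz[, 2]^2)
  expect_equal(r, rfun(bar$xyz[, 3]), tolerance = 1e-9)
  one <- bar$xyz[z == lev[1], ]
  ang <- sort(atan2(one[, 2], one[, 1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_equal(max(gaps), min(gaps), tolerance = 1e-9)
})

test_that("mini proteins have complete residues and round-trip through PDB", {
  mp <- fix_mini_protein(c("GLY", "PRO", "SER"), seed = 2)
  at <- mp$atoms
  expect_setequal(at$elety[at$resno == 1], c("N", "CA", "C", "O", "H"))
  expect_false("H" %in% at$elety[at$resno == 2])      # proline
  expect_true(all(c("OG", "HG") %in% at$elety[at$resno == 3]))
  expect_error(fix_mini_protein(c("ALA", "ZZZ")), "ZZZ")

  tmp <- tempfile(fileext = ".pdb")
  write_pdb_structure(mp, tmp)
  pdb <- bio3d::read.pdb(tmp)
  expect_equal(pdb$atom$x, at$x, tolerance = 1e-3)
  expect_equal(pdb$atom$elety, at$elety)
  expect_equal(pdb$atom$resno, at$resno)
})

test_that("toy trajectories record their planted truth and stay rigid-mode free", {
  mp <- fix_mini_protein(seed = 1)
  tr <- fix_toy_trajectory(mp, n_frames = 30, drift_slope = 0.2,
                           drift_intercept = 0.5, noise_sd = 0.01,
                           seed = 11)
  pl <- attr(tr, "planted")
  expect_equal(pl$drift_slope, 0.2)
  expect_equal(pl$drift_intercept, 0.5)
  expect_identical(tr$xyz, fix_toy_trajectory(mp, n_frames = 30,
                                              drift_slope = 0.2,
                                              drift_intercept = 0.5,
                                              noise_sd = 0.01,
                                              seed = 11)$xyz)
  # the superposition rotation really is the identity: the drift field
  # carries no rigid component
  sel <- which(tr$atoms$elety %in% c("N", "CA", "C", "O"))
  f10 <- matrix(tr$xyz[10, ], ncol = 3, byrow = TRUE)
  fit <- superpose(mp$xyz, f10, sel)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-6)
  expect_error(fix_toy_trajectory(mp, n_frames = 1), "at least 2")
})
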