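# Random rotation matrix from a QR decomposition, det +1.
random_rotation <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

test_that("superpose undoes an arbitrary rigid motion exactly", {
  set.seed(21)
  a <- matrix(rnorm(60, sd = 4), ncol = 3)
  for (s in 1:10) {
    R <- random_rotation(s)
    tr <- rnorm(3, sd = 20)
    b <- a %*% t(R) + matrix(tr, nrow(a), 3, byrow = TRUE)
    fit <- superpose(a, b)
    expect_equal(fit$rmsd, 0, tolerance = 1e-9)
    expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-9)
  }
})

test_that("superpose RMSD matches bio3d's fitted RMSD on noisy frames", {
  set.seed(22)
  a <- matrix(rnorm(45, sd = 3), ncol = 3)
  b <- a %*% t(random_rotation(3)) + matrix(rnorm(45, sd = 0.3), ncol = 3)
  ours <- superpose(a, b)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
  # and never exceeds the unfitted RMSD
  expect_lte(ours, sqrt(mean(rowSums((a - b)^2))))
})

test_that("noiseless planted drift is recovered exactly by the regression", {
  mp <- fix_mini_protein(seed = 1)
  tr <- fix_toy_trajectory(mp, n_frames = 50, drift_slope = 0.4,
                           noise_sd = 0, seed = 2, time_step = 1)
  ds <- drift_series(tr)
  expect_s3_class(ds, "distance_series")
  expect_equal(attr(ds, "slope"), 0.4, tolerance = 1e-9)
  expect_equal(attr(ds, "intercept"), 0, tolerance = 1e-9)
  # with a baseline offset and the structure as reference, the intercept
  # is recovered too
  tr2 <- fix_toy_trajectory(mp, n_frames = 50, drift_slope = 0.4,
                            drift_intercept = 1, seed = 2)
  ds2 <- drift_series(tr2, reference = mp$xyz)
  expect_equal(attr(ds2, "slope"), 0.4, tolerance = 1e-9)
  expect_equal(attr(ds2, "intercept"), 1, tolerance = 1e-9)
})

test_that("region centre-of-mass distances match a hand computation", {
  at <- data.frame(elety = rep(c("N", "CA", "C", "O"), 2),
                   resid = "GLY", resno = rep(c(1, 5), each = 4),
                   x = c(0, 2, 0, 2, 10, 12, 10, 12),
                   y = c(0, 0, 2, 2, 0, 0, 2, 2),
                   z = 0, stringsAsFactors = FALSE)
  xyz <- rbind(as.numeric(t(cbind(at$x, at$y, at$z))),
               as.numeric(t(cbind(at$x + 1, at$y, at$z))))
  tr <- trajectory(xyz, at, time_step = 2)
  cs <- com_distance_series(tr, list(a = 1, b = 5), c("a", "b"),
                            selection = "backbone")
  # centroids (1,1,0) and (11,1,0) in both frames -> distance 10
  expect_equal(cs$values, c(10, 10))
  expect_equal(cs$mean, 10)
  expect_error(com_distance_series(tr, default_regions(), c("a", "rt_loop")),
               "unknown region")
  # identical atom compositions shifted by 10 A: mass weighting must
  # leave the centroid separation unchanged
  cs2 <- com_distance_series(tr, list(a = 1, b = 5), c("a", "b"),
                             mass_weighted = TRUE)
  expect_equal(cs2$values, c(10, 10), tolerance = 1e-9)
})

test_that("pair distances, hydrophobic presets and hbond formation resolve by atom spec", {
  mp <- fix_mini_protein(sequence = c("TYR", "ALA", "LEU", "VAL", "ALA",
                                      "LEU", "VAL"),
                         first_resno = 49, seed = 4)
  tr <- fix_toy_trajectory(mp, n_frames = 3, seed = 1)
  ps <- pair_distance_series(tr, list(list("49:CB", "51:CD1")))[[1]]
  at <- mp$atoms
  p1 <- unlist(at[at$resno == 49 & at$elety == "CB", c("x", "y", "z")])
  p2 <- unlist(at[at$resno == 51 & at$elety == "CD1", c("x", "y", "z")])
  expect_equal(ps$values, rep(sqrt(sum((p1 - p2)^2)), 3), tolerance = 1e-9)
  expect_error(pair_distance_series(tr, list(list("49:CB", "51:XX"))),
               "not found")

  # the published preset pairs resolve on a 60-residue chain
  seq60 <- rep("ALA", 60)
  seq60[c(5, 27, 29, 40, 50, 55)] <- c("TYR", "LEU", "VAL", "ALA",
                                       "VAL", "LEU")
  big <- fix_mini_protein(seq60, seed = 5)
  trb <- fix_toy_trajectory(big, n_frames = 2, seed = 1)
  series <- pair_distance_series(trb, hydrophobic_core_pairs())
  expect_length(series, 5)

  hb <- hbond_series(tr, "49:H", "50:O", cutoff = 1e6)
  expect_true(attr(hb, "formed"))
  expect_false(attr(hbond_series(tr, "49:H", "50:O", cutoff = 0.1),
                    "formed"))
})

test_that("gaussian and empirical contact probabilities agree on normal data", {
  set.seed(31)
  n <- 10000
  d <- rnorm(n, mean = 7.5, sd = 1.2)
  at <- data.frame(elety = c("CA", "CA"), resid = "ALA", resno = c(1, 2),
                   x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  xyz <- cbind(0, 0, 0, abs(d), 0, 0)
  tr <- trajectory(xyz, at)
  s <- pair_distance_series(tr, list(list("1:CA", "2:CA")))[[1]]
  for (thr in c(6.5, 7.5, 8.5)) {
    pg <- contact_probability(s, threshold = thr)
    pe <- contact_probability(s, threshold = thr, model = "empirical")
    expect_lt(abs(pg - pe), 0.02)
  }
  # zero-variance series degenerates to an indicator, with a warning
  xyz0 <- matrix(rep(c(0, 0, 0, 5, 0, 0), 4), 4, 6, byrow = TRUE)
  s0 <- pair_distance_series(trajectory(xyz0, at),
                             list(list("1:CA", "2:CA")))[[1]]
  expect_warning(p0 <- contact_probability(s0, threshold = 7.5),
                 "zero-variance")
  expect_equal(p0, 1)
})

test_that("multi-model PDB trajectories round-trip through disk", {
  mp <- fix_mini_protein(seed = 6)
  tr <- fix_toy_trajectory(mp, n_frames = 4, drift_slope = 0.3,
                           noise_sd = 0.05, seed = 3)
  tmp <- tempfile(fileext = ".pdb")
  write_pdb_trajectory(tr, tmp)
  back <- read_trajectory(tmp, time_step = 1)
  expect_equal(nrow(back$xyz), 4)
  expect_equal(back$xyz, tr$xyz, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$atoms$resno, tr$atoms$resno)
  ds1 <- drift_series(tr); ds2 <- drift_series(back)
  expect_equal(attr(ds2, "slope"), attr(ds1, "slope"), tolerance = 1e-2)
})
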