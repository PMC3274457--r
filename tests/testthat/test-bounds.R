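test_that("chain-model baseline smooths to u * |i - j| capped at u_max", {
  rs <- restraint_set(1, "H", 2, "H", 0, 5)  # carries no extra information
  bl <- baseline_spec("chain_model", u = 4, u_max = 30)
  sm <- smooth_bounds(build_bounds(rs, bl, nodes = chain_nodes(12)))
  expected <- pmin(4 * abs(outer(1:12, 1:12, `-`)), 30)
  expect_equal(sm$upper, expected, tolerance = 1e-12)
  expect_true(all(sm$lower == 0))
})

test_that("triangle smoothing tightens uppers by paths and lowers by inverse triangles", {
  # u12 = 2, u23 = 3, no direct 1-3 bound: path gives u13 = 5
  rs <- restraint_set(c(1, 2), c("H", "H"), c(2, 3), c("H", "H"),
                      lower = c(0, 0), upper = c(2, 3))
  sm <- smooth_bounds(build_bounds(rs, baseline_spec("restraints_only")))
  expect_equal(sm$upper[1, 3], 5)

  # l13 = 5 with u23 = 2 forces l12 >= 5 - 2 = 3
  rs2 <- restraint_set(c(1, 2), c("H", "H"), c(3, 3), c("H", "H"),
                       lower = c(5, 0), upper = c(9, 2))
  sm2 <- smooth_bounds(build_bounds(rs2, baseline_spec("restraints_only")))
  expect_equal(sm2$lower[1, 2], 3)
})

test_that("smoothing is idempotent, symmetric and never loosens bounds", {
  for (s in 1:20) {
    bm <- build_bounds(random_restraints(sample(4:9, 1), seed = s))
    sm <- smooth_bounds(bm)
    expect_true(all(sm$upper <= bm$upper + 1e-12))
    expect_true(all(sm$lower >= bm$lower - 1e-12))
    expect_true(all(sm$lower <= sm$upper + 1e-12))
    expect_identical(sm$upper, t(sm$upper))
    expect_identical(sm$lower, t(sm$lower))
    again <- smooth_bounds(sm)
    expect_equal(again$upper, sm$upper, tolerance = 1e-12)
    expect_equal(again$lower, sm$lower, tolerance = 1e-12)
  }
})

test_that("inconsistent bound intersections are rejected with the offending pair", {
  rs <- restraint_set(c(1, 1), c("H", "H"), c(2, 2), c("HA", "HA"),
                      lower = c(6, 0), upper = c(9, 3))
  expect_error(build_bounds(rs), "inconsistent.*HA")

  # geometric inconsistency only surfaces after smoothing:
  # l13 = 10 but u12 + u23 = 4
  rs2 <- restraint_set(c(1, 2, 1), c("H", "H", "H"),
                       c(2, 3, 3), c("H", "H", "H"),
                       lower = c(0, 0, 10), upper = c(2, 2, 12))
  expect_error(smooth_bounds(build_bounds(rs2)), "inconsistent")
})

test_that("topology baseline pins same- and sequential-residue pairs to the structure", {
  mp <- fix_mini_protein(seed = 3)
  rs <- restraint_set(c(1, 1), c("H", "H"), c(2, 8), c("H", "H"),
                      lower = c(2, 2), upper = c(5, 5))
  bl <- baseline_spec("topology", structure = mp)
  bm <- build_bounds(rs, bl)
  nodes <- bm$nodes
  i <- which(nodes$resid == 1)
  j <- which(nodes$resid == 2)
  k <- which(nodes$resid == 8)
  at <- mp$atoms
  d12 <- sqrt(sum((unlist(at[at$resno == 1 & at$elety == "H",
                             c("x", "y", "z")]) -
                   unlist(at[at$resno == 2 & at$elety == "H",
                             c("x", "y", "z")]))^2))
  # sequential pair: near-exact structural bounds (intersected with [2, 5])
  expect_equal(bm$lower[i, j], max(2, d12 - 0.01), tolerance = 1e-9)
  expect_equal(bm$upper[i, j], min(5, d12 + 0.01), tolerance = 1e-9)
  # non-adjacent pair: restraint bounds only, no structural pinning
  expect_equal(c(bm$lower[i, k], bm$upper[i, k]), c(2, 5))
  expect_error(baseline_spec("topology"), "reference structure")
})

test_that("pseudoatom selections resolve to the centroid of the matching atoms", {
  at <- data.frame(elety = c("N", "CA", "HB1", "HB2", "HB3"),
                   resid = "ALA", resno = 1,
                   x = c(0, 1, 2, 4, 6), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  rs <- restraint_set(1, "HB#", 1, "CA", 0, 10)
  bl <- baseline_spec("topology",
                      structure = list(atom = at))
  bm <- build_bounds(rs, bl)
  i <- which(bm$nodes$name == "HB#")
  j <- which(bm$nodes$name == "CA")
  # centroid of HB1..HB3 at x = 4; CA at x = 1 -> distance 3
  expect_equal(bm$upper[i, j], 3 + 0.01, tolerance = 1e-9)
  expect_equal(bm$lower[i, j], 3 - 0.01, tolerance = 1e-9)
})

test_that("bounds_as_table enumerates every unordered pair once", {
  bm <- build_bounds(random_restraints(6, seed = 2))
  tab <- bounds_as_table(bm)
  expect_equal(nrow(tab), choose(nrow(bm$nodes), 2))
  expect_true(all(tab$i < tab$j))
  expect_equal(tab$upper, bm$upper[cbind(tab$i, tab$j)])
})
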