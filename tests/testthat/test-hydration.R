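test_that("donor/acceptor templates flag the chemistry, not the geometry", {
  mp <- fix_mini_protein(c("ALA", "SER", "PRO", "ASP", "LYS"), seed = 2)
  da <- donors_acceptors(mp)
  get <- function(rn, nm, col)
    da[[col]][da$resno == rn & da$elety == nm]
  expect_true(all(vapply(1:5, function(r) get(r, "O", "acceptor"), TRUE)))
  expect_true(get(1, "H", "donor_h"))
  expect_length(get(3, "H", "donor_h"), 0)       # PRO has no amide H
  expect_true(get(2, "OG", "acceptor"))          # SER side chain
  expect_true(get(2, "HG", "donor_h"))
  expect_true(all(get(4, "OD1", "acceptor"), get(4, "OD2", "acceptor")))
  expect_true(get(5, "HZ1", "donor_h"))          # LYS ammonium
  expect_false(get(1, "CA", "acceptor") || get(1, "CA", "donor_h"))
  # unknown residues are skipped with a warning, waters silently
  odd <- mp
  odd$atoms$resid[odd$atoms$resno == 5] <- "XYZ"
  expect_warning(donors_acceptors(odd), "XYZ")
})

test_that("a water bridge needs two different water atoms within the strict cutoff", {
  tr <- star_trajectory(list(1), 1, d1 = 2.0, d2 = 2.0)
  at <- tr$atoms
  da <- donors_acceptors(list(atoms = at))
  xyz <- matrix(tr$xyz[1, ], ncol = 3, byrow = TRUE)
  br <- frame_bridges(xyz, at, da)
  expect_equal(dim(br), c(1L, 2L))
  expect_equal(as.numeric(br), c(1, 2))

  # at exactly the cutoff the contact does not count (strict <)
  tr2 <- star_trajectory(list(1), 1, d1 = 2.5, d2 = 2.0)
  xyz2 <- matrix(tr2$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(nrow(frame_bridges(xyz2, tr2$atoms, da)), 0)

  # a single water atom touching both residues is not a bridge: put the
  # two residues' O atoms 4 A apart with one water O midway (2 A each)
  at3 <- star_structure()
  at3$x[at3$resno == 2] <- at3$x[at3$resno == 2] - 26  # O atoms: x = 3, 7
  wat <- data.frame(elety = "OW", resid = "HOH", resno = 11,
                    x = 5, y = 0, z = 0, stringsAsFactors = FALSE)
  all3 <- rbind(at3, wat)
  br3 <- frame_bridges(cbind(all3$x, all3$y, all3$z), all3,
                       donors_acceptors(list(atoms = all3)))
  expect_equal(nrow(br3), 0)
})

test_that("planted occupancies are reproduced exactly and thresholds are strict", {
  on <- list(1:14, 1:10, 1:8)       # occupancies 0.7, 0.5, 0.4 over 20
  tr <- star_trajectory(on, 20)
  net <- bridge_network(tr)
  occ <- net$occupancy
  expect_equal(occ$occupancy[occ$res_a == 1 & occ$res_b == 2], 0.7)
  expect_equal(occ$occupancy[occ$res_a == 1 & occ$res_b == 3], 0.5)
  expect_equal(occ$occupancy[occ$res_a == 1 & occ$res_b == 4], 0.4)
  # 0.4 is NOT an edge (strictly above 40% required); 0.5 is an edge but
  # not thick; 0.7 is thick
  ekey <- paste(net$edges$res_a, net$edges$res_b)
  expect_setequal(ekey, c("1 2", "1 3"))
  expect_equal(net$edges$thick[ekey == "1 2"], TRUE)
  expect_equal(net$edges$thick[ekey == "1 3"], FALSE)
  # the max-degree node of the single component is the center
  expect_equal(net$hubs, 1)
})

test_that("hub detection breaks degree ties by the lower residue number", {
  # two disjoint 2-node components: every node has degree 1, so each
  # component's hub is its lower-numbered residue
  at <- star_structure()
  at2 <- at
  # move residue 4 near nothing; bridge 1-2 and 3-4 instead
  site <- rbind(c(0, 0, 0), c(8, 0, 0), c(100, 0, 0), c(108, 0, 0))
  for (i in 1:4) {
    rows <- at2$resno == i
    at2$x[rows] <- site[i, 1] + c(0, 1.5, 2.5, 3.0)
    at2$y[rows] <- site[i, 2]
    at2$z[rows] <- site[i, 3]
  }
  wat <- data.frame(elety = rep(c("OW", "HW1"), 2), resid = "HOH",
                    resno = rep(11:12, each = 2), x = 0, y = 0, z = 0,
                    stringsAsFactors = FALSE)
  all_at <- rbind(at2, wat)
  xyz <- cbind(all_at$x, all_at$y, all_at$z)
  # water 11 between O of 1 (x=3) and O of 2 (x=11): atoms at 5 and 9
  xyz[nrow(at2) + 1, ] <- c(5, 0, 0)
  xyz[nrow(at2) + 2, ] <- c(9, 0, 0)
  # water 12 between O of 3 (x=103) and O of 4 (x=111)
  xyz[nrow(at2) + 3, ] <- c(105, 0, 0)
  xyz[nrow(at2) + 4, ] <- c(109, 0, 0)
  frames <- matrix(rep(as.numeric(t(xyz)), 12), nrow = 12, byrow = TRUE)
  tr <- trajectory(frames, all_at)
  net <- bridge_network(tr)
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$thick))
  expect_equal(net$hubs, c(1, 3))
})

test_that("planted toy-trajectory bridges surface at their planted occupancy", {
  mp <- fix_mini_protein(rep(c("SER", "ALA", "ASP", "GLY"), 3), seed = 8)
  tr <- fix_toy_trajectory(mp, n_frames = 20,
                           water_bridges = list(
                             list(pair = c(1, 7), occupancy = 0.45)),
                           seed = 5)
  net <- bridge_network(tr)
  occ <- net$occupancy
  hit <- occ$occupancy[occ$res_a == 1 & occ$res_b == 7]
  expect_equal(hit, 0.45)
  expect_equal(attr(tr, "planted")$water_bridges[[1]]$occupancy, 0.45)
})
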