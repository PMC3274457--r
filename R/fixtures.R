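# Synthetic fixture generators. Every generator is seed-deterministic
# (same spec + seed gives byte-identical artifacts) and its output
# satisfies the preconditions of the module it feeds.

#' Rigid pentahedron fixture
#'
#' Five spins in general 3-D position with all 10 pairwise distances
#' restrained to near-exact bounds (width 0.02 A around the true
#' distance). Five points with nine of the ten edges form a minimally
#' rigid framework, so every restraint here is fully redundant: each
#' leave-one-out unique information is zero.
#'
#' @return List with `xyz` (5 x 3 coordinates) and `restraints` (a
#'   10-restraint [restraint_set()], one node per spin, names `H`).
#' @export
fix_pentahedron <- function() {
  xyz <- matrix(c(0.0, 0.0, 0.0,
                  3.0, 0.2, 0.1,
                  1.2, 2.8, 0.3,
                  0.8, 1.1, 2.6,
                  2.1, 1.7, 1.4), ncol = 3, byrow = TRUE)
  idx <- utils::combn(5, 2)
  d <- sqrt(colSums((t(xyz)[, idx[1, ]] - t(xyz)[, idx[2, ]])^2))
  rs <- restraint_set(resid_a = idx[1, ], name_a = rep("H", 10),
                      resid_b = idx[2, ], name_b = rep("H", 10),
                      lower = d - 0.01, upper = d + 0.01,
                      label = "full")
  list(xyz = xyz, restraints = rs)
}

#' Fully triangulated restraint set from a point cloud
#'
#' One restraint per pair of points closer than `cutoff`, all with the
#' same `[lower, upper]` bounds — the synthetic construction in which
#' every restraint is implied by the full triangulation and carries no
#' unique information.
#'
#' @param xyz n x 3 coordinate matrix (one spin per row; row i becomes
#'   node resid i, name `H`). A structure object is also accepted, in
#'   which case its hydrogen atoms are used.
#' @param cutoff pair distance cutoff in Angstrom (default 3).
#' @param lower,upper uniform bounds (defaults 2 and 5 A).
#' @return A [restraint_set()].
#' @export
fix_triangulated_cloud <- function(xyz, cutoff = 3.0, lower = 2.0,
                                   upper = 5.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!is.matrix(xyz)) {
    at <- structure_atoms(xyz)
    hy <- grepl("^H", at$elety)
    xyz <- cbind(at$x[hy], at$y[hy], at$z[hy])
  }
  n <- nrow(xyz)
  idx <- utils::combn(n, 2)
  d <- sqrt(colSums((t(xyz)[, idx[1, ]] - t(xyz)[, idx[2, ]])^2))
  hit <- d < cutoff
  if (!any(hit)) stop("no pair closer than ", cutoff, " A")
  restraint_set(resid_a = idx[1, hit], name_a = rep("H", sum(hit)),
                resid_b = idx[2, hit], name_b = rep("H", sum(hit)),
                lower = rep(lower, sum(hit)), upper = rep(upper, sum(hit)),
                label = "full")
}

#' Dense point cluster
#'
#' `n` points drawn uniformly in a ball of radius `radius` (default
#' 1.4 A, so all pairs are closer than 2.8 A and the cluster is fully
#' triangulated at a 3 A cutoff).
#'
#' @param n number of points (default 20).
#' @param radius ball radius in Angstrom.
#' @param seed integer seed.
#' @return n x 3 coordinate matrix.
#' @export
fix_dense_cluster <- function(n = 20L, radius = 1.4, seed = 1L) {
  with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- radius * stats::runif(n)^(1 / 3)
    u * r
  })
}

#' Ideal beta-barrel point cloud
#'
#' Points on a tube of height `height` whose radius varies along the
#' axial coordinate z as `radius_fn(z)` (constant 5 A by default), with
#' seeded isotropic jitter (sd 0.05 A). The points are emitted as
#' backbone-style PDB atom records (N, CA, C, O cycling) so the barrel
#' profiler can treat them as a backbone.
#'
#' Two samplings are available. The default `"spiral"` winds a golden-
#' angle helix up the tube (a generic, featureless point cloud). With
#' `"rings"` the points sit on equally spaced z-levels, each level a
#' uniformly sampled circle; use this for cavity-profile recovery
#' studies, since a full uniform ring at the minimal radius pins the
#' largest-empty-circle centre to the axis (the spiral's z-theta
#' coupling leaves angular gaps among the near-minimal points that bias
#' slab radii upward by more than the jitter).
#'
#' @param n_points number of surface points (default 400).
#' @param height barrel height in Angstrom (default 20).
#' @param radius_fn function of the axial coordinate, must be positive
#'   on `[-height/2, height/2]`.
#' @param seed integer seed.
#' @param jitter_sd coordinate jitter (default 0.05 A).
#' @param arrangement `"spiral"` (default) or `"rings"`.
#' @param ring_spacing z-distance between rings (Angstrom, only for
#'   `"rings"`; default 0.5). Rings are cell-centred on
#'   `[-height/2, height/2]`, so for spacings that divide the height
#'   evenly the level set is symmetric about z = 0.
#' @return Structure list with `atoms` (atom table incl. x, y, z) and
#'   `xyz` (n x 3 matrix).
#' @export
fix_ideal_barrel <- function(n_points = 400L, height = 20,
                             radius_fn = function(z) rep(5, length(z)),
                             seed = 1L, jitter_sd = 0.05,
                             arrangement = c("spiral", "rings"),
                             ring_spacing = 0.5) {
  arrangement <- match.arg(arrangement)
  golden <- 2.399963229728653
  if (arrangement == "spiral") {
    z <- seq(-height / 2, height / 2, length.out = n_points)
    theta <- (seq_len(n_points) - 1) * golden
  } else {
    # cell-centred levels: symmetric about 0, so recentring the axial
    # coordinate on the data midrange leaves rings where they were
    # placed; a ring cut by a slab edge would be a partial circle whose
    # angular gaps let an empty circle drift off-axis
    n_rings <- max(2L, floor(height / ring_spacing))
    levels <- (seq_len(n_rings) - (n_rings + 1) / 2) * ring_spacing
    per_ring <- max(3L, round(n_points / length(levels)))
    n_points <- per_ring * length(levels)
    z <- rep(levels, each = per_ring)
    # uniform ring, de-phased ring-to-ring by the golden angle
    theta <- rep(seq(0, 2 * pi, length.out = per_ring + 1)[-1],
                 times = length(levels)) +
             rep(seq_along(levels) * golden, each = per_ring)
  }
  r <- radius_fn(z)
  if (any(r <= 0)) stop("radius_fn must be positive on the barrel span")
  xyz <- cbind(r * cos(theta), r * sin(theta), z)
  xyz <- xyz + with_seed(seed,
    matrix(stats::rnorm(3 * n_points, sd = jitter_sd), n_points, 3))
  elety <- rep(c("N", "CA", "C", "O"), length.out = n_points)
  atoms <- data.frame(elety = elety, resid = "ALA",
                      resno = (seq_len(n_points) - 1) %/% 4 + 1,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = xyz)
}

# Minimal side-chain atom templates (names only; coordinates are
# jittered offsets from CB). Covers the atoms the donor/acceptor
# templates and the hydrophobic-core monitor presets refer to.
.sidechain_atoms <- list(
  ALA = "CB", ARG = c("CB", "CG", "CD", "NE", "HE", "CZ", "NH1",
                      "HH11", "HH12", "NH2", "HH21", "HH22"),
  ASN = c("CB", "CG", "OD1", "ND2", "HD21", "HD22"),
  ASP = c("CB", "CG", "OD1", "OD2"), CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2", "HE21", "HE22"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"), GLY = character(0),
  HIS = c("CB", "CG", "ND1", "HD1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"), SER = c("CB", "OG", "HG"),
  THR = c("CB", "OG1", "HG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "HE1"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH", "HH"),
  VAL = c("CB", "CG1", "CG2"))

#' Small synthetic protein structure
#'
#' Builds a compact helical backbone (N, CA, C, O plus amide H except
#' proline) with schematic side chains for an arbitrary sequence, for
#' use as a toy-trajectory and water-bridge test bed. Geometry is
#' plausible at the Angstrom scale but not stereochemically exact.
#'
#' @param sequence character vector of 3-letter residue codes; either
#'   unnamed (numbered from `first_resno`) or named by residue number.
#' @param first_resno first residue number (default 1).
#' @param seed seed for the side-chain jitter.
#' @return Structure list with `atoms` and `xyz` as in
#'   [fix_ideal_barrel()].
#' @export
fix_mini_protein <- function(sequence = rep(c("ALA", "LEU", "SER", "ASP",
                                              "VAL", "GLY"), 2),
                             first_resno = 1L, seed = 1L) {
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, names(.sidechain_atoms))
  if (length(bad) > 0) stop("unknown residue code(s): ",
                            paste(unique(bad), collapse = ", "))
  n <- length(sequence)
  resno <- if (!is.null(names(sequence))) as.integer(names(sequence))
           else first_resno + seq_len(n) - 1L
  rows <- list()
  jit <- with_seed(seed, stats::rnorm(20000, sd = 0.4))
  jp <- 0L
  next_jit <- function(k) {
    jp <<- jp + k
    jit[(jp - k + 1):jp]
  }
  for (i in seq_len(n)) {
    ca <- c(2.3 * cos(1.745 * i), 2.3 * sin(1.745 * i), 1.5 * i)
    add <- function(name, pos)
      rows[[length(rows) + 1]] <<- data.frame(
        elety = name, resid = sequence[i], resno = resno[i],
        x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
    nn <- ca + c(-0.52, -1.21, -0.41)
    cc <- ca + c(0.63, 1.12, 0.48)
    add("N", nn)
    add("CA", ca)
    add("C", cc)
    add("O", cc + c(0.31, 0.58, -0.52))
    if (sequence[i] != "PRO") add("H", nn + c(-0.58, -0.49, 0.33))
    side <- .sidechain_atoms[[sequence[i]]]
    if (length(side) > 0) {
      cb <- ca + c(1.02, -0.87, 0.61)
      add("CB", cb)
      for (k in seq_along(side)[-1])
        add(side[k], cb + c(0.45 * k, -0.3 * k, 0.35 * k) + next_jit(3))
    }
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  list(atoms = atoms, xyz = cbind(atoms$x, atoms$y, atoms$z))
}

#' Toy trajectory with planted drift and water bridges
#'
#' Frames are the input structure plus a growing displacement along a
#' fixed random direction field, plus optional amplitude noise, so the
#' superposed-RMSD drift has a closed form. The displacement field is
#' projected orthogonal to the rigid motions (translations and
#' infinitesimal rotations) of the selection and normalised to unit
#' root-mean-square atom displacement; this keeps the optimal Kabsch
#' rotation exactly the identity, so the fitted RMSD at frame time t
#' (ns) is exactly `|drift_slope * t + eps_t|` with
#' `eps_t ~ N(0, noise_sd^2)`.
#'
#' For each requested water bridge `(pair = c(p, q), occupancy = f)` a
#' water molecule is placed in bridging geometry between the nearest
#' donor/acceptor atoms of residues p and q in exactly
#' `round(f * n_frames)` randomly chosen frames (and parked far away in
#' the others).
#'
#' @param structure a structure list (see [fix_mini_protein()]) or
#'   `bio3d` pdb object.
#' @param n_frames number of frames (>= 2).
#' @param drift_slope planted drift slope in Angstrom/ns (default 0).
#' @param drift_intercept baseline drift amplitude in Angstrom at t = 0
#'   (default 0), emulating the offset real drifts acquire during
#'   equilibration; keep `intercept + slope * t` well above `noise_sd`
#'   when testing slope recovery, since the fitted RMSD is the
#'   absolute amplitude.
#' @param noise_sd amplitude noise on the drift coordinate, Angstrom
#'   (default 0).
#' @param water_bridges list of `list(pair = c(p, q), occupancy = f)`.
#' @param seed integer seed.
#' @param time_step frame spacing in ps (default 1).
#' @param selection atoms carrying the drift (default `"backbone"`).
#' @return A [trajectory()] whose atom table includes any planted
#'   waters, with attribute `planted` recording the generated truth.
#' @export
fix_toy_trajectory <- function(structure, n_frames, drift_slope = 0,
                               drift_intercept = 0, noise_sd = 0,
                               water_bridges = list(), seed = 1L,
                               time_step = 1, selection = "backbone") {
  if (n_frames < 2) stop("need at least 2 frames")
  at <- structure_atoms(structure)
  xyz0 <- cbind(at$x, at$y, at$z)
  sel <- selection_indices(at, selection)
  time <- (seq_len(n_frames) - 1) * time_step
  t_ns <- time / 1000

  planted <- list(drift_slope = drift_slope,
                  drift_intercept = drift_intercept, noise_sd = noise_sd)
  rng <- with_seed(seed, list(
    field = stats::rnorm(3 * length(sel)),
    eps = stats::rnorm(n_frames, sd = noise_sd),
    frame_picks = lapply(water_bridges, function(wb)
      sample(n_frames, round(wb$occupancy * n_frames)))))

  # drift mode: orthogonal to rigid motions of the selection, unit rms
  U <- matrix(0, nrow(xyz0), 3)
  if (drift_slope != 0 || drift_intercept != 0 || noise_sd != 0) {
    xs <- xyz0[sel, , drop = FALSE]
    ctr <- colMeans(xs)
    xc <- sweep(xs, 2, ctr)
    u <- matrix(rng$field, ncol = 3)
    basis <- cbind(
      rep(c(1, 0, 0), each = nrow(xs)),
      rep(c(0, 1, 0), each = nrow(xs)),
      rep(c(0, 0, 1), each = nrow(xs)),
      as.numeric(cbind(0, -xc[, 3], xc[, 2])),
      as.numeric(cbind(xc[, 3], 0, -xc[, 1])),
      as.numeric(cbind(-xc[, 2], xc[, 1], 0)))
    uv <- as.numeric(u)
    q <- qr.Q(qr(basis))
    uv <- uv - q %*% crossprod(q, uv)
    u <- matrix(uv, ncol = 3)
    u <- u / sqrt(mean(rowSums(u^2)))
    U[sel, ] <- u
  }

  # bridging geometry targets (per bridge: flagged atoms of p and q)
  datab <- NULL
  bridge_atoms <- lapply(water_bridges, function(wb) {
    if (is.null(datab))
      datab <<- suppressWarnings(donors_acceptors(list(atoms = at)))
    fp <- which((datab$donor_h | datab$acceptor) & at$resno == wb$pair[1])
    fq <- which((datab$donor_h | datab$acceptor) & at$resno == wb$pair[2])
    if (length(fp) == 0 || length(fq) == 0)
      stop("no donor/acceptor atoms in residue ", wb$pair[1], " or ",
           wb$pair[2])
    dd <- sqrt(outer(xyz0[fp, 1], xyz0[fq, 1], `-`)^2 +
               outer(xyz0[fp, 2], xyz0[fq, 2], `-`)^2 +
               outer(xyz0[fp, 3], xyz0[fq, 3], `-`)^2)
    best <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    c(fp[best[1]], fq[best[2]])
  })

  n_wat <- length(water_bridges)
  wat_atoms <- NULL
  if (n_wat > 0) {
    maxres <- max(at$resno)
    wat_atoms <- do.call(rbind, lapply(seq_len(n_wat), function(w)
      data.frame(elety = c("OW", "HW1", "HW2"), resid = "HOH",
                 resno = maxres + w, x = 0, y = 0, z = 0,
                 stringsAsFactors = FALSE)))
  }
  all_atoms <- rbind(at[, c("elety", "resid", "resno", "x", "y", "z")],
                     wat_atoms)

  frames <- matrix(NA_real_, n_frames, 3 * nrow(all_atoms))
  np <- nrow(xyz0)
  for (f in seq_len(n_frames)) {
    amp <- drift_intercept + drift_slope * t_ns[f] + rng$eps[f]
    xf <- xyz0 + amp * U
    wxyz <- NULL
    if (n_wat > 0) {
      wxyz <- matrix(0, 3 * n_wat, 3)
      for (w in seq_len(n_wat)) {
        ap <- xf[bridge_atoms[[w]][1], ]
        aq <- xf[bridge_atoms[[w]][2], ]
        uvec <- aq - ap
        uvec <- uvec / max(sqrt(sum(uvec^2)), 1e-9)
        o <- ap + 1.9 * uvec
        h1 <- aq - 1.9 * uvec
        h2 <- o + c(0.25, 0.25, 0.9)
        if (!f %in% rng$frame_picks[[w]]) {
          off <- c(0, 0, 999 + 50 * w)
          o <- o + off; h1 <- h1 + off; h2 <- h2 + off
        }
        wxyz[(3 * w - 2):(3 * w), ] <- rbind(o, h1, h2)
      }
    }
    frames[f, ] <- as.numeric(t(rbind(xf, wxyz)))
  }
  planted$bridge_frames <- rng$frame_picks
  planted$water_bridges <- water_bridges
  tr <- trajectory(frames, all_atoms, time_step = time_step)
  attr(tr, "planted") <- planted
  tr
}

# ---- plain-text PDB writers -------------------------------------------

format_pdb_atom <- function(serial, name, resid, chain, resno, x, y, z) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, nm, resid, chain, resno, x, y, z, 1, 0)
}

#' Write a structure as a PDB file
#'
#' Minimal coordinate-record writer for the synthetic fixtures (byte
#' deterministic). Use [bio3d::write.pdb] for full-featured output.
#'
#' @param structure structure list with `atoms` (and x/y/z columns).
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_pdb_structure <- function(structure, file) {
  at <- structure_atoms(structure)
  lines <- vapply(seq_len(nrow(at)), function(i)
    format_pdb_atom(i, at$elety[i], at$resid[i], "A", at$resno[i],
                    at$x[i], at$y[i], at$z[i]), "")
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_pdb_trajectory <- function(traj, file) {
  at <- traj$atoms
  out <- character(0)
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    lines <- vapply(seq_len(nrow(at)), function(i)
      format_pdb_atom(i, at$elety[i], at$resid[i], "A", at$resno[i],
                      xyz[i, 1], xyz[i, 2], xyz[i, 3]), "")
    out <- c(out, sprintf("MODEL %8d", f), lines, "ENDMDL")
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}
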