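#' Construct a trajectory object
#'
#' A trajectory is an ordered set of coordinate frames over a fixed
#' atom table, saved at a constant time step (1 ps by default, the
#' usual coordinate-saving interval for short explicit-solvent runs).
#'
#' @param xyz numeric matrix with one row per frame and `3 * n_atoms`
#'   columns (x1, y1, z1, x2, ...), or a list of n x 3 matrices.
#' @param atoms atom table (data frame with at least `elety`, `resid`,
#'   `resno`).
#' @param time_step time between frames in ps (default 1).
#' @param time optional explicit time vector in ps (strictly
#'   increasing).
#' @return A `trajectory` object.
#' @export
trajectory <- function(xyz, atoms, time_step = 1, time = NULL) {
  if (is.list(xyz) && !is.matrix(xyz))
    xyz <- do.call(rbind, lapply(xyz, function(m) as.numeric(t(m))))
  n_at <- ncol(xyz) / 3
  stopifnot(ncol(xyz) %% 3 == 0, nrow(atoms) == n_at)
  if (is.null(time)) time <- (seq_len(nrow(xyz)) - 1) * time_step
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(xyz = xyz, atoms = atoms, time = time),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, %g-%g ps\n",
              nrow(x$xyz), ncol(x$xyz) / 3, min(x$time), max(x$time)))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

frame_coords <- function(traj, i)
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)

#' Read a multi-model PDB file as a trajectory
#'
#' @param file path to a (multi-model) PDB file.
#' @param time_step frame spacing in ps (default 1).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(file, time_step = 1) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  trajectory(unclass(xyz), pdb$atom, time_step = time_step)
}

# Atom-table row indices for a selection: "backbone", "all", a logical
# vector, or an integer index vector.
selection_indices <- function(atoms, selection) {
  if (is.character(selection)) {
    if (selection == "backbone")
      return(which(atoms$elety %in% c("N", "CA", "C", "O")))
    if (selection == "all") return(seq_len(nrow(atoms)))
    stop("unknown selection: ", selection)
  }
  if (is.logical(selection)) return(which(selection))
  as.integer(selection)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `frame` onto `reference` over the selected atoms.
#'
#' @param reference,frame n x 3 coordinate matrices.
#' @param selection row indices used for the fit (default all rows).
#' @return List with `rotation` (3 x 3, det = +1), `translation`
#'   (length 3; the fitted frame is `frame %*% t(R) + translation`),
#'   and `rmsd` over the selection after the fit.
#' @export
superpose <- function(reference, frame, selection = NULL) {
  A <- as.matrix(reference); B <- as.matrix(frame)
  if (is.null(selection)) selection <- seq_len(nrow(A))
  a <- A[selection, , drop = FALSE]
  b <- B[selection, , drop = FALSE]
  if (nrow(a) < 3) stop("need at least 3 atoms for superposition")
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(b, 2, cb), sweep(a, 2, ca))
  if (qr(H)$rank < 2) stop("rank-deficient selection: cannot superpose")
  sv <- svd(H)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)
  tr <- ca - as.numeric(R %*% cb)
  fitted <- sweep(b %*% t(R), 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - a)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

new_distance_series <- function(values, label, time = NULL) {
  structure(list(values = values, mean = mean(values),
                 sd = stats::sd(values), label = label, time = time),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean = %.3f, sd = %.3f\n",
              x$label, length(x$values), x$mean,
              ifelse(is.na(x$sd), 0, x$sd)))
  invisible(x)
}

#' Conformational drift of a trajectory
#'
#' Per-frame RMSD (after rigid superposition on the selection) with
#' respect to a reference, plus the ordinary least-squares regression
#' line of the drift against time.
#'
#' @param traj a [trajectory()].
#' @param reference reference coordinates (n x 3) or `NULL` for the
#'   first frame.
#' @param selection atom selection for both fit and RMSD (default
#'   `"backbone"`).
#' @return A `distance_series` of RMSD values (Angstrom) with
#'   attributes `slope` (Angstrom/ns) and `intercept` (Angstrom).
#' @export
drift_series <- function(traj, reference = NULL, selection = "backbone") {
  if (n_frames(traj) == 0) stop("empty trajectory")
  sel <- selection_indices(traj$atoms, selection)
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  rmsd <- vapply(seq_len(n_frames(traj)), function(i)
    superpose(reference, frame_coords(traj, i), sel)$rmsd, 0)
  out <- new_distance_series(rmsd, "conformational drift",
                             time = traj$time)
  t_ns <- traj$time / 1000
  fit <- stats::lm(rmsd ~ t_ns)
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  attr(out, "slope_ci95") <- suppressWarnings(
    unname(stats::confint(fit)[2, ]))
  out
}

#' Named residue regions
#'
#' The default regions are the three loops decorating the SH3 fold:
#' RT loop (residues 8-23), n-src loop (30-37) and distal hairpin
#' (41-47). Additional named ranges can be supplied.
#'
#' @param ... further named regions, each an integer vector of residue
#'   numbers.
#' @return Named list of residue-number vectors.
#' @export
default_regions <- function(...) {
  extra <- list(...)
  base <- list(rt_loop = 8:23, n_src_loop = 30:37, distal_hairpin = 41:47)
  c(base, extra)
}

#' Distance between region centers of mass along a trajectory
#'
#' Per-frame Euclidean distance between the (by default unweighted)
#' centroids of two named regions' selected atoms.
#'
#' @param traj a [trajectory()].
#' @param regions named list of residue-number vectors (see
#'   [default_regions()]).
#' @param pair character vector of two region names.
#' @param selection atom-type selection inside each region (default
#'   `"backbone"`).
#' @param mass_weighted weight centroids by rough atomic masses
#'   inferred from the element (default FALSE).
#' @return A `distance_series`.
#' @export
com_distance_series <- function(traj, regions, pair,
                                selection = "backbone",
                                mass_weighted = FALSE) {
  if (!all(pair %in% names(regions)))
    stop("unknown region name: ",
         paste(setdiff(pair, names(regions)), collapse = ", "))
  sel <- selection_indices(traj$atoms, selection)
  ra <- intersect(sel, which(traj$atoms$resno %in% regions[[pair[1]]]))
  rb <- intersect(sel, which(traj$atoms$resno %in% regions[[pair[2]]]))
  if (length(ra) == 0 || length(rb) == 0)
    stop("empty region selection")
  w <- function(idx) {
    if (!mass_weighted) return(rep(1, length(idx)))
    el <- substr(gsub("^[0-9]", "", traj$atoms$elety[idx]), 1, 1)
    m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
    out <- m[el]; out[is.na(out)] <- 12
    unname(out)
  }
  wa <- w(ra); wb <- w(rb)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    ca <- colSums(xyz[ra, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(xyz[rb, , drop = FALSE] * wb) / sum(wb)
    sqrt(sum((ca - cb)^2))
  }, 0)
  new_distance_series(vals, paste(pair, collapse = "/"),
                      time = traj$time)
}

#' Per-frame distances for specific atom pairs
#'
#' @param traj a [trajectory()].
#' @param atom_pairs list of pairs; each pair is a list of two atom
#'   specs, each a `c(resno, elety)`-style list
#'   `list(resno = , elety = )` or a string `"resno:elety"` (e.g.
#'   `"50:CG2"`).
#' @return List of `distance_series`, one per pair.
#' @export
pair_distance_series <- function(traj, atom_pairs) {
  resolve <- function(spec) {
    if (is.character(spec)) {
      parts <- strsplit(spec, ":")[[1]]
      spec <- list(resno = as.integer(parts[1]), elety = parts[2])
    }
    hit <- which(traj$atoms$resno == spec$resno &
                 traj$atoms$elety == spec$elety)
    if (length(hit) == 0)
      stop("atom not found: residue ", spec$resno, " atom ", spec$elety)
    hit[1]
  }
  lapply(atom_pairs, function(pr) {
    i <- resolve(pr[[1]]); j <- resolve(pr[[2]])
    vals <- sqrt(rowSums((traj$xyz[, (3 * i - 2):(3 * i), drop = FALSE] -
                          traj$xyz[, (3 * j - 2):(3 * j), drop = FALSE])^2))
    lab <- paste0(traj$atoms$resid[i], traj$atoms$resno[i], "-",
                  traj$atoms$elety[i], "/", traj$atoms$resid[j],
                  traj$atoms$resno[j], "-", traj$atoms$elety[j])
    new_distance_series(vals, lab, time = traj$time)
  })
}

#' Hydrophobic-core monitor pairs
#'
#' The side-chain carbon pairs monitored around the core of the
#' nephrocystin SH3 domain: V50-CG2/V29-CG1, L55-CD1/V29-CG2,
#' Y5-CD1/V29-CG2, A40-CB/L27-CD2 and V29-CG2/L27-CD2.
#'
#' @return List of atom pairs for [pair_distance_series()].
#' @export
hydrophobic_core_pairs <- function() {
  list(list("50:CG2", "29:CG1"),
       list("55:CD1", "29:CG2"),
       list("5:CD1", "29:CG2"),
       list("40:CB", "27:CD2"),
       list("29:CG2", "27:CD2"))
}

#' Contact probability from a distance series
#'
#' Probability that the monitored distance is below `threshold`. The
#' default Gaussian model uses the series mean and standard deviation,
#' `Phi((threshold - mean) / sd)`; the empirical model counts frames.
#'
#' @param series a `distance_series`.
#' @param threshold contact threshold in Angstrom (default 7.5).
#' @param model `"gaussian"` or `"empirical"`.
#' @return Probability in `[0, 1]`.
#' @export
contact_probability <- function(series, threshold = 7.5,
                                model = c("gaussian", "empirical")) {
  model <- match.arg(model)
  if (model == "empirical")
    return(mean(series$values < threshold))
  s <- series$sd
  if (is.na(s) || s == 0) {
    warning("zero-variance series under the gaussian model; ",
            "returning 0/1 by mean vs threshold")
    return(as.numeric(series$mean < threshold))
  }
  stats::pnorm((threshold - series$mean) / s)
}

#' Hydrogen-bond distance monitoring
#'
#' Tracks the donor-hydrogen / acceptor distance along a trajectory;
#' the bond is considered formed when the MEAN distance is strictly
#' below the cutoff (2.5 Angstrom by default), not frame by frame.
#'
#' @param traj a [trajectory()].
#' @param donor_hydrogen,acceptor atom specs as in
#'   [pair_distance_series()].
#' @param cutoff mean-distance cutoff in Angstrom.
#' @return The `distance_series` with attribute `formed` (logical).
#' @export
hbond_series <- function(traj, donor_hydrogen, acceptor, cutoff = 2.5) {
  s <- pair_distance_series(traj, list(list(donor_hydrogen, acceptor)))[[1]]
  attr(s, "formed") <- s$mean < cutoff
  s
}
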