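#' Fit the main axis of a beta barrel
#'
#' Finds the line maximising the minimum distance to a backbone point
#' cloud — the axis of the largest cylinder containing no backbone atom
#' — with the on-axis point constrained to a ball of radius half the
#' cloud's gyration radius around the centroid (this keeps the axis
#' inside the barrel rather than escaping to infinity).
#'
#' The max-min objective is optimised as an annealed softmin (the
#' smooth lower envelope `-(1/beta) log sum exp(-beta d_i)` with `beta`
#' increased over rounds), multistarted from the three principal
#' inertia axes plus seeded random perturbations; the reported radius
#' is the exact minimum point-to-line distance at the best optimum, so
#' it is always feasible.
#'
#' @param backbone n x 3 coordinate matrix (Angstrom), n >= 10,
#'   non-coplanar.
#' @param n_starts number of optimisation starts (default 20).
#' @param tol convergence tolerance passed to the optimiser.
#' @param seed seed for the start perturbations (default 1).
#' @return An `axis` object: list with `point` (on-axis point),
#'   `direction` (unit vector), `radius` (maximal empty-cylinder
#'   radius, Angstrom).
#' @export
main_axis <- function(backbone, n_starts = 20L, tol = 1e-6, seed = 1L) {
  x <- as.matrix(backbone)
  if (nrow(x) < 10) stop("need at least 10 backbone points")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  if (ev$values[3] < 1e-8 * ev$values[1])
    stop("degenerate (coplanar) point cloud")
  rg <- sqrt(mean(rowSums(xc^2)))
  ball <- rg / 2

  dir_from_angles <- function(th, ph)
    c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  angles_from_dir <- function(d) c(acos(max(-1, min(1, d[3]))),
                                   atan2(d[2], d[1]))

  dists <- function(p, d) {
    rel <- sweep(x, 2, p)
    proj <- rel %*% d
    sqrt(pmax(0, rowSums(rel^2) - proj^2))
  }
  clamp_offset <- function(o) {
    nn <- sqrt(sum(o^2))
    if (nn > ball) o * (ball / nn) else o
  }
  obj <- function(par, beta) {
    d <- dir_from_angles(par[1], par[2])
    p <- ctr + clamp_offset(par[3:5])
    dd <- dists(p, d)
    m <- min(dd)
    # softmin, shifted for numerical stability
    m - log(sum(exp(-beta * (dd - m)))) / beta
  }

  starts <- list()
  for (k in 1:3)
    starts[[k]] <- c(angles_from_dir(ev$vectors[, k]), 0, 0, 0)
  extra <- n_starts - length(starts)
  if (extra > 0) {
    pert <- with_seed(seed, matrix(stats::rnorm(extra * 5), extra, 5))
    for (k in seq_len(extra)) {
      base <- starts[[1 + (k - 1) %% 3]]
      starts[[3 + k]] <- base + pert[k, ] * c(0.4, 0.4, rep(ball / 3, 3))
    }
  }

  best <- NULL
  for (s in starts) {
    par <- s
    for (beta in c(1, 4, 16, 64, 256)) {
      fit <- stats::optim(par, obj, beta = beta,
                          method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = 600,
                                         reltol = tol))
      par <- fit$par
    }
    d <- dir_from_angles(par[1], par[2])
    p <- ctr + clamp_offset(par[3:5])
    r <- min(dists(p, d))
    if (is.null(best) || r > best$radius)
      best <- list(point = p, direction = d, radius = r)
  }
  # project the point onto the plane through the centroid for a
  # canonical representation
  shift <- sum((ctr - best$point) * best$direction)
  best$point <- best$point + shift * best$direction
  structure(best, class = "barrel_axis")
}

#' Largest empty circle among 2-D points
#'
#' Exact solver: the largest circle containing no input point, with
#' center constrained to the convex hull of the points (the constraint
#' removes the unbounded outside solution). The optimum is attained at
#' a Voronoi vertex (a circumcenter of a point triple) inside the hull
#' or where a Voronoi edge (a pairwise perpendicular bisector) crosses
#' the hull boundary; all such candidates are enumerated and the best
#' kept.
#'
#' @param points2d n x 2 coordinate matrix, n >= 3, non-collinear.
#' @param hull_constraint constrain the center to the convex hull
#'   (default TRUE; FALSE is only meaningful with few points and is
#'   rejected if the problem is unbounded).
#' @return List with `center` (length-2) and `radius`.
#' @export
largest_empty_circle <- function(points2d, hull_constraint = TRUE) {
  pts <- as.matrix(points2d)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  if (n > 300) stop("too many points for exact enumeration (n > 300)")
  hull <- grDevices::chull(pts)
  if (length(hull) < 3) stop("collinear points: no bounded interior")
  if (!hull_constraint)
    stop("unconstrained largest empty circle is unbounded")
  hp <- pts[hull, , drop = FALSE]

  inside_hull <- function(cand) {
    # hull vertices from chull are clockwise; test sign consistency
    h <- nrow(hp)
    ok <- rep(TRUE, nrow(cand))
    for (e in seq_len(h)) {
      a <- hp[e, ]; b <- hp[if (e == h) 1 else e + 1, ]
      cr <- (b[1] - a[1]) * (cand[, 2] - a[2]) -
            (b[2] - a[2]) * (cand[, 1] - a[1])
      ok <- ok & (cr <= 1e-9)
    }
    ok
  }

  cands <- list(matrix(colMeans(hp), 1, 2))

  # circumcenters of all point triples (Voronoi vertex candidates)
  if (n >= 3) {
    tri <- utils::combn(n, 3)
    a <- pts[tri[1, ], , drop = FALSE]
    b <- pts[tri[2, ], , drop = FALSE]
    c2 <- pts[tri[3, ], , drop = FALSE]
    d <- 2 * ((a[, 1] - c2[, 1]) * (b[, 2] - c2[, 2]) -
              (b[, 1] - c2[, 1]) * (a[, 2] - c2[, 2]))
    ok <- abs(d) > 1e-12
    if (any(ok)) {
      a2 <- rowSums(a^2); b2 <- rowSums(b^2); c22 <- rowSums(c2^2)
      ux <- (a2 * (b[, 2] - c2[, 2]) + b2 * (c2[, 2] - a[, 2]) +
             c22 * (a[, 2] - b[, 2])) / d
      uy <- -(a2 * (b[, 1] - c2[, 1]) + b2 * (c2[, 1] - a[, 1]) +
              c22 * (a[, 1] - b[, 1])) / d
      cands[[length(cands) + 1]] <- cbind(ux[ok], uy[ok])
    }
  }

  # pairwise bisector crossings with each hull edge
  pr <- utils::combn(n, 2)
  pa <- pts[pr[1, ], , drop = FALSE]
  pb <- pts[pr[2, ], , drop = FALSE]
  mid <- (pa + pb) / 2
  dir <- cbind(-(pb[, 2] - pa[, 2]), pb[, 1] - pa[, 1])  # bisector dir
  h <- nrow(hp)
  for (e in seq_len(h)) {
    q <- hp[e, ]; r <- hp[if (e == h) 1 else e + 1, ] - q
    # solve mid + t*dir = q + s*r for s in [0,1]
    det <- dir[, 1] * (-r[2]) - dir[, 2] * (-r[1])
    ok <- abs(det) > 1e-12
    rhs1 <- q[1] - mid[, 1]; rhs2 <- q[2] - mid[, 2]
    s <- (dir[, 1] * rhs2 - dir[, 2] * rhs1) / det
    good <- ok & s >= -1e-9 & s <= 1 + 1e-9
    if (any(good))
      cands[[length(cands) + 1]] <-
        cbind(q[1] + s[good] * r[1], q[2] + s[good] * r[2])
  }

  cand <- do.call(rbind, cands)
  cand <- cand[inside_hull(cand), , drop = FALSE]
  if (nrow(cand) == 0) cand <- matrix(colMeans(hp), 1, 2)

  # nearest input point for each candidate, chunked
  best_r <- -Inf; best_c <- NULL
  chunk <- 20000L
  for (s0 in seq(1, nrow(cand), by = chunk)) {
    s1 <- min(s0 + chunk - 1, nrow(cand))
    cc <- cand[s0:s1, , drop = FALSE]
    dd <- sqrt(outer(cc[, 1], pts[, 1], `-`)^2 +
               outer(cc[, 2], pts[, 2], `-`)^2)
    mind <- apply(dd, 1, min)
    i <- which.max(mind)
    if (mind[i] > best_r) { best_r <- mind[i]; best_c <- cc[i, ] }
  }
  list(center = as.numeric(best_c), radius = best_r)
}

#' Slab-by-slab cavity profile of a barrel
#'
#' Moves a slab of width `slab_width` along the fitted main axis in
#' steps of `step`; within each slab the member atoms (axial coordinate
#' in `[c - w/2, c + w/2)`) are projected onto the plane normal to the
#' axis and the largest empty circle with center inside their convex
#' hull gives the local cavity radius (per-slab cylinders stay parallel
#' to the main axis). Slabs with fewer than `min_atoms` members (or
#' degenerate projections) are marked empty. The axial origin is the
#' midpoint of the occupied axis interval.
#'
#' @param backbone n x 3 coordinate matrix.
#' @param axis a `barrel_axis` from [main_axis()].
#' @param slab_width slab width in Angstrom (default 2).
#' @param step slab-center step in Angstrom (default 0.5).
#' @param min_atoms minimum atoms for a non-empty slab (default 3).
#' @return A `slab_profile`: data frame with `center`, `radius` (NA for
#'   empty slabs), `n_atoms`; attributes `slab_width`, `step`,
#'   `length` (distance between extreme non-empty slab centers).
#' @export
slab_profile <- function(backbone, axis, slab_width = 2, step = 0.5,
                         min_atoms = 3L) {
  x <- as.matrix(backbone)
  d <- axis$direction
  rel <- sweep(x, 2, axis$point)
  t_ax <- as.numeric(rel %*% d)
  t_ax <- t_ax - (min(t_ax) + max(t_ax)) / 2
  # orthonormal in-plane basis
  e1 <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  p2 <- cbind(rel %*% e1, rel %*% e2)

  centers <- seq(floor(min(t_ax) / step) * step,
                 ceiling(max(t_ax) / step) * step, by = step)
  radii <- rep(NA_real_, length(centers))
  n_atoms <- integer(length(centers))
  for (i in seq_along(centers)) {
    inslab <- t_ax >= centers[i] - slab_width / 2 &
              t_ax < centers[i] + slab_width / 2
    n_atoms[i] <- sum(inslab)
    if (n_atoms[i] < min_atoms) next
    lec <- tryCatch(largest_empty_circle(p2[inslab, , drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(lec)) radii[i] <- lec$radius
  }
  occ <- which(!is.na(radii))
  if (length(occ) == 0) stop("no non-empty slab along the axis")
  structure(data.frame(center = centers, radius = radii,
                       n_atoms = n_atoms),
            class = c("slab_profile", "data.frame"),
            slab_width = slab_width, step = step,
            length = centers[max(occ)] - centers[min(occ)])
}

#' Barrel length from a slab profile
#'
#' The position difference between the two extreme non-empty slabs.
#'
#' @param profile a [slab_profile()].
#' @return Length in Angstrom (0 for a single non-empty slab).
#' @export
barrel_length <- function(profile) {
  occ <- which(!is.na(profile$radius))
  if (length(occ) == 0) stop("all slabs are empty")
  profile$center[max(occ)] - profile$center[min(occ)]
}
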