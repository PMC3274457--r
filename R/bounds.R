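#' Baseline specification for the distance-bound matrix
#'
#' The baseline supplies the bounds every pair of restrained nodes
#' carries before the experimental restraints are intersected in:
#'
#' * `"restraints_only"`: every pair starts at `[0, u_max]`.
#' * `"chain_model"`: sequence-adjacent nodes additionally get the
#'   sequential upper bound `u`, so triangle smoothing yields
#'   `u_ij = u * |i - j|` (capped at `u_max`) — the chain model used to
#'   relate unique information to contact order.
#' * `"topology"`: node pairs within the same or sequentially adjacent
#'   residues get near-exact bounds (width 0.02 A) around their
#'   distance in a reference structure, emulating the geometry fixed by
#'   the covalent structure.
#'
#' @param mode one of `"restraints_only"`, `"chain_model"`, `"topology"`.
#' @param u sequential upper bound in Angstrom (chain model), default 5.
#' @param u_max default upper bound for otherwise unbounded pairs
#'   (default 100 A, larger than any SH3 dimension, so every pair
#'   uncertainty is finite).
#' @param structure a `bio3d` pdb object (required for `"topology"`).
#' @return A list of class `baseline_spec`.
#' @export
baseline_spec <- function(mode = c("restraints_only", "chain_model",
                                   "topology"),
                          u = 5, u_max = 100, structure = NULL) {
  mode <- match.arg(mode)
  stopifnot(u > 0, u_max >= u)
  if (mode == "topology" && is.null(structure))
    stop("topology baseline requires a reference structure")
  structure(list(mode = mode, u = u, u_max = u_max, structure = structure),
            class = "baseline_spec")
}

# One node per distinct (resid, name) selection; pseudoatom wildcards
# collapse to a single node. Nodes sorted by residue then atom name.
node_table <- function(set) {
  sel <- unique(rbind(
    data.frame(resid = set$resid_a, name = set$name_a,
               stringsAsFactors = FALSE),
    data.frame(resid = set$resid_b, name = set$name_b,
               stringsAsFactors = FALSE)))
  sel <- sel[order(sel$resid, sel$name), , drop = FALSE]
  rownames(sel) <- NULL
  sel$node_id <- seq_len(nrow(sel))
  sel
}

#' Node universe for a linear chain
#'
#' One node per residue 1..n (atom name `H`), for use as the `nodes`
#' argument of [build_bounds()], [unique_information()] or
#' [rank_restraints()] under the chain-model baseline.
#'
#' @param n chain length.
#' @param name atom name for every node (default `"H"`).
#' @return A node table.
#' @export
chain_nodes <- function(n, name = "H") {
  data.frame(resid = seq_len(n), name = name, node_id = seq_len(n),
             stringsAsFactors = FALSE)
}

node_index <- function(nodes, resid, name) {
  key <- paste(nodes$resid, nodes$name)
  match(paste(resid, name), key)
}

#' Build the inter-node distance-bound matrix
#'
#' Constructs symmetric lower/upper bound matrices over the node
#' universe of `nodes` (by default the distinct selections of `set`),
#' taking for each pair the tightest intersection of all applicable
#' sources: the baseline and every restraint on the pair. Pairs with no
#' source get `[0, u_max]`.
#'
#' @param set a [restraint_set()].
#' @param baseline a [baseline_spec()].
#' @param nodes optional node table fixing the node universe (use the
#'   full set's nodes when computing leave-one-out uncertainties so the
#'   node count stays constant).
#' @return A `bounds_matrix`: list with `lower`, `upper` (n x n
#'   matrices), `nodes`, and `smoothed = FALSE`.
#' @export
build_bounds <- function(set, baseline = baseline_spec(), nodes = NULL) {
  if (is.null(nodes)) nodes <- node_table(set)
  n <- nrow(nodes)
  if (n == 0) stop("empty node universe")
  L <- matrix(0, n, n)
  U <- matrix(baseline$u_max, n, n)
  diag(U) <- 0

  if (baseline$mode == "chain_model" && n > 1) {
    for (i in seq_len(n - 1)) {
      U[i, i + 1] <- min(U[i, i + 1], baseline$u)
      U[i + 1, i] <- U[i, i + 1]
    }
  } else if (baseline$mode == "topology") {
    xyz <- resolve_nodes_xyz(nodes, baseline$structure)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(nodes$resid[i] - nodes$resid[j]) <= 1 &&
            !anyNA(xyz[c(i, j), ])) {
          d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
          L[i, j] <- L[j, i] <- max(L[i, j], d - 0.01)
          U[i, j] <- U[j, i] <- min(U[i, j], d + 0.01)
        }
      }
    }
  }

  ia <- node_index(nodes, set$resid_a, set$name_a)
  ib <- node_index(nodes, set$resid_b, set$name_b)
  if (anyNA(ia) || anyNA(ib))
    stop("restraint selection not resolvable in the node universe")
  for (r in seq_len(nrow(set))) {
    i <- ia[r]; j <- ib[r]
    L[i, j] <- L[j, i] <- max(L[i, j], set$lower[r])
    U[i, j] <- U[j, i] <- min(U[i, j], set$upper[r])
  }
  bad <- which(L > U + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    p <- bad[1, ]
    stop(sprintf("inconsistent bounds after intersection for pair (%s %s, %s %s): lower %.3f > upper %.3f",
                 nodes$resid[p[1]], nodes$name[p[1]], nodes$resid[p[2]],
                 nodes$name[p[2]], L[p[1], p[2]], U[p[1], p[2]]))
  }
  structure(list(lower = L, upper = U, nodes = nodes, smoothed = FALSE),
            class = "bounds_matrix")
}

# Coordinates for each node in a structure (bio3d pdb or fixture list):
# exact atom-name match, or the centroid of the atoms matching a
# trailing-# pseudoatom wildcard.
resolve_nodes_xyz <- function(nodes, pdb) {
  at <- structure_atoms(pdb)
  xyz <- matrix(NA_real_, nrow(nodes), 3)
  for (i in seq_len(nrow(nodes))) {
    nm <- nodes$name[i]
    rows <- which(at$resno == nodes$resid[i])
    if (length(rows) == 0) next
    if (grepl("#$", nm)) {
      stem <- sub("#$", "", nm)
      hit <- rows[startsWith(at$elety[rows], stem)]
    } else {
      hit <- rows[at$elety[rows] == nm]
    }
    if (length(hit) > 0)
      xyz[i, ] <- colMeans(cbind(at$x[hit], at$y[hit], at$z[hit]))
  }
  xyz
}

#' Smooth a bound matrix with triangle inequalities
#'
#' Upper bounds are replaced by all-pairs shortest paths over the
#' upper-bound graph (Floyd-Warshall); lower bounds are raised by
#' iterating the inverse triangle inequality
#' `l_ij >= max_k(l_ik - u_kj, l_kj - u_ik)` to a fixed point (at most
#' `max_sweeps` sweeps). Smoothing is idempotent and never loosens a
#' bound. Tetrangle (4-point) smoothing is not performed.
#'
#' @param bm a `bounds_matrix` from [build_bounds()].
#' @param max_sweeps maximum lower-bound sweeps (default 10).
#' @return The smoothed `bounds_matrix` (`smoothed = TRUE`).
#' @export
smooth_bounds <- function(bm, max_sweeps = 10L) {
  stopifnot(inherits(bm, "bounds_matrix"))
  res <- smooth_bounds_cpp(bm$lower, bm$upper, as.integer(max_sweeps))
  L <- res$lower
  U <- res$upper
  bad <- which(L > U + 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    p <- bad[1, ]
    stop(sprintf("geometrically inconsistent bounds for pair (%s %s, %s %s): smoothed lower %.3f > upper %.3f",
                 bm$nodes$resid[p[1]], bm$nodes$name[p[1]],
                 bm$nodes$resid[p[2]], bm$nodes$name[p[2]],
                 L[p[1], p[2]], U[p[1], p[2]]))
  }
  structure(list(lower = L, upper = U, nodes = bm$nodes, smoothed = TRUE),
            class = "bounds_matrix")
}

#' Exhaustive path-enumeration smoothing oracle
#'
#' Independent reference for [smooth_bounds()] on tiny systems: the
#' smoothed upper bound of each pair is computed by enumerating all
#' simple paths (branch-and-bound), and lower bounds by iterating the
#' inverse triangle inequality in plain R until convergence. Intended
#' for tests only.
#'
#' @param bm a `bounds_matrix` with at most 10 nodes.
#' @return The smoothed `bounds_matrix`.
#' @export
path_oracle <- function(bm) {
  n <- nrow(bm$upper)
  if (n > 10) stop("path_oracle refuses n > 10 (combinatorial blow-up)")
  U0 <- bm$upper
  U <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      best <- U0[i, j]
      # DFS over simple paths i -> j, pruning branches >= best
      dfs <- function(v, cost, visited) {
        if (cost >= best) return(invisible())
        if (v == j) { best <<- cost; return(invisible()) }
        for (w in seq_len(n)) {
          if (!visited[w]) {
            visited[w] <- TRUE
            dfs(w, cost + U0[v, w], visited)
            visited[w] <- FALSE
          }
        }
      }
      visited <- rep(FALSE, n)
      visited[i] <- TRUE
      dfs(i, 0, visited)
      U[i, j] <- best
    }
  }
  L <- bm$lower
  repeat {
    changed <- FALSE
    for (k in seq_len(n)) {
      cand <- outer(L[, k], U[k, ], `-`)
      cand <- pmax(cand, t(cand))
      diag(cand) <- 0
      upd <- cand > L + 1e-15
      if (any(upd)) {
        L[upd] <- cand[upd]
        L <- pmax(L, t(L))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(lower = L, upper = U, nodes = bm$nodes, smoothed = TRUE),
            class = "bounds_matrix")
}

# Upper-triangle index pairs of an n x n matrix as a 2-column matrix.
pair_indices <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Export a bounds matrix as a tidy table
#'
#' @param bm a `bounds_matrix`.
#' @return Data frame with columns `i`, `j`, `lower`, `upper` over all
#'   unordered node pairs.
#' @export
bounds_as_table <- function(bm) {
  idx <- pair_indices(nrow(bm$upper))
  data.frame(i = idx[, 1], j = idx[, 2],
             lower = bm$lower[idx], upper = bm$upper[idx])
}
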