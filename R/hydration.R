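# Template donor-hydrogen and acceptor atoms for the 20 standard amino
# acids. Backbone: amide H is a donor hydrogen (absent in proline),
# carbonyl O (and OXT) is an acceptor. Side chains: N/O atoms with lone
# pairs as acceptors, their attached hydrogens as donor hydrogens.
# Sulfur is not counted.
.sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
  GLN = c("OE1"), SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1", "NE2"))

.sidechain_donor_h <- list(
  SER = c("HG"), THR = c("HG1"), TYR = c("HH"),
  ASN = c("HD21", "HD22"), GLN = c("HE21", "HE22"),
  LYS = c("HZ1", "HZ2", "HZ3"),
  ARG = c("HE", "HH11", "HH12", "HH21", "HH22"),
  TRP = c("HE1"), HIS = c("HD1", "HE2"))

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                  "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                  "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Flag hydrogen-bond donor hydrogens and acceptors
#'
#' Template-driven per-atom flags for the 20 standard amino acids:
#' backbone amide hydrogens (except proline) and side-chain hydroxyl,
#' amide, amine and guanidinium hydrogens are donor hydrogens; backbone
#' carbonyl oxygens and side-chain N/O atoms with lone pairs are
#' acceptors. Non-standard residues (including waters) are skipped with
#' a warning.
#'
#' @param structure a `bio3d` pdb object or a fixture structure (see
#'   [contact_map()] for accepted forms).
#' @return A `donor_acceptor_table`: the atom table with logical
#'   columns `donor_h` and `acceptor` and the atom row index `atom_idx`.
#' @export
donors_acceptors <- function(structure) {
  at <- structure_atoms(structure)
  if (nrow(at) == 0) stop("empty structure")
  prot <- at$resid %in% .standard_aa
  unknown <- setdiff(unique(at$resid[!prot]),
                     c("HOH", "WAT", "SOL", "TIP3"))
  if (length(unknown) > 0)
    warning("skipping non-standard residue(s): ",
            paste(unknown, collapse = ", "))
  donor_h <- acceptor <- rep(FALSE, nrow(at))
  for (i in which(prot)) {
    rn <- at$resid[i]; nm <- at$elety[i]
    if (nm %in% c("O", "OXT")) acceptor[i] <- TRUE
    if (nm %in% c("H", "HN") && rn != "PRO") donor_h[i] <- TRUE
    if (nm %in% .sidechain_acceptors[[rn]]) acceptor[i] <- TRUE
    if (nm %in% .sidechain_donor_h[[rn]]) donor_h[i] <- TRUE
  }
  out <- at
  out$donor_h <- donor_h
  out$acceptor <- acceptor
  out$atom_idx <- seq_len(nrow(at))
  structure(out, class = c("donor_acceptor_table", "data.frame"))
}

water_residue_names <- c("HOH", "WAT", "SOL", "TIP3")

#' Water bridges in a single frame
#'
#' A water molecule bridges protein residues p and q (p != q) when one
#' of its atoms lies strictly within `cutoff` of a flagged
#' donor/acceptor atom of p and another of its atoms lies strictly
#' within `cutoff` of a flagged atom of q.
#'
#' @param frame_xyz n x 3 coordinates of the frame (full atom table).
#' @param atoms the atom table (must include waters, residue name
#'   HOH/WAT/SOL).
#' @param table a [donors_acceptors()] table for the same atom table.
#' @param cutoff distance cutoff in Angstrom (default 2.5, strict `<`).
#' @return Two-column matrix of bridged residue-number pairs (p < q);
#'   zero rows when no water bridges anything.
#' @export
frame_bridges <- function(frame_xyz, atoms, table, cutoff = 2.5) {
  flag <- which(table$donor_h | table$acceptor)
  wat <- which(atoms$resid %in% water_residue_names)
  if (length(wat) == 0 || length(flag) == 0)
    return(matrix(integer(0), 0, 2))
  fx <- frame_xyz[flag, , drop = FALSE]
  fres <- atoms$resno[flag]
  out <- list()
  for (w in split(wat, atoms$resno[wat])) {
    wx <- frame_xyz[w, , drop = FALSE]
    dd <- sqrt(outer(wx[, 1], fx[, 1], `-`)^2 +
               outer(wx[, 2], fx[, 2], `-`)^2 +
               outer(wx[, 3], fx[, 3], `-`)^2)
    hit <- which(dd < cutoff, arr.ind = TRUE)
    if (nrow(hit) < 2) next
    # pairs of DIFFERENT water atoms touching DIFFERENT residues
    res_by_atom <- split(fres[hit[, 2]], hit[, 1])
    if (length(res_by_atom) < 2) next
    ats <- names(res_by_atom)
    for (a in seq_along(ats)) {
      for (b in seq_len(a - 1)) {
        for (p in res_by_atom[[a]]) {
          for (q in res_by_atom[[b]]) {
            if (p != q)
              out[[length(out) + 1]] <- c(min(p, q), max(p, q))
          }
        }
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 2))
  unique(do.call(rbind, out))
}

#' Persistent water-bridge network of a trajectory
#'
#' For every residue pair, the occupancy is the fraction of frames in
#' which ANY water bridges the pair. Pairs with occupancy strictly
#' above `edge_occ` (default 40%) become network edges; edges above
#' `thick_occ` (default 60%) are flagged thick. Hubs are the
#' maximal-degree nodes of each connected component (ties broken by
#' lower residue number).
#'
#' @param traj a [trajectory()] whose atom table includes waters.
#' @param table a [donors_acceptors()] table; computed from the atom
#'   table when `NULL`.
#' @param cutoff hydrogen-bond distance cutoff in Angstrom.
#' @param edge_occ,thick_occ occupancy thresholds (fractions).
#' @return A `bridge_network`: list with `edges` (data frame `res_a`,
#'   `res_b`, `occupancy`, `thick`), `hubs` (residue numbers), and the
#'   full `occupancy` table before thresholding.
#' @export
bridge_network <- function(traj, table = NULL, cutoff = 2.5,
                           edge_occ = 0.4, thick_occ = 0.6) {
  nf <- n_frames(traj)
  if (nf == 0) stop("empty trajectory")
  if (nf < 10)
    warning("fewer than 10 frames: occupancies are coarse")
  if (is.null(table))
    table <- suppressWarnings(donors_acceptors(list(atoms = traj$atoms)))
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    br <- frame_bridges(frame_coords(traj, i), traj$atoms, table, cutoff)
    if (nrow(br) == 0) next
    for (r in seq_len(nrow(br))) {
      key <- paste(br[r, 1], br[r, 2])
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    occ <- data.frame(res_a = integer(0), res_b = integer(0),
                      occupancy = numeric(0))
  } else {
    kv <- do.call(rbind, strsplit(keys, " "))
    occ <- data.frame(res_a = as.integer(kv[, 1]),
                      res_b = as.integer(kv[, 2]),
                      occupancy = vapply(keys, function(k) counts[[k]],
                                         0) / nf)
    occ <- occ[order(occ$res_a, occ$res_b), , drop = FALSE]
    rownames(occ) <- NULL
  }
  edges <- occ[occ$occupancy > edge_occ, , drop = FALSE]
  edges$thick <- edges$occupancy > thick_occ
  rownames(edges) <- NULL

  hubs <- integer(0)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$res_a),
                 to = as.character(edges$res_b)), directed = FALSE)
    comp <- igraph::components(g)
    deg <- igraph::degree(g)
    verts <- as.integer(igraph::V(g)$name)
    for (cc in seq_len(comp$no)) {
      members <- which(comp$membership == cc)
      dmax <- max(deg[members])
      cand <- verts[members[deg[members] == dmax]]
      hubs <- c(hubs, min(cand))
    }
    hubs <- sort(hubs)
  }
  structure(list(edges = edges, hubs = hubs, occupancy = occ,
                 n_frames = nf, edge_occ = edge_occ,
                 thick_occ = thick_occ),
            class = "bridge_network")
}

#' @export
print.bridge_network <- function(x, ...) {
  cat(sprintf("Water-bridge network: %d edge(s) (> %d%% occupancy), %d thick (> %d%%), hubs: %s\n",
              nrow(x$edges), round(100 * x$edge_occ),
              sum(x$edges$thick), round(100 * x$thick_occ),
              if (length(x$hubs)) paste(x$hubs, collapse = ", ")
              else "none"))
  invisible(x)
}
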