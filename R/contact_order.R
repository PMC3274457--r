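#' Native contact map of a structure
#'
#' A residue pair (k, l) with `|k - l| >= min_sep` is a native contact
#' when its representative-atom distance is strictly below `threshold`.
#' Under the default `"cbeta"` rule the representative atom is C-beta
#' (C-alpha for glycine); `"heavy_min"` uses the minimum distance over
#' all heavy atoms instead. Residues lacking a representative atom are
#' skipped with a warning.
#'
#' @param structure a `bio3d` pdb object, or a list with elements
#'   `atoms` (data frame with `elety`, `resno`, `resid`) and `xyz`.
#' @param threshold contact distance threshold in Angstrom (default
#'   7.5).
#' @param atom_rule `"cbeta"` or `"heavy_min"`.
#' @param min_sep minimum sequence separation (default 2).
#' @return A `contact_map`: data frame of contact pairs `k`, `l`
#'   (residue numbers) with attributes `n_contact`, `n_seq`,
#'   `threshold`, `atom_rule`.
#' @export
contact_map <- function(structure, threshold = 7.5,
                        atom_rule = c("cbeta", "heavy_min"),
                        min_sep = 2L) {
  atom_rule <- match.arg(atom_rule)
  at <- structure_atoms(structure)
  resnos <- sort(unique(at$resno))
  n_seq <- length(resnos)

  if (atom_rule == "cbeta") {
    rep_xyz <- t(vapply(resnos, function(rn) {
      rows <- at[at$resno == rn, , drop = FALSE]
      nm <- if (any(rows$resid == "GLY")) "CA" else "CB"
      hit <- which(rows$elety == nm)
      if (length(hit) == 0) hit <- which(rows$elety == "CA")
      if (length(hit) == 0) return(c(NA_real_, NA_real_, NA_real_))
      unlist(rows[hit[1], c("x", "y", "z")])
    }, numeric(3)))
    ok <- !is.na(rep_xyz[, 1])
    if (any(!ok))
      warning("skipping ", sum(!ok),
              " residue(s) without a representative atom")
    resnos <- resnos[ok]
    rep_xyz <- rep_xyz[ok, , drop = FALSE]
    D <- as.matrix(stats::dist(rep_xyz))
  } else {
    heavy <- at[!grepl("^H", at$elety), , drop = FALSE]
    D <- matrix(Inf, length(resnos), length(resnos))
    sp <- split(seq_len(nrow(heavy)), heavy$resno)
    for (a in seq_along(resnos)) {
      for (b in seq_len(a - 1)) {
        ra <- sp[[as.character(resnos[a])]]
        rb <- sp[[as.character(resnos[b])]]
        if (is.null(ra) || is.null(rb)) next
        dd <- sqrt(outer(heavy$x[ra], heavy$x[rb], `-`)^2 +
                   outer(heavy$y[ra], heavy$y[rb], `-`)^2 +
                   outer(heavy$z[ra], heavy$z[rb], `-`)^2)
        D[a, b] <- D[b, a] <- min(dd)
      }
    }
  }

  idx <- which(upper.tri(D), arr.ind = TRUE)
  k <- resnos[idx[, 1]]; l <- resnos[idx[, 2]]
  hit <- abs(k - l) >= min_sep & D[idx] < threshold
  out <- data.frame(k = k[hit], l = l[hit])
  structure(out, class = c("contact_map", "data.frame"),
            n_contact = nrow(out), n_seq = n_seq,
            threshold = threshold, atom_rule = atom_rule)
}

# Normalise a structure argument to an atom data frame with x, y, z.
structure_atoms <- function(structure) {
  if (!is.null(structure$atom)) return(structure$atom)
  if (!is.null(structure$atoms)) {
    at <- structure$atoms
    if (is.null(at$x)) {
      xyz <- matrix(structure$xyz, ncol = 3, byrow = TRUE)
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    }
    return(at)
  }
  stop("cannot interpret structure argument")
}

#' Contact order
#'
#' `CO = 1 / (N_contact * N_seq) * sum over contacts |k - l|`: the mean
#' sequence separation of native contacts normalised by chain length.
#' Always in (0, 1] on a non-empty map.
#'
#' @param cm a [contact_map()].
#' @return Dimensionless contact order.
#' @export
contact_order <- function(cm) {
  if (nrow(cm) == 0) stop("empty contact map")
  sum(abs(cm$k - cm$l)) / (attr(cm, "n_contact") * attr(cm, "n_seq"))
}

#' Closed-form chain-model information table
#'
#' Under the sequential chain model the smoothed upper bound of a pair
#' `(k, l)` with no direct restraint is `u * |k - l|` and its lower
#' bound is 0, so the information carried by a restraint on that pair
#' is `log(u * |k - l|)` in closed form. This builds the corresponding
#' `information_table` directly (restraint-level, unnormalised), the
#' form under which [co_star()] reduces exactly to [contact_order()].
#'
#' @param resid_a,resid_b residue numbers of each restrained pair
#'   (`|resid_a - resid_b| >= 1`).
#' @param u sequential upper bound in Angstrom (default 5).
#' @param log_base 2 (bits, default) or `exp(1)` (nats).
#' @return An `information_table` sorted by descending information.
#' @export
chain_information <- function(resid_a, resid_b, u = 5, log_base = 2) {
  stopifnot(length(resid_a) == length(resid_b), u > 0)
  sep <- abs(resid_a - resid_b)
  if (any(sep < 1)) stop("restrained pairs must differ in residue number")
  out <- data.frame(id = seq_along(resid_a),
                    resid_a = as.integer(resid_a), name_a = "H",
                    resid_b = as.integer(resid_b), name_b = "H",
                    i_uni = log(u * sep, base = log_base),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$i_uni, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("information_table", "data.frame"),
            log_base = log_base, normalization = "per_restraint")
}

#' Information-weighted contact order
#'
#' `CO* = 1 / (N_contact * N_seq) * sum over restraints
#' base^(I_uni,r) / u`, where the exponential inverts the logarithm
#' used to compute the unique-information values. Under the sequential
#' chain model (`u_ij = u |i - j|`, `l_ij = 0`) each restraint
#' contributes exactly `|i - j|` and `CO*` reduces to `CO`.
#'
#' @param info an `information_table` (see [rank_restraints()]).
#' @param n_contact number of contacts (by default the number of
#'   restraints in `info`).
#' @param n_seq sequence length.
#' @param u sequential upper bound in Angstrom.
#' @param log_base if given, must match `info`'s log base.
#' @return Dimensionless weighted contact order.
#' @export
co_star <- function(info, n_contact = nrow(info), n_seq, u,
                    log_base = NULL) {
  if (nrow(info) == 0) stop("empty information table")
  stopifnot(u > 0)
  base <- attr(info, "log_base")
  if (is.null(base)) base <- 2
  if (!is.null(log_base) && !isTRUE(all.equal(log_base, base)))
    stop("log base mismatch: information table uses base ", base,
         ", co_star called with ", log_base)
  sum(base^info$i_uni / u) / (n_contact * n_seq)
}
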