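#' Uncertainty of a single distance interval
#'
#' The uncertainty of a distance known to lie in `[lower, upper]` is the
#' entropy of the uniform distribution on that interval,
#' `log(upper - lower)`, in the configured base (bits for base 2).
#'
#' @param lower,upper bounds in Angstrom, `upper > lower`; vectorised.
#' @param log_base 2 (bits, default) or `exp(1)` (nats).
#' @return Information value(s).
#' @export
pair_uncertainty <- function(lower, upper, log_base = 2) {
  if (any(upper <= lower))
    stop("pair uncertainty requires upper > lower; fixed pairs must be excluded by the caller")
  log(upper - lower, base = log_base)
}

# Pairs whose bound width is below this are geometrically fixed and are
# excluded from uncertainty sums (their log-width diverges).
FIXED_WIDTH <- 1e-6

fixed_pairs <- function(bm) (bm$upper - bm$lower) < FIXED_WIDTH

#' Total structure uncertainty of a smoothed bound matrix
#'
#' `(1/N)` times the sum of [pair_uncertainty()] over all unordered,
#' non-fixed node pairs, where `N` is the node count. Pairs with bound
#' width below 1e-6 A are flagged fixed and skipped.
#'
#' @param bm a smoothed `bounds_matrix`.
#' @inheritParams pair_uncertainty
#' @return A single information value.
#' @export
structure_uncertainty <- function(bm, log_base = 2) {
  n <- nrow(bm$upper)
  if (n == 0) stop("empty bounds matrix")
  idx <- pair_indices(n)
  w <- bm$upper[idx] - bm$lower[idx]
  w <- w[w >= FIXED_WIDTH]
  sum(log(w, base = log_base)) / n
}

# Smoothed bound matrix for a restraint subset over a fixed node universe.
smoothed_bounds_for <- function(set, baseline, nodes) {
  smooth_bounds(build_bounds(set, baseline, nodes = nodes))
}

#' Unique information of one restraint
#'
#' The unique information of restraint `r` is the increase in structure
#' uncertainty caused by removing it: both the full set and the set
#' without `r` are built into bound matrices over the same node universe
#' (fixed by the full set) and smoothed, and the per-pair uncertainties
#' are differenced.
#'
#' By default the removed restraint's own pair is excluded from the
#' difference, so the value measures the information the restraint
#' propagates to the rest of the structure through the triangle
#' inequalities. This is the redundancy-consistent convention: it is
#' exactly zero for fully triangulated rigid sets and for exact
#' duplicates, and is never negative (smoothing with more restraints
#' only tightens each pair). Set `include_removed_pair = TRUE` for the
#' literal all-pairs difference.
#'
#' @param set a [restraint_set()] containing `r`.
#' @param r a restraint id in `set`.
#' @param baseline a [baseline_spec()].
#' @inheritParams pair_uncertainty
#' @param include_removed_pair include the removed restraint's own pair
#'   in the uncertainty difference (default `FALSE`).
#' @param nodes optional node table fixing the node universe (e.g. all
#'   chain nodes under the chain-model baseline); defaults to the
#'   distinct selections of `set`.
#' @return A single information value (>= 0 under the default
#'   convention).
#' @export
unique_information <- function(set, r, baseline = baseline_spec(),
                               log_base = 2,
                               include_removed_pair = FALSE,
                               nodes = NULL) {
  if (!r %in% set$id) stop("restraint id ", r, " not in the set")
  if (is.null(nodes)) nodes <- node_table(set)
  full <- smoothed_bounds_for(set, baseline, nodes)
  i_uni_one(set, r, baseline, nodes, full, log_base, include_removed_pair)
}

i_uni_one <- function(set, r, baseline, nodes, full, log_base,
                      include_removed_pair) {
  n <- nrow(nodes)
  red <- smoothed_bounds_for(set[set$id != r, , drop = FALSE],
                             baseline, nodes)
  w_full <- full$upper - full$lower
  w_red <- red$upper - red$lower
  keep <- upper.tri(w_full) & w_full >= FIXED_WIDTH
  if (!include_removed_pair) {
    row <- set[set$id == r, ]
    i <- node_index(nodes, row$resid_a, row$name_a)
    j <- node_index(nodes, row$resid_b, row$name_b)
    keep[i, j] <- keep[j, i] <- FALSE
  }
  sum(log(w_red[keep] / w_full[keep], base = log_base)) / n
}

#' Rank restraints by unique information
#'
#' Computes the unique information of every restraint in the set by
#' leave-one-out bound smoothing over the fixed node universe, and
#' returns the records sorted by descending information (least
#' redundant first), ties broken by ascending id.
#'
#' @inheritParams unique_information
#' @param max_sweeps maximum lower-bound smoothing sweeps.
#' @return An `information_table`: data frame with columns `id`,
#'   `resid_a`, `name_a`, `resid_b`, `name_b`, `i_uni`, `rank`, and
#'   attributes `H_full` (structure uncertainty of the full set),
#'   `log_base`, and `normalization`.
#' @export
rank_restraints <- function(set, baseline = baseline_spec(), log_base = 2,
                            include_removed_pair = FALSE,
                            max_sweeps = 10L, nodes = NULL) {
  if (nrow(set) == 0) stop("empty restraint set")
  if (is.null(nodes)) nodes <- node_table(set)
  full <- smoothed_bounds_for(set, baseline, nodes)
  i_uni <- vapply(set$id, function(r)
    i_uni_one(set, r, baseline, nodes, full, log_base,
              include_removed_pair), 0)
  out <- data.frame(id = set$id, resid_a = set$resid_a,
                    name_a = set$name_a, resid_b = set$resid_b,
                    name_b = set$name_b, i_uni = i_uni,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$i_uni, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("information_table", "data.frame"),
            H_full = structure_uncertainty(full, log_base),
            log_base = log_base,
            normalization = "per_node",
            pair_convention = if (include_removed_pair) "all_pairs"
                              else "other_pairs")
}

#' @export
print.information_table <- function(x, ...) {
  h <- attr(x, "H_full")
  cat(sprintf("Unique-information ranking: %d restraints (log base %s%s)\n",
              nrow(x), format(attr(x, "log_base")),
              if (is.null(h)) "" else sprintf(", H_full = %.4f", h)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
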