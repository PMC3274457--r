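# Random consistent restraint set on n nodes (atom H, residues 1..n):
# each unordered pair restrained with probability p, bounds [lo, lo + w].
random_restraints <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  idx <- utils::combn(n, 2)
  keep <- stats::runif(ncol(idx)) < p
  if (sum(keep) < 2) keep[1:2] <- TRUE
  m <- sum(keep)
  lo <- stats::runif(m, 0, 3)
  hi <- lo + stats::runif(m, 0.5, 6)
  restraint_set(idx[1, keep], rep("H", m), idx[2, keep], rep("H", m),
                lo, hi)
}
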