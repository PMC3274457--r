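# Sparse hand-placed hydration geometry: isolated GLY residues whose
# backbone O atoms sit far apart, with waters positioned to bridge
# chosen pairs. Distances are controlled exactly, so no accidental
# bridges can form.
star_structure <- function() {
  # residues 1 (center), 2, 3, 4 on far-apart sites
  site <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0), c(0, 0, 30))
  rows <- lapply(1:4, function(i)
    data.frame(elety = c("N", "CA", "C", "O"), resid = "GLY", resno = i,
               x = site[i, 1] + c(0, 1.5, 2.5, 3.0),
               y = site[i, 2], z = site[i, 3], stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# One water per requested bridge; in "on" frames its O sits `d1` from
# the center residue's O atom and its H1 `d2` from the partner's O atom
# (off frames park it 500 A away).
star_trajectory <- function(on_frames, n_frames, d1 = 2.0, d2 = 2.0) {
  at <- star_structure()
  n_bridge <- length(on_frames)
  wat <- do.call(rbind, lapply(seq_len(n_bridge), function(w)
    data.frame(elety = c("OW", "HW1"), resid = "HOH", resno = 10 + w,
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE)))
  all_at <- rbind(at, wat)
  o_center <- which(at$resno == 1 & at$elety == "O")
  frames <- matrix(0, n_frames, 3 * nrow(all_at))
  for (f in seq_len(n_frames)) {
    xyz <- cbind(all_at$x, all_at$y, all_at$z)
    for (w in seq_len(n_bridge)) {
      o_part <- which(at$resno == w + 1 & at$elety == "O")
      a <- xyz[o_center, ]; b <- xyz[o_part, ]
      u <- (b - a) / sqrt(sum((b - a)^2))
      ow <- a + d1 * u
      hw <- b - d2 * u
      rows <- nrow(at) + c(2 * w - 1, 2 * w)
      if (f %in% on_frames[[w]]) {
        xyz[rows, ] <- rbind(ow, hw)
      } else {
        xyz[rows, ] <- rbind(ow, hw) + 500 * w
      }
    }
    frames[f, ] <- as.numeric(t(xyz))
  }
  trajectory(frames, all_at, time_step = 1)
}
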