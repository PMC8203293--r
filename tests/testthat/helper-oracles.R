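# Independent brute-force oracles used across the suite. These deliberately
# use plain loops and textbook formulas, not the package's code paths.

oracle_stiff_fraction <- function(values, roi, threshold) {
  n_stiff <- 0L; n_tot <- 0L
  for (r in seq_len(nrow(values))) {
    for (c in seq_len(ncol(values))) {
      if (roi[r, c]) {
        v <- values[r, c]
        if (is.finite(v) && v >= 0) {
          n_tot <- n_tot + 1L
          if (v > threshold) n_stiff <- n_stiff + 1L
        }
      }
    }
  }
  n_stiff / n_tot
}

# Unique greedy assignment of traced fibers to ground-truth fibers by
# midpoint distance (plain nearest-neighbour matching can pair two fibers
# whose midpoints happen to lie close).
match_fibers <- function(est_paths, truth_paths) {
  mid <- function(p) p[ceiling(nrow(p) / 2), ]
  em <- t(sapply(est_paths, mid))
  tm <- t(sapply(truth_paths, mid))
  d <- outer(seq_len(nrow(em)), seq_len(nrow(tm)), Vectorize(function(i, j) {
    sqrt(sum((em[i, ] - tm[j, ])^2))
  }))
  assign <- rep(NA_integer_, nrow(em))
  repeat {
    if (all(!is.finite(d))) break
    ij <- arrayInd(which.min(d), dim(d))
    if (!is.finite(d[ij[1], ij[2]])) break
    assign[ij[1]] <- ij[2]
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  assign
}

path_arc_length_for_test <- function(p) {
  sum(sqrt(rowSums(diff(p)^2)))
}

oracle_arc_chord <- function(path) {
  arc <- 0
  for (i in 2:nrow(path)) {
    arc <- arc + sqrt(sum((path[i, ] - path[i - 1, ])^2))
  }
  chord <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  c(arc = arc, chord = chord)
}

oracle_motility <- function(t_s, xyz) {
  path <- 0
  for (i in 2:nrow(xyz)) path <- path + sqrt(sum((xyz[i, ] - xyz[i - 1, ])^2))
  disp <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
  dur <- t_s[length(t_s)] - t_s[1]
  list(speed = path / dur * 60, displacement = disp,
       straightness = if (path > 0) disp / path else 0,
       path_length = path, duration = dur)
}

oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, p = 2 * pt(-abs(tstat), n1 + n2 - 2))
}

oracle_anova_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  (ssb / df1) / (ssw / df2)
}

oracle_kruskal_H <- function(groups) {
  # no-tie form
  all_v <- unlist(groups)
  N <- length(all_v)
  rk <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  s <- 0
  for (g in seq_along(groups)) {
    rg <- rk[idx == g]
    s <- s + sum(rg)^2 / length(rg)
  }
  12 / (N * (N + 1)) * s - 3 * (N + 1)
}

# Raw AFM approach trace: baseline then Hertzian contact at z0, solving
# k d = hertz(z - z0 - d) per point by fixed-point iteration.
make_raw_afm_curve <- function(E, z, z0, k = 0.6, R = 2.25e-6, nu = 0.5,
                               baseline = 0, drift = 0) {
  C <- (4 / 3) * (E / (1 - nu^2)) * sqrt(R)
  d <- numeric(length(z))
  for (i in seq_along(z)) {
    if (z[i] > z0) {
      di <- 0
      for (it in 1:200) {
        delta <- max(z[i] - z0 - di, 0)
        dn <- C * delta^1.5 / k
        if (abs(dn - di) < 1e-15) break
        di <- (di + dn) / 2
      }
      d[i] <- di
    }
  }
  d + baseline + drift * z
}
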