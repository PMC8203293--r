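#' Hertzian force for a spherical indenter
#'
#' Paraxial Hertz model for a rigid sphere indenting an elastic half-space:
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)`, valid for
#' indentations small compared to the bead radius.
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio (incompressible tissue: 0.5).
#' @param R Bead radius, m.
#' @param delta Indentation depth(s), m; vectorised.
#' @return Force in newtons, same length as `delta`.
#' @examples
#' hertz_force(1000, 0.5, 2.25e-6, 1e-6) # 2.667e-9 N
#' @export
hertz_force <- function(E, nu = 0.5, R, delta) {
  if (any(delta < 0)) abort("Indentation `delta` must be >= 0.")
  if (E < 0 || R <= 0 || nu >= 1) abort("Require E >= 0, R > 0 and nu < 1.")
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5
}

#' Force-indentation curve objects
#'
#' A `force_curve` is a tibble of ordered (indentation, force) pairs in SI
#' units carrying the probe metadata needed for Hertzian fitting: cantilever
#' spring constant, bead radius, and Poisson ratio.
#'
#' @param indentation_m Non-decreasing indentation depths, m.
#' @param force_N Forces, N, same length (>= 10 points).
#' @param spring_constant_N_per_m Cantilever stiffness, N/m.
#' @param bead_radius_m Probe bead radius, m (a 4.5 um diameter bead has
#'   radius 2.25e-6).
#' @param poisson_ratio Dimensionless, in `[0, 0.5]`; default 0.5.
#' @return A `force_curve` tibble with attributes holding the metadata.
#' @export
force_curve <- function(indentation_m, force_N,
                        spring_constant_N_per_m = 0.6,
                        bead_radius_m = 2.25e-6,
                        poisson_ratio = 0.5) {
  if (length(indentation_m) != length(force_N) || length(force_N) < 10L) {
    abort("Need equal-length indentation/force vectors with >= 10 points.")
  }
  if (is.unsorted(indentation_m)) abort("`indentation_m` must be non-decreasing.")
  if (bead_radius_m <= 0) abort("`bead_radius_m` must be positive.")
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    abort("`poisson_ratio` must lie in [0, 0.5].")
  }
  out <- tibble(indentation_m = as.numeric(indentation_m),
                force_N = as.numeric(force_N))
  attr(out, "spring_constant_N_per_m") <- spring_constant_N_per_m
  attr(out, "bead_radius_m") <- bead_radius_m
  attr(out, "poisson_ratio") <- poisson_ratio
  class(out) <- c("force_curve", class(out))
  out
}

#' Contact-point estimation on a raw approach curve
#'
#' Converts a raw piezo-position/deflection approach curve into a
#' force-indentation curve. The baseline (pre-contact) linear drift is removed
#' first; the contact index is then chosen to maximise the ratio of deflection
#' variance after the split to variance before it, swept over all admissible
#' splits. Force is `spring_constant x deflection`; indentation is piezo
#' displacement minus deflection, zeroed at the contact point.
#'
#' @param piezo_m Monotone piezo positions, m.
#' @param deflection_m Cantilever deflections, m.
#' @param spring_constant_N_per_m Cantilever stiffness, N/m.
#' @param bead_radius_m,poisson_ratio Probe metadata passed to the returned
#'   [force_curve()].
#' @param min_segment Minimum number of samples on each side of the split.
#' @return A list with `contact_index` and `curve` (a [force_curve()] of the
#'   post-contact points).
#' @export
estimate_contact_point <- function(piezo_m, deflection_m,
                                   spring_constant_N_per_m = 0.6,
                                   bead_radius_m = 2.25e-6,
                                   poisson_ratio = 0.5,
                                   min_segment = 10L) {
  n <- length(piezo_m)
  if (n != length(deflection_m) || n < 3L * min_segment) {
    abort("Raw curve too short for contact detection.")
  }
  if (is.unsorted(piezo_m)) abort("`piezo_m` must be monotone non-decreasing.")
  if (stats::var(deflection_m) == 0) {
    abort("Flat deflection trace: no contact detected.")
  }
  splits <- seq(min_segment, n - min_segment)
  ratio <- vapply(splits, function(i) {
    base <- stats::.lm.fit(cbind(1, piezo_m[1:i]), deflection_m[1:i])
    resid_before <- base$residuals
    pred_after <- cbind(1, piezo_m[(i + 1):n]) %*% base$coefficients
    resid_after <- deflection_m[(i + 1):n] - pred_after
    v_before <- sum(resid_before^2) / (i - 1L)
    v_after <- sum(resid_after^2) / (n - i - 1L)
    if (v_before <= 0) v_before <- .Machine$double.eps
    v_after / v_before
  }, numeric(1))
  k <- splits[which.max(ratio)]
  if (max(ratio) < 4) abort("No contact detected: deflection is flat within noise.")
  base <- stats::.lm.fit(cbind(1, piezo_m[1:k]), deflection_m[1:k])
  defl <- deflection_m - as.vector(cbind(1, piezo_m) %*% base$coefficients)
  idx <- k:n
  indentation <- (piezo_m[idx] - piezo_m[k]) - (defl[idx] - defl[k])
  force <- spring_constant_N_per_m * (defl[idx] - defl[k])
  keep <- indentation >= 0
  ord <- order(indentation[keep])
  list(
    contact_index = k,
    curve = force_curve(indentation[keep][ord], force[keep][ord],
                        spring_constant_N_per_m = spring_constant_N_per_m,
                        bead_radius_m = bead_radius_m,
                        poisson_ratio = poisson_ratio)
  )
}

#' Fit Young's modulus to a force-indentation curve
#'
#' Least-squares fit of the Hertzian sphere model over indentations in
#' `(0, fit_depth_max_m]`. Because force is linear in E at fixed geometry, the
#' minimiser has the closed form `E = sum(F * g) / sum(g^2)` with
#' `g(delta) = (4/3) sqrt(R) delta^(3/2) / (1 - nu^2)`; a negative solution
#' (possible under noise at near-zero modulus) is clipped to 0 and flagged
#' with a warning.
#'
#' @param curve A [force_curve()].
#' @param fit_depth_max_m Upper end of the fit window, m; defaults to one
#'   bead radius.
#' @return Fitted Young's modulus in Pa, with attributes `n_points` and
#'   `relative_residual` (residual norm over force norm in the window).
#' @export
fit_young_modulus <- function(curve, fit_depth_max_m = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  R <- attr(curve, "bead_radius_m")
  nu <- attr(curve, "poisson_ratio")
  if (is.null(fit_depth_max_m)) fit_depth_max_m <- R
  win <- curve$indentation_m > 0 & curve$indentation_m <= fit_depth_max_m
  if (sum(win) < 10L) {
    abort(sprintf("Only %d points with indentation in (0, %.3g m]; >= 10 required.",
                  sum(win), fit_depth_max_m))
  }
  f <- curve$force_N[win]
  if (any(!is.finite(f))) abort("Non-finite force values in the fit window.")
  g <- (4 / 3) * sqrt(R) * curve$indentation_m[win]^1.5 / (1 - nu^2)
  E <- sum(f * g) / sum(g^2)
  if (E < 0) {
    warn("Fitted modulus was negative; clipped to 0 Pa.")
    E <- 0
  }
  resid <- f - E * g
  rel <- if (sum(f^2) > 0) sqrt(sum(resid^2) / sum(f^2)) else 0
  structure(E, n_points = sum(win), relative_residual = rel)
}

#' Pool and summarise Young's-modulus maps
#'
#' Pools per-point moduli across indentation maps of a sample (e.g. nine
#' 64-point maps over 10 x 10 um scan areas) and reports the pooled mean,
#' sample standard deviation, and a binned histogram of the distribution.
#' Points flagged as failed fits (relative residual above `max_relative_residual`)
#' are excluded and counted.
#'
#' @param maps A data frame with a numeric `E_Pa` column (optionally
#'   `sample_id`, `map_id`, `relative_residual`), or a list of numeric vectors
#'   of moduli in Pa.
#' @param bin_width_kPa Histogram bin width, kPa.
#' @param max_relative_residual Exclusion threshold for failed fits when a
#'   `relative_residual` column is present.
#' @return A list with `summary` (one-row tibble: `n_points`, `n_excluded`,
#'   `mean_Pa`, `sd_Pa`) and `histogram` (tibble of bin mids and counts).
#' @export
summarize_moduli <- function(maps, bin_width_kPa = 0.25,
                             max_relative_residual = 0.5) {
  if (is.list(maps) && !is.data.frame(maps)) {
    maps <- list_rbind(imap(maps, function(v, i) tibble(map_id = i, E_Pa = v)))
  }
  maps <- as_tibble(maps)
  if (!"E_Pa" %in% names(maps) || nrow(maps) == 0L) {
    abort("`maps` must contain at least one modulus in an `E_Pa` column.")
  }
  excluded <- 0L
  if ("relative_residual" %in% names(maps)) {
    bad <- !is.na(maps$relative_residual) &
      maps$relative_residual > max_relative_residual
    excluded <- sum(bad)
    maps <- maps[!bad, ]
    if (nrow(maps) == 0L) abort("All points excluded by the fit-quality filter.")
  }
  e <- maps$E_Pa
  if (any(!is.finite(e)) || any(e < 0)) abort("Moduli must be finite and >= 0.")
  s <- if (length(e) > 1L) sd(e) else {
    warn("Single modulus point: SD is undefined, reported as 0.")
    0
  }
  bw <- bin_width_kPa * 1000
  breaks <- seq(0, (floor(max(e) / bw) + 1) * bw, by = bw)
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  list(
    summary = tibble(n_points = length(e), n_excluded = excluded,
                     mean_Pa = mean(e), sd_Pa = s),
    histogram = tibble(bin_mid_kPa = h$mids / 1000, count = h$counts)
  )
}

#' Read a force curve from CSV
#'
#' Reads a two-column per-curve CSV. Processed curves have columns
#' `indentation_m, force_N`; raw curves (`raw = TRUE`) have
#' `piezo_m, deflection_m` and are passed through [estimate_contact_point()].
#' Probe metadata comes from a YAML sidecar with keys `spring_constant`,
#' `bead_radius`, `poisson_ratio` (SI units), or from the arguments.
#'
#' @param path CSV path.
#' @param meta Optional YAML sidecar path.
#' @param raw Whether the CSV holds a raw piezo/deflection approach trace.
#' @param ... Metadata overrides passed to [force_curve()].
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, meta = NULL, raw = FALSE, ...) {
  df <- utils::read.csv(path)
  args <- list(...)
  if (!is.null(meta)) {
    y <- yaml::read_yaml(meta)
    args$spring_constant_N_per_m <- args$spring_constant_N_per_m %||% y$spring_constant
    args$bead_radius_m <- args$bead_radius_m %||% y$bead_radius
    args$poisson_ratio <- args$poisson_ratio %||% y$poisson_ratio
  }
  args <- args[!vapply(args, is.null, logical(1))]
  if (raw) {
    res <- do.call(estimate_contact_point,
                   c(list(piezo_m = df[[1]], deflection_m = df[[2]]), args))
    res$curve
  } else {
    do.call(force_curve, c(list(indentation_m = df[[1]], force_N = df[[2]]), args))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
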