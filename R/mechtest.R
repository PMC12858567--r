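#' Load-displacement curve container
#'
#' @param displacement displacement samples, mm (monotone non-decreasing).
#' @param force force samples, N.
#' @param test_kind one of `"bend_3pt"`, `"bend_notched"`, `"vb_compression"`.
#' @param span support span, mm (bending kinds).
#' @param loading_rate crosshead rate, mm/min (metadata).
#' @export
load_displacement_curve <- function(displacement, force,
                                    test_kind = c("bend_3pt", "bend_notched",
                                                  "vb_compression"),
                                    span = NA_real_, loading_rate = NA_real_) {
  test_kind <- match.arg(test_kind)
  if (length(displacement) != length(force)) stop("unequal array lengths")
  if (length(force) < 50L) stop("curve too short (< 50 samples)")
  if (any(diff(displacement) < -1e-12)) stop("displacement must be non-decreasing")
  if (test_kind != "vb_compression" && (!is.finite(span) || span <= 0))
    stop("span must be > 0 for bending tests")
  structure(list(displacement = as.numeric(displacement),
                 force = as.numeric(force), test_kind = test_kind,
                 span = span, loading_rate = loading_rate),
            class = "load_displacement_curve")
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  n <- length(x)
  pad <- c(rep(x[1], w), x, rep(x[n], w))
  as.numeric(stats::filter(pad, k, sides = 2))[(w + 1):(w + n)]
}

#' Analyze a whole-bone load-displacement curve
#'
#' Extracts the structural properties reported for rodent three-point
#' bending: toe-corrected origin (back-extrapolation of the stiffest linear
#' segment to zero force), stiffness (best sliding-window linear fit by R^2
#' over the 20-80% of-ultimate ascending limb), yield by the 0.9-secant
#' criterion (first point at which the secant stiffness from the corrected
#' origin falls to 90% of stiffness; the ultimate point if no such drop),
#' ultimate force, failure point (first post-ultimate sample below 10% of
#' ultimate, else the last sample), post-yield displacement, and trapezoidal
#' work-to-fracture (N.mm = mJ) total and post-yield.
#'
#' @param curve a [load_displacement_curve()].
#' @param window_frac sliding-window width as a fraction of the candidate
#'   segment (default 0.6; wide enough to average acquisition noise, short
#'   enough to reject residual toe curvature).
#' @param force_range force band (fractions of ultimate) defining the
#'   candidate linear segment.
#' @param secant_ratio secant-stiffness drop ratio defining yield.
#' @param smooth_window moving-average width (samples) used for stiffness /
#'   yield / ultimate detection; work terms integrate the raw record.
#' @param toe_correct apply the toe correction (the raw origin is kept when
#'   `FALSE`, for audit).
#' @return list of class `mechanical_properties`: `stiffness` (N/mm),
#'   `yield_force` (N), `ultimate_force` (N), `pyd` (mm), `w_f` and `py_wf`
#'   (mJ), the detected displacements, fit `r_squared`, and `flags`.
#' @export
analyze_curve <- function(curve, window_frac = 0.6,
                          force_range = c(0.2, 0.8), secant_ratio = 0.9,
                          smooth_window = 5L, toe_correct = TRUE) {
  stopifnot(inherits(curve, "load_displacement_curve"))
  d <- curve$displacement
  f_raw <- curve$force
  # high-frequency noise estimate from second differences; skip smoothing on
  # effectively noiseless records so sharp yield/ultimate kinks stay sharp
  sig_hf <- median(abs(diff(f_raw, differences = 2))) / (0.6745 * sqrt(6))
  if (sig_hf < 1e-4 * max(abs(f_raw))) smooth_window <- 1L
  f <- moving_average(f_raw, smooth_window)
  flags <- character()
  # ultimate from the raw record (smoothing would clip a sharp peak)
  i_ult <- which.max(f_raw)
  f_ult <- f_raw[i_ult]
  if (f_ult <= 0) stop("force never exceeds the noise floor")
  # candidate ascending-limb segment between the force-range bounds
  asc <- seq_len(i_ult)
  seg <- asc[f[asc] >= force_range[1] * f_ult & f[asc] <= force_range[2] * f_ult]
  if (length(seg) < 5L) seg <- asc[f[asc] <= force_range[2] * f_ult]
  w <- max(5L, floor(length(seg) * window_frac))
  best <- list(r2 = -Inf)
  starts <- unique(round(seq(1L, length(seg) - w + 1L, length.out = 60L)))
  for (s in starts) {
    ii <- seg[s:(s + w - 1L)]
    fit <- stats::lm.fit(cbind(1, d[ii]), f[ii])
    slope <- fit$coefficients[2]
    r2 <- 1 - sum(fit$residuals^2) / sum((f[ii] - mean(f[ii]))^2)
    if (is.finite(slope) && slope > 0 &&
        (r2 > best$r2 || (r2 >= best$r2 - 1e-12 && slope > best$slope %||% -Inf)))
      best <- list(r2 = r2, slope = slope, intercept = fit$coefficients[1],
                   ii = ii)
  }
  if (!is.finite(best$r2)) stop("no usable linear segment found")
  if (best$r2 < 0.99) {
    warning("no linear segment with R^2 >= 0.99; best-effort stiffness")
    flags <- c(flags, "low_linearity")
  }
  stiffness <- unname(best$slope)
  d0 <- if (toe_correct) unname(-best$intercept / best$slope) else 0
  # 0.9-secant yield, scanned from the end of the fitted window; the
  # crossing is located to sub-sample precision by linear interpolation
  start_scan <- max(best$ii)
  sec <- f / (d - d0)
  tau <- secant_ratio * stiffness
  cand <- seq(start_scan, i_ult)
  drop_i <- cand[which(sec[cand] < tau)[1]]
  if (is.na(drop_i) || drop_i <= 1L) {
    i_yield <- i_ult
    d_yield <- d[i_ult]
    f_yield <- f[i_ult]
    if (is.na(drop_i)) flags <- c(flags, "yield_at_ultimate")
  } else {
    i_yield <- drop_i
    wgt <- (sec[drop_i - 1L] - tau) / (sec[drop_i - 1L] - sec[drop_i])
    wgt <- min(max(wgt, 0), 1)
    d_yield <- d[drop_i - 1L] + wgt * (d[drop_i] - d[drop_i - 1L])
    f_yield <- f[drop_i - 1L] + wgt * (f[drop_i] - f[drop_i - 1L])
  }
  # failure: first post-ultimate sample below 10% of ultimate, else last
  post <- seq(i_ult, length(f))
  fail_i <- post[which(f_raw[post] < 0.1 * f_ult)[1]]
  if (is.na(fail_i)) fail_i <- length(f)
  trapz <- function(ii) sum(diff(d[ii]) * (head(f_raw[ii], -1) + tail(f_raw[ii], -1)) / 2)
  w_span <- which(d >= d0 & seq_along(d) <= fail_i)
  w_f <- trapz(w_span)
  py_wf <- if (fail_i > i_yield) {
    (f_yield + f_raw[i_yield]) / 2 * (d[i_yield] - d_yield) +
      trapz(seq(i_yield, fail_i))
  } else 0
  out <- list(stiffness = stiffness,
              yield_force = unname(f_yield),
              ultimate_force = unname(f_ult),
              pyd = unname(d[fail_i] - d_yield),
              w_f = w_f, py_wf = py_wf,
              d_origin = d0, d_yield = unname(d_yield),
              d_ultimate = unname(d[i_ult]), d_failure = unname(d[fail_i]),
              r_squared = best$r2, flags = flags)
  class(out) <- "mechanical_properties"
  out
}

#' Measure micro-notch geometry from a mask stack
#'
#' The notch plane is the slice of minimal bone area in the stack.  The
#' annulus center is the bone-region centroid; outer and inner radii come
#' from equivalent-area fits of the periosteal and endosteal (medullary)
#' contours; the notch half-angle `theta` is half the angle subtended at the
#' center by the longest contiguous missing arc of the mid-wall circle.
#'
#' @param mask logical 3D mask of the notched segment.
#' @param voxel_size voxel edge, micrometers.
#' @param closing_radius closing radius (voxels) for contouring.
#' @param min_arc_deg smallest arc (degrees) accepted as a notch.
#' @return list of class `notch_geometry`: `r_o`, `r_i`, `r_m`, `t` (mm),
#'   `theta` (rad), `notch_plane` (slice index).
#' @export
measure_notch_geometry <- function(mask, voxel_size, closing_radius = 3L,
                                   min_arc_deg = 3) {
  areas <- apply(mask, 3, sum)
  if (!any(areas > 0)) stop("notch not detected: empty slice stack")
  z <- which.min(ifelse(areas == 0, Inf, areas))
  m <- mask[, , z]
  h <- voxel_size * 1e-3
  # wall geometry from the intact reference slice (maximal bone area); the
  # notch plane's own ring is open by construction
  zref <- which.max(areas)
  comp <- slice_compartments(mask[, , zref], closing_radius)
  a_tt <- sum(comp$filled) * h^2
  a_med <- sum(comp$medullary) * h^2
  r_o <- sqrt(a_tt / pi)
  r_i <- sqrt(a_med / pi)
  idx <- which(comp$filled, arr.ind = TRUE)
  cx <- mean((idx[, 1] - 0.5) * h); cy <- mean((idx[, 2] - 0.5) * h)
  r_m <- (r_o + r_i) / 2
  ang <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
  px <- pmin(pmax(round((cx + r_m * cos(ang)) / h + 0.5), 1L), nrow(m))
  py <- pmin(pmax(round((cy + r_m * sin(ang)) / h + 0.5), 1L), ncol(m))
  occ <- m[cbind(px, py)]
  if (all(occ)) stop("notch not detected: mid-wall circle fully occupied")
  # longest circular run of missing samples
  gap <- !occ
  runs <- rle(c(gap, gap))            # doubled to handle wrap-around
  len <- pmin(max(runs$lengths[runs$values]), length(ang))
  arc <- len * (2 * pi / length(ang))
  if (arc < min_arc_deg * pi / 180)
    stop("notch not detected: no contiguous missing arc")
  structure(list(r_o = r_o, r_i = r_i, r_m = r_m, t = r_o - r_i,
                 theta = arc / 2, notch_plane = z),
            class = "notch_geometry")
}

# Geometry factor for a circumferential through-wall crack in a thin-walled
# pipe under bending (Takahashi 2002 polynomial, as used in rodent-femur
# fracture-toughness protocols): F_b(xi = theta/pi) for r_m/t in the
# thin-wall regime, valid for theta <= 110 degrees.
takahashi_fb <- function(theta, rm_over_t) {
  if (theta <= 0 || theta > 110 * pi / 180)
    stop("notch angle outside the geometry factor's validity range (0, 110 deg]")
  if (rm_over_t < 1)
    stop("r_m/t outside the geometry factor's validity range (>= 1)")
  xi <- theta / pi
  1 + 6.8 * xi^1.5 - 13.6 * xi^2.5 + 20.0 * xi^3.5
}

#' Crack-initiation toughness of a micro-notched femur
#'
#' Treats the notched diaphysis as a thin-walled pipe with a circumferential
#' through-wall crack loaded in three-point bending: the nominal bending
#' stress at the notch section is `sigma = M r_o / I` with `M = F_ult S / 4`
#' and `I` the annulus second moment of area, and
#' `K_c = F_b(theta/pi, r_m/t) * sigma * sqrt(pi * r_m * theta)` with the
#' Takahashi pipe-bending geometry factor.
#'
#' @param curve a notched-bending [load_displacement_curve()] (its span must
#'   be recorded; the protocol sets it to 4x the anterior-posterior width).
#' @param geom a [measure_notch_geometry()] result.
#' @param ultimate_force optional override of the peak force, N.
#' @return K_c in MPa.sqrt(m).
#' @export
compute_crack_initiation_toughness <- function(curve, geom,
                                               ultimate_force = NULL) {
  stopifnot(inherits(geom, "notch_geometry"))
  if (inherits(curve, "load_displacement_curve")) {
    if (curve$test_kind != "bend_notched")
      stop("curve must be a notched bending test")
    f_ult <- ultimate_force %||% max(curve$force)
    span <- curve$span
  } else stop("`curve` must be a load_displacement_curve")
  M <- f_ult * span / 4                         # N.mm
  I <- pi / 4 * (geom$r_o^4 - geom$r_i^4)       # mm^4
  sigma <- M * geom$r_o / I                     # MPa
  fb <- takahashi_fb(geom$theta, geom$r_m / geom$t)
  a_m <- geom$r_m * geom$theta * 1e-3           # crack length, m
  fb * sigma * sqrt(pi * a_m)
}

#' Ultimate load of a vertebral compression test
#'
#' First-failure convention: the maximum force reached before the first drop
#' exceeding 20% of the running maximum (the pure global maximum is available
#' with `convention = "global_max"`).  A curve with no such drop returns its
#' maximum with a truncation warning.
#'
#' @param curve a `vb_compression` [load_displacement_curve()].
#' @param drop_fraction drop (fraction of running max) that defines failure.
#' @param convention `"first_failure"` (default) or `"global_max"`.
#' @return ultimate load, N.
#' @export
analyze_vb_compression <- function(curve, drop_fraction = 0.2,
                                   convention = c("first_failure",
                                                  "global_max")) {
  convention <- match.arg(convention)
  stopifnot(inherits(curve, "load_displacement_curve"),
            curve$test_kind == "vb_compression")
  f <- curve$force
  if (convention == "global_max") return(max(f))
  run <- cummax(f)
  drop_i <- which(f < (1 - drop_fraction) * run)[1]
  if (is.na(drop_i)) {
    warning("no failure drop detected: curve truncated, returning max force")
    return(max(f))
  }
  max(f[seq_len(drop_i)])
}
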