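#' Cortical tube phantom
#'
#' Voxelizes a hollow circular cylinder (an idealized femur mid-diaphysis)
#' with analytically known cross-sectional morphometry.  A voxel belongs to
#' the cortex iff its center lies inside the annulus `r_i < r <= r_o`.
#' Optional pore voxels emulate cortical porosity; additive Gaussian noise
#' emulates acquisition noise.
#'
#' @param outer_radius,inner_radius annulus radii, mm (`inner_radius` may be 0
#'   for a solid rod); defaults approximate a murine femur mid-diaphysis.
#' @param length tube length along the scan (z) axis, mm.
#' @param voxel_size isotropic voxel size, micrometers.
#' @param tmd_mean,tmd_sd tissue mineral density of cortex voxels,
#'   mg HA/cm^3 (mean and per-voxel spread).
#' @param noise_sd additive Gaussian background noise, mg HA/cm^3.
#' @param porosity fraction of cortex voxels reset to background to emulate
#'   pores.
#' @param margin background margin around the tube, mm.
#' @param seed integer seed; all draws are deterministic given it.
#' @return list with `volume` (a [voxel_volume()]), `mask` (the exact
#'   voxelized cortex, before pores are noise-thresholded away), and
#'   `truth`: closed-form Ct.Ar, Tt.Ar, Ct.Th, I_min, Z_min, Ct.Po plus the
#'   voxel-count porosity actually realized.
#' @export
make_cortical_tube_phantom <- function(outer_radius = 1.0, inner_radius = 0.6,
                                       length = 0.5, voxel_size = 12,
                                       tmd_mean = 900, tmd_sd = 0,
                                       noise_sd = 0, porosity = 0,
                                       margin = 0.1, seed = 1) {
  if (inner_radius < 0 || outer_radius <= 0 || length <= 0)
    stop("invalid geometry: radii and length must be positive")
  if (inner_radius >= outer_radius)
    stop("invalid geometry: inner_radius must be < outer_radius")
  if (voxel_size * 1e-3 > (outer_radius - inner_radius))
    warning("under-resolved: voxel size exceeds wall thickness")
  h <- voxel_size * 1e-3                      # mm per voxel
  half <- outer_radius + margin
  nxy <- ceiling(2 * half / h)
  nz <- max(1L, round(length / h))
  cx <- (seq_len(nxy) - 0.5) * h - half       # centered on the axis
  r2 <- outer(cx^2, cx^2, "+")
  ann2d <- r2 <= outer_radius^2 & r2 > inner_radius^2
  mask <- array(ann2d, dim = c(nxy, nxy, nz))
  data <- array(0, dim = dim(mask))
  with_op_seed(seed, "cortical_tube", {
    nb <- sum(mask)
    data[mask] <- rnorm(nb, tmd_mean, tmd_sd)
    pores <- logical(nb)
    if (porosity > 0) {
      pores[sample.int(nb, round(porosity * nb))] <- TRUE
      idx <- which(mask)
      data[idx[pores]] <- 0
      mask[idx[pores]] <- FALSE
    }
    if (noise_sd > 0) data <- data + rnorm(base::length(data), 0, noise_sd)
    vol <- voxel_volume(data, voxel_size)
    truth <- list(
      ct_ar = pi * (outer_radius^2 - inner_radius^2) * (1 - porosity),
      tt_ar = pi * outer_radius^2,
      ct_th = outer_radius - inner_radius,
      i_min = pi / 4 * (outer_radius^4 - inner_radius^4),
      z_min = pi / 4 * (outer_radius^4 - inner_radius^4) / outer_radius,
      ct_po = sum(pores) / nb,
      tmd_mean = tmd_mean,
      outer_radius = outer_radius, inner_radius = inner_radius)
    list(volume = vol, mask = mask, truth = truth)
  })
}

# first Betti number of the full orthogonal rod-lattice graph:
# nodes at grid vertices, edges along every cell edge, one component
lattice_betti1 <- function(n) {
  v <- prod(n + 1L)
  e <- n[1] * (n[2] + 1L) * (n[3] + 1L) +
       n[2] * (n[1] + 1L) * (n[3] + 1L) +
       n[3] * (n[1] + 1L) * (n[2] + 1L)
  as.integer(e - v + 1L)
}

#' Trabecular lattice phantom
#'
#' Orthogonal lattice of cylindrical rods (diameter `rod_diameter`, pitch
#' `pitch`) along all three axes, the classic idealization of rod-like
#' trabecular bone.  Ground-truth morphometry is known in closed form:
#' Tb.Th = rod diameter, Tb.Sp = pitch - diameter, Tb.N = 1/pitch, BV/TV from
#' the voxelized rod-union count, and Conn.D from the lattice graph's first
#' Betti number.
#'
#' @param rod_diameter,pitch rod diameter and lattice pitch, mm
#'   (`rod_diameter < pitch`).
#' @param n_cells number of lattice cells per axis (length 1 or 3).
#' @param fill if `TRUE`, generate a fully solid block instead of a lattice
#'   (BV/TV ground truth 1).
#' @inheritParams make_cortical_tube_phantom
#' @return list with `volume`, `mask`, and `truth` (`bvtv`, `tb_th`, `tb_sp`,
#'   `tb_n`, `conn_d`, `betti1`, `tv_mm3`).
#' @export
make_trabecular_lattice_phantom <- function(rod_diameter = 0.06, pitch = 0.30,
                                            n_cells = 2L, voxel_size = 12,
                                            tmd_mean = 900, tmd_sd = 0,
                                            noise_sd = 0, fill = FALSE,
                                            margin = pitch / 4, seed = 1) {
  if (!fill && rod_diameter >= pitch)
    stop("invalid geometry: rod_diameter must be < pitch")
  if (rod_diameter <= 0 || pitch <= 0) stop("invalid geometry")
  n_cells <- rep(as.integer(n_cells), length.out = 3L)
  h <- voxel_size * 1e-3
  ext <- n_cells * pitch + 2 * margin       # physical extent, mm
  nd <- pmax(2L, round(ext / h))
  cc <- lapply(1:3, function(a) (seq_len(nd[a]) - 0.5) * h - margin)
  r <- rod_diameter / 2
  if (fill) {
    mask <- array(TRUE, dim = nd)
  } else {
    # distance of each voxel center to the nearest lattice *plane* per axis
    dist_to_grid <- function(x, a) {
      gmax <- n_cells[a] * pitch
      xx <- pmin(pmax(x, 0), gmax)              # clamp to lattice span
      d1 <- abs(xx - round(xx / pitch) * pitch)
      out <- abs(x - pmin(pmax(x, 0), gmax))    # distance outside the span
      sqrt(d1^2 + out^2)
    }
    dx <- dist_to_grid(cc[[1]], 1); dy <- dist_to_grid(cc[[2]], 2)
    dz <- dist_to_grid(cc[[3]], 3)
    # rods along x exist where (y,z) is near a grid line intersection
    in_x <- outer(dy^2, dz^2, "+") <= r^2   # ny x nz
    in_y <- outer(dx^2, dz^2, "+") <= r^2   # nx x nz
    in_z <- outer(dx^2, dy^2, "+") <= r^2   # nx x ny
    mask <- array(FALSE, dim = nd)
    for (k in seq_len(nd[3])) {
      sl <- matrix(FALSE, nd[1], nd[2])
      sl <- sl | outer(rep(TRUE, nd[1]), in_x[, k])  # x-rods
      sl <- sl | outer(in_y[, k], rep(TRUE, nd[2]))  # y-rods
      sl <- sl | in_z
      mask[, , k] <- sl
    }
    # restrict rods to the lattice span along their own axis
    inx <- cc[[1]] >= -r & cc[[1]] <= n_cells[1] * pitch + r
    iny <- cc[[2]] >= -r & cc[[2]] <= n_cells[2] * pitch + r
    inz <- cc[[3]] >= -r & cc[[3]] <= n_cells[3] * pitch + r
    keep <- outer(outer(inx, iny, "&"), inz, "&")
    mask <- mask & keep
  }
  data <- array(0, dim = nd)
  with_op_seed(seed, "trabecular_lattice", {
    data[mask] <- rnorm(sum(mask), tmd_mean, tmd_sd)
    if (noise_sd > 0) data <- data + rnorm(length(data), 0, noise_sd)
  })
  tv <- prod(nd) * h^3
  b1 <- if (fill) 0L else lattice_betti1(n_cells)
  truth <- list(
    bvtv = sum(mask) / prod(nd),
    tb_th = if (fill) NA_real_ else rod_diameter,
    tb_sp = if (fill) NA_real_ else pitch - rod_diameter,
    tb_n = if (fill) NA_real_ else 1 / pitch,
    betti1 = b1, conn_d = b1 / tv, tv_mm3 = tv,
    tmd_mean = tmd_mean)
  list(volume = voxel_volume(data, voxel_size), mask = mask, truth = truth)
}

#' Vertebral body phantom
#'
#' Elliptical cortical shell enclosing a trabecular rod lattice, with flat
#' cranial/caudal end plates: a minimal stand-in for an L5 vertebral centrum
#' used to exercise the micro-FE chain.  Shell and rods may carry different
#' tissue mineral densities, giving a known per-bin voxel count for any TMD
#' binning.
#'
#' @param semi_axes outer in-plane semi-axes of the elliptical shell, mm
#'   (length 2).
#' @param height body height along z, mm.
#' @param shell_thickness cortical shell (and end-plate) thickness, mm.
#' @param tmd_shell,tmd_rods tissue mineral densities, mg HA/cm^3.
#' @param rod_diameter,pitch trabecular lattice geometry, mm.
#' @inheritParams make_cortical_tube_phantom
#' @return list with `volume`, `mask`, and `truth` (`n_bone`, `n_shell`,
#'   `n_rods`, `n_slices`).
#' @export
make_vertebral_phantom <- function(semi_axes = c(0.9, 0.7), height = 1.2,
                                   shell_thickness = 0.08,
                                   tmd_shell = 1100, tmd_rods = 800,
                                   rod_diameter = 0.06, pitch = 0.24,
                                   voxel_size = 12, noise_sd = 0,
                                   margin = 0.06, seed = 1) {
  if (any(semi_axes <= 0) || height <= 0 || shell_thickness <= 0)
    stop("invalid geometry")
  if (shell_thickness < voxel_size * 1e-3)
    warning("under-resolved: shell thinner than one voxel")
  h <- voxel_size * 1e-3
  half <- semi_axes + margin
  nx <- ceiling(2 * half[1] / h); ny <- ceiling(2 * half[2] / h)
  nz <- round((height + 2 * margin) / h)
  cx <- (seq_len(nx) - 0.5) * h - half[1]
  cy <- (seq_len(ny) - 0.5) * h - half[2]
  cz <- (seq_len(nz) - 0.5) * h - margin       # 0 .. height spans the body
  el <- function(a, b) outer((cx / a)^2, (cy / b)^2, "+") <= 1
  outer2d <- el(semi_axes[1], semi_axes[2])
  inner2d <- el(semi_axes[1] - shell_thickness, semi_axes[2] - shell_thickness)
  ring2d <- outer2d & !inner2d
  inside_z <- cz >= 0 & cz <= height
  plate_z <- inside_z & (cz <= shell_thickness | cz >= height - shell_thickness)
  # trabecular rod lattice clipped to the inner ellipse
  r <- rod_diameter / 2
  dgrid <- function(x) abs(x - round(x / pitch) * pitch)
  dx <- dgrid(cx); dy <- dgrid(cy); dz <- dgrid(cz)
  in_x <- outer(dy^2, dz^2, "+") <= r^2
  in_y <- outer(dx^2, dz^2, "+") <= r^2
  in_z <- outer(dx^2, dy^2, "+") <= r^2
  shell <- array(FALSE, c(nx, ny, nz)); rods <- shell
  for (k in seq_len(nz)) {
    if (!inside_z[k]) next
    sh <- ring2d | (plate_z[k] & outer2d)
    rd <- (outer(rep(TRUE, nx), in_x[, k]) |
           outer(in_y[, k], rep(TRUE, ny)) | in_z) & inner2d & !sh
    shell[, , k] <- sh
    rods[, , k] <- rd
  }
  mask <- shell | rods
  data <- array(0, c(nx, ny, nz))
  data[shell] <- tmd_shell
  data[rods] <- tmd_rods
  with_op_seed(seed, "vertebral_body", {
    if (noise_sd > 0) data <- data + rnorm(length(data), 0, noise_sd)
  })
  truth <- list(n_bone = sum(mask), n_shell = sum(shell), n_rods = sum(rods),
                n_slices = sum(inside_z),
                tmd_shell = tmd_shell, tmd_rods = tmd_rods)
  list(volume = voxel_volume(data, voxel_size), mask = mask, truth = truth)
}

#' Simulate a CPMG echo train
#'
#' Multi-compartment mono-exponential transverse relaxation decay, as acquired
#' by a Carr-Purcell-Meiboom-Gill sequence: the amplitude of echo k at time
#' `t_k = k * echo_spacing` is `sum_j c * v_j * exp(-t_k / T2_j)` plus
#' additive Gaussian noise (a Rician option is available for magnitude data;
#' at high SNR the two are indistinguishable).
#'
#' @param compartments data frame with columns `volume_ul` and `t2_s`.
#' @param echo_spacing echo spacing, seconds (default 100 us).
#' @param n_echoes number of echoes (default 10000).
#' @param noise_sd additive noise standard deviation, a.u.
#' @param signal_per_ul proportionality constant between water volume and
#'   extrapolated t = 0 signal.
#' @param rician if `TRUE`, apply magnitude (Rician) noise instead of
#'   additive Gaussian.
#' @param seed integer seed.
#' @return object of class `cpmg_signal`: list with `echo_times`,
#'   `amplitudes`, `echo_spacing`, `n_echoes`.
#' @export
simulate_cpmg_signal <- function(compartments, echo_spacing = 100e-6,
                                 n_echoes = 10000L, noise_sd = 0,
                                 signal_per_ul = 1, rician = FALSE, seed = 1) {
  if (n_echoes < 2L) stop("invalid: n_echoes must be >= 2")
  if (noise_sd < 0) stop("invalid: noise_sd must be >= 0")
  if (echo_spacing <= 0) stop("invalid: echo_spacing must be > 0")
  if (nrow(compartments) > 0) {
    if (any(compartments$volume_ul < 0)) stop("compartment volumes must be >= 0")
    if (any(compartments$t2_s <= 0)) stop("compartment T2 must be > 0")
  }
  t <- seq_len(n_echoes) * echo_spacing
  s <- numeric(n_echoes)
  for (j in seq_len(nrow(compartments)))
    s <- s + signal_per_ul * compartments$volume_ul[j] *
      exp(-t / compartments$t2_s[j])
  with_op_seed(seed, "cpmg", {
    if (noise_sd > 0) {
      if (rician) s <- sqrt((s + rnorm(n_echoes, 0, noise_sd))^2 +
                            rnorm(n_echoes, 0, noise_sd)^2)
      else s <- s + rnorm(n_echoes, 0, noise_sd)
    }
  })
  structure(list(echo_times = t, amplitudes = s, echo_spacing = echo_spacing,
                 n_echoes = n_echoes),
            class = "cpmg_signal")
}

# continuous piecewise bending model used by the curve generator; returns
# force (N) at displacement d (mm) plus the breakpoints
bending_model <- function(stiffness, yield_force, ultimate_force,
                          post_yield_displacement, failure_drop_fraction,
                          hardening_fraction = 0.4, toe_displacement = 0) {
  d_y <- yield_force / stiffness
  d_fail <- d_y + post_yield_displacement
  d_u <- d_y + hardening_fraction * post_yield_displacement
  f_end <- failure_drop_fraction * ultimate_force
  t0 <- toe_displacement
  shift <- t0 / 2                     # linear-region back-extrapolated origin
  force <- function(d) {
    dd <- d - shift                   # displacement in the model frame
    f <- numeric(length(d))
    if (t0 > 0) {
      toe <- d <= t0
      f[toe] <- stiffness * d[toe]^2 / (2 * t0)
    } else toe <- rep(FALSE, length(d))
    lin <- !toe & dd <= d_y
    f[lin] <- stiffness * dd[lin]
    if (post_yield_displacement > 0) {
      hard <- !toe & dd > d_y & dd <= d_u
      f[hard] <- ultimate_force - (ultimate_force - yield_force) *
        ((d_u - dd[hard]) / (d_u - d_y))^2
      dec <- !toe & dd > d_u & dd <= d_fail
      f[dec] <- ultimate_force + (f_end - ultimate_force) *
        (dd[dec] - d_u) / (d_fail - d_u)
      f[dd > d_fail] <- 0
    } else f[dd > d_y] <- 0
    f
  }
  list(force = force, d_y = d_y + shift, d_u = d_u + shift,
       d_fail = d_fail + shift, shift = shift, f_end = f_end)
}

#' Simulate a three-point-bending load-displacement curve
#'
#' Piecewise structural model: optional quadratic toe-in, linear ramp at
#' `stiffness` to the yield force, quadratic work-hardening to the ultimate
#' force, linear decay over the post-yield displacement, and termination at
#' `failure_drop_fraction * ultimate_force`.  The returned ground truth
#' contains both the model breakpoints and the analytic values of every
#' property *as defined by the curve-analysis criteria* (0.9-secant yield,
#' trapezoidal work), computed in closed form / by root finding on the
#' continuous model, so recovery from sampled data can be tested without
#' circularity.
#'
#' @param stiffness linear-region slope, N/mm.
#' @param yield_force force at departure from linearity, N.
#' @param ultimate_force peak force, N (>= `yield_force`).
#' @param post_yield_displacement displacement between the linearity limit and
#'   failure, mm.
#' @param failure_drop_fraction terminal force as a fraction of ultimate.
#' @param sampling_rate samples per mm of displacement.
#' @param noise_sd additive force noise, N.
#' @param toe_displacement extent of the compliant toe-in region, mm.
#' @param span support span, mm (carried as metadata; 8 mm in the femur
#'   three-point-bending protocol).
#' @param seed integer seed.
#' @return list with `curve` (class `load_displacement_curve`) and `truth`.
#' @export
simulate_bending_curve <- function(stiffness = 112, yield_force = 14.2,
                                   ultimate_force = 15.7,
                                   post_yield_displacement = 0.25,
                                   failure_drop_fraction = 0.3,
                                   sampling_rate = 2000, noise_sd = 0,
                                   toe_displacement = 0, span = 8,
                                   test_kind = "bend_3pt", seed = 1) {
  if (stiffness <= 0 || yield_force <= 0) stop("invalid curve specification")
  if (ultimate_force < yield_force)
    stop("invalid: ultimate_force must be >= yield_force")
  if (post_yield_displacement < 0) stop("invalid: post_yield_displacement < 0")
  if (post_yield_displacement == 0 && ultimate_force != yield_force)
    stop("invalid: with zero post-yield displacement, yield and ultimate coincide")
  m <- bending_model(stiffness, yield_force, ultimate_force,
                     post_yield_displacement, failure_drop_fraction,
                     toe_displacement = toe_displacement)
  d_end <- m$d_fail
  d <- seq(0, d_end, by = 1 / sampling_rate)
  if (sum(d <= m$d_y) < 10L)
    stop("invalid: sampling too coarse to place the yield point")
  f <- m$force(d)
  with_op_seed(seed, "bending_curve", {
    if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  })
  # analytic criterion values on the continuous model: first 0.9-secant
  # crossing on the ascending limb, else the ultimate point (the analyzer's
  # convention for curves whose secant never drops before the peak)
  shift <- m$shift
  secant_gap <- function(d) m$force(d) - 0.9 * stiffness * (d - shift)
  d_yield_crit <- if (post_yield_displacement > 0) {
    if (secant_gap(m$d_u) < 0) {
      uniroot(secant_gap, c(m$d_y + 1e-12, m$d_u), tol = 1e-12)$root
    } else m$d_u
  } else m$d_y
  f_yield_crit <- m$force(d_yield_crit)
  area <- function(lo, hi) {
    if (hi <= lo) return(0)
    stats::integrate(m$force, lo, hi, subdivisions = 2000L,
                     rel.tol = 1e-10)$value
  }
  w_f <- area(shift, d_end)
  py_wf <- area(d_yield_crit, d_end)
  curve <- structure(list(displacement = d, force = f, test_kind = test_kind,
                          span = span, loading_rate = 3),
                     class = "load_displacement_curve")
  truth <- list(stiffness = stiffness, yield_force = f_yield_crit,
                ultimate_force = ultimate_force,
                pyd = d_end - d_yield_crit, w_f = w_f, py_wf = py_wf,
                d_yield = d_yield_crit, d_failure = d_end,
                yield_force_model = yield_force, d_yield_model = m$d_y,
                toe_shift = shift)
  list(curve = curve, truth = truth)
}

#' Simulate a two-factor cohort table
#'
#' One row per specimen in the 2 x 3 design (canagliflozin pre-treatment x
#' glucose group).  Default cell locations and spreads are patterned on the
#' published end-point blood-glucose medians (mg/dl) and interquartile ranges
#' of the six cells; per-cell sample sizes default to the study's group sizes.
#' Noise families: `gaussian` (location + scale * N(0,1)), `lognormal`
#' (location * exp(scale * N(0,1)); median = location, right-skewed) and
#' `scaled_t` (location + scale * t_3; heavy-tailed).
#'
#' @param n_per_cell integer vector of 6 cell sizes (order: NoCana x
#'   (ND-Palm, T1D-Palm, T1D-Ins), then Cana x (...)), or a single integer.
#' @param cell_location,cell_scale numeric vectors of 6 per-cell centers and
#'   spreads (outcome units).
#' @param noise_family one of `"gaussian"`, `"lognormal"`, `"scaled_t"`.
#' @param outcome_name column name for the outcome.
#' @param seed integer seed.
#' @return data frame with columns `specimen_id`, `cana`, `group`, and the
#'   outcome column.
#' @export
simulate_cohort_table <- function(n_per_cell = c(10L, 8L, 10L, 10L, 6L, 14L),
                                  cell_location = c(176, 723, 280, 174, 727, 324),
                                  cell_scale = c(4.5, 23, 81, 9.6, 49, 133),
                                  noise_family = c("gaussian", "lognormal",
                                                   "scaled_t"),
                                  outcome_name = "outcome", seed = 1) {
  noise_family <- match.arg(noise_family)
  n_per_cell <- rep(as.integer(n_per_cell), length.out = 6L)
  if (any(n_per_cell < 2L)) stop("invalid: n_per_cell must be >= 2")
  cell_location <- rep(as.numeric(cell_location), length.out = 6L)
  cell_scale <- rep(as.numeric(cell_scale), length.out = 6L)
  if (any(cell_scale < 0)) stop("invalid: cell_scale must be >= 0")
  cana_lv <- c("NoCana", "Cana")
  grp_lv <- c("ND-Palm", "T1D-Palm", "T1D-Ins")
  cells <- expand.grid(group = grp_lv, cana = cana_lv,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("cana", "group")]
  with_op_seed(seed, "cohort", {
    rows <- lapply(seq_len(6L), function(i) {
      n <- n_per_cell[i]; loc <- cell_location[i]; sc <- cell_scale[i]
      y <- switch(noise_family,
        gaussian = loc + sc * rnorm(n),
        lognormal = loc * exp(sc / max(loc, .Machine$double.eps) * rnorm(n)),
        scaled_t = loc + sc * rt(n, df = 3))
      data.frame(cana = cells$cana[i], group = cells$group[i], y = y)
    })
    tab <- do.call(rbind, rows)
    tab <- data.frame(specimen_id = sprintf("S%03d", seq_len(nrow(tab))),
                      cana = factor(tab$cana, levels = cana_lv),
                      group = factor(tab$group, levels = grp_lv),
                      y = tab$y)
    names(tab)[names(tab) == "y"] <- outcome_name
    tab
  })
}
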