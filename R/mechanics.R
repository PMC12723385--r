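# Closed-form escape mechanics: grip contact area and friction, friction
# coefficient from the slide angle, elliptical body-section areas, pressure
# drag, mass x acceleration, Reynolds number, and the lever escape model.

#' Grip model parameters
#'
#' @param mu friction coefficient between tadpole skin and forceps steel
#'   (default 0.08, from a 4.5 degree slide angle).
#' @param E elastic modulus of the head tissue, Pa (default 700).
#' @param area_coeffs contact-area law coefficients `c(slope, intercept)`
#'   in mm^2 per compression fraction: A = slope x dw + intercept
#'   (default `c(1.35, -0.0043)`).
#' @param fitted_coeffs measured-friction fit `c(quadratic, linear)` in uN
#'   (default `c(49, 19.8)`).
#' @param head_width head width in mm (default 0.83); compression `dw` is
#'   expressed as a fraction of it.
#' @return list of class `grip_model`.
#' @export
grip_model <- function(mu = 0.08, E = 700, area_coeffs = c(1.35, -0.0043),
                       fitted_coeffs = c(49, 19.8), head_width = 0.83) {
  stopifnot(mu > 0, E > 0, head_width > 0)
  structure(list(mu = mu, E = E, area_coeffs = area_coeffs,
                 fitted_coeffs = fitted_coeffs, head_width = head_width),
            class = "grip_model")
}

#' Body model parameters
#'
#' @param body_length body length, mm (default 5).
#' @param total_side_area side-view body area, mm^2 (default 4.95).
#' @param zeta dimensionless pressure-drag shape coefficient (default 1.18,
#'   elliptical coronal section).
#' @param water_density kg/m^3 (default 1000).
#' @param dynamic_viscosity Pa.s (default 0.00089, water at 20-25 C).
#' @param total_mass_mg total body mass in mg (default 141.41; 14141
#'   particles of 10 ug in the reference biomechanical model).
#' @param section_masses_ug optional per-section masses in ug; default:
#'   proportional to the elliptical section areas of a 10-section partition,
#'   normalized to `total_mass_mg`.
#' @param n_sections number of body sections (default 10, the inter-point
#'   segments of an 11-point midline).
#' @return list of class `body_model` with derived ellipse semi-axes
#'   `a = body_length/2` and `b = total_side_area/(pi a)`, section bounds
#'   (mm from head), section areas (mm^2) and masses (ug).
#' @export
body_model <- function(body_length = 5, total_side_area = 4.95,
                       zeta = 1.18, water_density = 1000,
                       dynamic_viscosity = 0.00089,
                       total_mass_mg = 141.41, section_masses_ug = NULL,
                       n_sections = 10) {
  a <- body_length / 2
  b <- total_side_area / (pi * a)
  bounds <- seq(0, body_length, length.out = n_sections + 1)
  areas <- section_areas_ellipse(a, b, bounds - a)
  if (is.null(section_masses_ug))
    section_masses_ug <- areas / sum(areas) * total_mass_mg * 1000
  stopifnot(length(section_masses_ug) == n_sections,
            all(section_masses_ug > 0))
  structure(list(body_length = body_length,
                 total_side_area = total_side_area, zeta = zeta,
                 water_density = water_density,
                 dynamic_viscosity = dynamic_viscosity,
                 a = a, b = b, section_bounds = bounds,
                 section_areas = areas,
                 section_masses = section_masses_ug),
            class = "body_model")
}

#' Grip contact area
#'
#' Contact area between the forceps inner surface and one side of the head
#' as a function of head compression: A(dw) = 1.35 dw - 0.0043 mm^2, with
#' dw the compressed distance as a fraction of head width, clamped at 0
#' below the small positive root.
#'
#' @param dw compression fraction of head width, in `[0, 1)`.
#' @param grip a [grip_model()].
#' @return contact area in mm^2.
#' @export
contact_area <- function(dw, grip = grip_model()) {
  if (any(dw < 0 | dw >= 1)) stop("dw must be in [0, 1)")
  pmax(0, grip$area_coeffs[1] * dw + grip$area_coeffs[2])
}

#' Hooke-law grip friction
#'
#' Friction from the compression force of an elastic grip:
#' F = 2 mu E A(dw) dw. At the default mu = 0.08, E = 700 Pa and
#' A = 1.35 dw - 0.0043 this expands to 151.2 dw^2 - 0.48 dw (uN), clamped
#' at 0.
#'
#' @inheritParams contact_area
#' @return friction in uN.
#' @export
hooke_friction <- function(dw, grip = grip_model()) {
  if (any(dw < 0 | dw >= 1)) stop("dw must be in [0, 1)")
  pmax(0, 2 * grip$mu * grip$E * contact_area(dw, grip) * dw)
}

#' Coefficients of the expanded Hooke friction polynomial
#'
#' Symbolic expansion of 2 mu E (a1 dw + a0) dw = (2 mu E a1) dw^2 +
#' (2 mu E a0) dw; at the defaults the quadratic and linear coefficients
#' are 151.2 and -0.48 uN.
#'
#' @param grip a [grip_model()].
#' @return named vector `c(quadratic, linear)`.
#' @export
hooke_coefficients <- function(grip = grip_model()) {
  c(quadratic = 2 * grip$mu * grip$E * grip$area_coeffs[1],
    linear = 2 * grip$mu * grip$E * grip$area_coeffs[2])
}

#' Measured (fitted) grip friction
#'
#' Friction fitted to simulated pull-off measurements with the ridged
#' forceps: F(dw) = 49 dw^2 + 19.8 dw (uN).
#'
#' @inheritParams contact_area
#' @return friction in uN.
#' @export
fitted_friction <- function(dw, grip = grip_model()) {
  if (any(dw < 0 | dw >= 1)) stop("dw must be in [0, 1)")
  grip$fitted_coeffs[1] * dw^2 + grip$fitted_coeffs[2] * dw
}

#' Friction coefficient from the slide angle
#'
#' At the tilt angle where the animal starts to slide, friction balances
#' gravity along the surface: mu = tan(alpha).
#'
#' @param slide_angle angle in degrees, in (0, 90).
#' @return dimensionless friction coefficient.
#' @export
friction_coefficient <- function(slide_angle) {
  if (any(slide_angle <= 0 | slide_angle >= 90))
    stop("slide_angle must be in (0, 90) degrees")
  tan(slide_angle * pi / 180)
}

# Closed-form area of the full-height elliptical slab between centred
# x-coordinates (ellipse x^2/a^2 + y^2/b^2 = 1):
# 2 int_b sqrt(1 - x^2/a^2) dx = (b/a) [x sqrt(a^2-x^2) + a^2 asin(x/a)].
section_areas_ellipse <- function(a, b, bounds) {
  F <- function(x) (b / a) * (x * sqrt(pmax(0, a^2 - x^2)) +
                              a^2 * asin(pmin(1, pmax(-1, x / a))))
  diff(F(bounds))
}

#' Elliptical body-section areas
#'
#' The side-view tadpole outline is approximated by an ellipse with
#' semi-axes `a = body_length/2` and `b` chosen so the full area equals the
#' total side area; section areas are closed-form integrals of the ellipse
#' between the section bounds.
#'
#' @param body a [body_model()].
#' @param n_sections number of equal sections to partition `span` into.
#' @param span `c(from, to)` in mm from the head (default: whole body).
#' @return numeric vector of section areas in mm^2.
#' @export
section_areas <- function(body = body_model(), n_sections = 10,
                          span = NULL) {
  if (is.null(span)) span <- c(0, body$body_length)
  if (span[1] < 0 - 1e-9 || span[2] > body$body_length + 1e-9)
    stop("span must lie within [0, body_length]")
  bounds <- seq(span[1], span[2], length.out = n_sections + 1) - body$a
  section_areas_ellipse(body$a, body$b, bounds)
}

#' Reynolds number
#'
#' Re = rho v L / mu for flow speed `v` (m/s) and characteristic length `L`
#' (m) in water of density rho and dynamic viscosity mu.
#'
#' @param v flow speed, m/s (>= 0).
#' @param L characteristic length, m (>= 0).
#' @param body a [body_model()] supplying rho and mu.
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(v, L, body = body_model()) {
  if (any(v < 0) || any(L < 0)) stop("v and L must be >= 0")
  body$water_density * v * L / body$dynamic_viscosity
}

#' Per-section pressure drag from tracked motion
#'
#' Each of the 10 body sections between consecutive tracked points is
#' treated as a rigid slab with the side area of the elliptical body model.
#' Per frame and section, the centre velocity is the average of the two
#' end-point velocities; the drag magnitude is zeta A_proj rho v^2 / 2
#' directed opposite the velocity, with projected area A_proj =
#' A sin(theta), theta the angle between the section axis and the velocity
#' (equivalently the cosine of the angle to the section normal: the full
#' side area is presented when moving broadside). Frames where a section
#' moves nearly parallel to its own axis are flagged low-validity; the
#' calculation assumes broadside motion.
#'
#' @param body a [body_model()].
#' @param tracked a [tracked_body()] (2D points get z = 0).
#' @param parallel_deg sections moving within this angle of their axis are
#'   flagged (default 20 degrees).
#' @return list with `total`: data.frame (time, Fx, Fy, Fz, Fmag; uN),
#'   `per_section`: array frames x sections x 3 (uN), `low_validity`:
#'   logical matrix frames x sections.
#' @export
pressure_drag <- function(body, tracked, parallel_deg = 20) {
  pts <- pad_z(tracked$points)
  nfr <- dim(pts)[1]
  nsec <- length(body$section_areas)
  dt <- 1 / tracked$frame_rate
  vel <- array(NA_real_, dim(pts))   # mm/s, central differences
  if (nfr >= 3)
    vel[2:(nfr - 1), , ] <- (pts[3:nfr, , , drop = FALSE] -
                             pts[1:(nfr - 2), , , drop = FALSE]) / (2 * dt)
  drag <- array(0, c(nfr, nsec, 3))
  lowv <- matrix(FALSE, nfr, nsec)
  rho <- body$water_density
  for (s in seq_len(nsec)) {
    axis <- pts[, s + 1, ] - pts[, s, ]                       # mm
    vsec <- (vel[, s, ] + vel[, s + 1, ]) / 2                 # mm/s
    vmag <- sqrt(rowSums(vsec^2))
    amag <- sqrt(rowSums(axis^2))
    cospar <- abs(rowSums(axis * vsec)) / (amag * vmag)
    cospar[!is.finite(cospar)] <- NA_real_
    sintheta <- sqrt(pmax(0, 1 - cospar^2))
    lowv[, s] <- !is.na(cospar) & cospar > cos(parallel_deg * pi / 180)
    ok <- which(is.finite(vmag) & vmag > 0 & amag > 0)
    if (!length(ok)) next
    aproj <- body$section_areas[s] * sintheta[ok] * 1e-6      # m^2
    v_ms <- vmag[ok] / 1000                                   # m/s
    dmag <- body$zeta * aproj * rho * v_ms^2 / 2 * 1e6        # uN
    drag[ok, s, ] <- -dmag / vmag[ok] * vsec[ok, , drop = FALSE]
  }
  tot <- apply(drag, c(1, 3), sum)
  list(total = data.frame(time = tracked$times, Fx = tot[, 1],
                          Fy = tot[, 2], Fz = tot[, 3],
                          Fmag = sqrt(rowSums(tot^2))),
       per_section = drag, low_validity = lowv)
}

pad_z <- function(pts) {
  if (dim(pts)[3] == 3) return(pts)
  out <- array(0, c(dim(pts)[1], dim(pts)[2], 3))
  out[, , 1:2] <- pts
  out
}

#' Mass x acceleration of the moving body
#'
#' Per-section acceleration by central second differences of the section
#' mass centres (midpoints of consecutive tracked points), optionally after
#' a zero-phase low-pass of the coordinates, multiplied by the section
#' masses and summed over sections.
#'
#' @param body a [body_model()].
#' @param tracked a [tracked_body()] with at least 3 frames and uniform
#'   frame times.
#' @param lowpass_hz optional coordinate low-pass cutoff in Hz (NULL to
#'   skip).
#' @return list with `total`: data.frame (time, Fx, Fy, Fz, Fmag; uN) and
#'   `per_section`: array frames x sections x 3 (uN).
#' @export
mass_acceleration <- function(body, tracked, lowpass_hz = NULL) {
  nfr <- dim(tracked$points)[1]
  if (nfr < 3) stop("at least 3 frames are required")
  dtv <- diff(tracked$times)
  if (max(abs(dtv - 1 / tracked$frame_rate)) > 0.5 / tracked$frame_rate)
    stop("frame times must be uniform")
  pts <- pad_z(tracked$points)
  if (!is.null(lowpass_hz)) {
    bf <- signal::butter(4, lowpass_hz / (tracked$frame_rate / 2), "low")
    for (p in seq_len(dim(pts)[2]))
      for (d in 1:3)
        pts[, p, d] <- signal::filtfilt(bf, pts[, p, d])
  }
  nsec <- length(body$section_masses)
  dt <- 1 / tracked$frame_rate
  force <- array(0, c(nfr, nsec, 3))
  for (s in seq_len(nsec)) {
    ctr <- (pts[, s, ] + pts[, s + 1, ]) / 2                  # mm
    acc <- matrix(NA_real_, nfr, 3)
    acc[2:(nfr - 1), ] <- (ctr[3:nfr, ] - 2 * ctr[2:(nfr - 1), ] +
                           ctr[1:(nfr - 2), ]) / dt^2         # mm/s^2
    # ug * mm/s^2 = 1e-9 kg * 1e-3 m/s^2 = 1e-12 N = 1e-6 uN
    f <- body$section_masses[s] * acc * 1e-6                  # uN
    f[is.na(f)] <- 0
    force[, s, ] <- f
  }
  tot <- apply(force, c(1, 3), sum)
  list(total = data.frame(time = tracked$times, Fx = tot[, 1],
                          Fy = tot[, 2], Fz = tot[, 3],
                          Fmag = sqrt(rowSums(tot^2))),
       per_section = force)
}

#' Lever model of the escape force
#'
#' The stiffened rostral trunk pivots on the forceps tip: the momentum
#' force F1 of the moving posterior segments, acting at lever arm L1,
#' produces F2 = F1 L1 / L2 at the head, whose axial component
#' F2x = F2 cos(alpha) opposes the grip friction; the animal escapes when
#' F2x exceeds the friction.
#'
#' @param F1 mass x acceleration of the moving segments, uN.
#' @param L1,L2 lever arm lengths, mm (> 0).
#' @param alpha angle between F2 and the forceps axis, degrees in
#'   `[0, 90)`.
#' @param friction grip friction, uN.
#' @return list with `F2`, `F2x` (uN) and `escapes` (logical).
#' @export
lever_escape <- function(F1, L1, L2, alpha = 0, friction = 0) {
  if (any(L1 <= 0) || any(L2 <= 0)) stop("L1 and L2 must be > 0")
  if (any(alpha < 0 | alpha >= 90)) stop("alpha must be in [0, 90) degrees")
  F2 <- F1 * L1 / L2
  F2x <- F2 * cos(alpha * pi / 180)
  list(F2 = F2, F2x = F2x, escapes = F2x > friction)
}
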