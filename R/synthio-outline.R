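#' Specify a synthetic hip outline
#'
#' Builds the parameter set for [generate_hip_outline()]. The construction
#' places a spherical femoral head (a circle in the 2-D projection), a waisted
#' femoral neck attached along `neck_axis_angle`, and, optionally, a cam bump:
#' a radial excess that starts exactly `cam_onset_angle` degrees from the neck
#' axis, so the ground-truth alpha angle of the shape is known by design.
#'
#' Angles are measured counter-clockwise from the neck axis; the superior
#' (measurement) side of the head covers 0--180 degrees.
#'
#' @param head_radius Radius of the femoral head circle (arbitrary length
#'   units, > 0).
#' @param head_center Numeric length-2 centre of the head circle.
#' @param neck_axis_angle Direction, in degrees, from the head centre toward
#'   the femoral neck midpoint.
#' @param neck_half_width Half-width of the neck at its narrowest point; must
#'   be smaller than `head_radius`.
#' @param cam_onset_angle Angle from the neck axis, in degrees in (0, 180), at
#'   which the contour departs the head circle. When `cam_amplitude > 0` this
#'   is the constructed ground-truth alpha angle.
#' @param cam_amplitude Radial excess of the cam bump in length units (>= 0).
#'   Zero gives a spherical head whose ground-truth alpha angle is the
#'   neck-contour/circle crossing angle.
#' @param osteophyte_arc Optional `list(start, end, amplitude)`: an angular
#'   interval (degrees from the neck axis) whose points are displaced radially
#'   outward by `amplitude` and flagged as osteophyte.
#' @param noise_sd Standard deviation of isotropic Gaussian jitter added to
#'   every point (length units).
#' @param n_points Total number of contour points (>= 20).
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   outlines.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(head_radius = 1, head_center = c(0, 0),
                       neck_axis_angle = 225, neck_half_width = 0.45,
                       cam_onset_angle = 50, cam_amplitude = 0,
                       osteophyte_arc = NULL, noise_sd = 0,
                       n_points = 160, seed = 1) {
  check_num(head_radius, "head_radius", lower = 0, strict_lower = TRUE, len = 1)
  check_num(head_center, "head_center", len = 2)
  check_num(neck_axis_angle, "neck_axis_angle", len = 1)
  check_num(neck_half_width, "neck_half_width", lower = 0, upper = head_radius,
            strict_lower = TRUE, strict_upper = TRUE, len = 1)
  check_num(cam_onset_angle, "cam_onset_angle", lower = 0, upper = 180,
            strict_lower = TRUE, strict_upper = TRUE, len = 1)
  check_num(cam_amplitude, "cam_amplitude", lower = 0, len = 1)
  check_num(noise_sd, "noise_sd", lower = 0, len = 1)
  check_num(n_points, "n_points", lower = 20, len = 1, integerish = TRUE)
  check_num(seed, "seed", len = 1, integerish = TRUE)
  if (!is.null(osteophyte_arc)) {
    if (!is.list(osteophyte_arc) ||
        !all(c("start", "end", "amplitude") %in% names(osteophyte_arc))) {
      stop_field("osteophyte_arc", "must be list(start, end, amplitude)")
    }
    check_num(osteophyte_arc$start, "osteophyte_arc$start", len = 1)
    check_num(osteophyte_arc$end, "osteophyte_arc$end", len = 1)
    check_num(osteophyte_arc$amplitude, "osteophyte_arc$amplitude",
              lower = 0, len = 1)
    if (osteophyte_arc$end <= osteophyte_arc$start) {
      stop_field("osteophyte_arc", "end must exceed start")
    }
  }
  structure(list(head_radius = head_radius, head_center = head_center,
                 neck_axis_angle = neck_axis_angle,
                 neck_half_width = neck_half_width,
                 cam_onset_angle = cam_onset_angle,
                 cam_amplitude = cam_amplitude,
                 osteophyte_arc = osteophyte_arc, noise_sd = noise_sd,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "shape_spec")
}

# Angular half-opening of the neck at the head: where the neck margin lines
# (at perpendicular distance w from the axis) meet the head circle.
neck_junction_angle <- function(spec) {
  rad2deg(asin(spec$neck_half_width / spec$head_radius))
}

# Width of the bump's linear rise from the circle to full amplitude, in
# degrees. Narrow by construction so that the interpolated departure point
# lands within 0.1 degree of cam_onset_angle on noiseless shapes.
CAM_RISE_DEG <- 0.5

#' Generate a synthetic hip outline
#'
#' Produces an ordered counter-clockwise contour: superior neck margin, cam
#' bump (when present), head arc from the bump onset around the far side of
#' the head, then the inferior neck margin, so the neck closes the sequence.
#' Only points on the spherical head carry `landmark_role = "head"`; the cam
#' bump, sitting at the head--neck junction, is labelled `"neck_superior"` so
#' the circle of best fit is determined by the spherical part alone. The far
#' pole of the head is labelled `"apex"`. Points inside `osteophyte_arc` are
#' displaced outward and flagged; downstream measurement excludes them.
#'
#' @param spec A [shape_spec()].
#' @param subject_id Identifier stored with the outline.
#' @return A data frame of class `hip_outline` with columns `point_index`,
#'   `x`, `y`, `landmark_role`, `osteophyte_flag`, and attributes `subject_id`
#'   and `truth` (ground-truth alpha angle, centre and radius).
#' @export
generate_hip_outline <- function(spec, subject_id = "synthetic") {
  if (!inherits(spec, "shape_spec")) {
    stop("spec must be created by shape_spec()", call. = FALSE)
  }
  set.seed(spec$seed)
  r <- spec$head_radius
  ctr <- spec$head_center
  phi <- spec$neck_axis_angle
  delta <- neck_junction_angle(spec)
  a0 <- spec$cam_onset_angle
  if (a0 <= delta + CAM_RISE_DEG && spec$cam_amplitude > 0) {
    stop_field("cam_onset_angle",
               sprintf("must exceed the neck junction angle (%.1f deg)",
                       delta + CAM_RISE_DEG))
  }

  n_neck <- max(6L, round(0.12 * spec$n_points))
  n_head <- spec$n_points - 2L * n_neck

  # Head arc samples in neck-relative angle t, always including the bump
  # breakpoints and the apex so key features are actual contour points.
  t_head <- seq(delta + 1e-6, 360 - delta - 1e-6, length.out = n_head)
  extra <- c(180)
  if (spec$cam_amplitude > 0) extra <- c(a0, a0 - CAM_RISE_DEG, extra)
  t_head <- sort(unique(c(t_head, extra)))

  radial <- function(t) {
    rho <- rep(r, length(t))
    if (spec$cam_amplitude > 0) {
      rise <- t < a0 & t >= a0 - CAM_RISE_DEG
      plateau <- t < a0 - CAM_RISE_DEG
      rho[rise] <- r + spec$cam_amplitude * (a0 - t[rise]) / CAM_RISE_DEG
      rho[plateau] <- r + spec$cam_amplitude
    }
    rho
  }
  rho <- radial(t_head)

  role_head <- rep("head", length(t_head))
  role_head[t_head < a0 & spec$cam_amplitude > 0] <- "neck_superior"
  role_head[which.min(abs(t_head - 180))] <- "apex"

  theta <- deg2rad(phi + t_head)
  head_xy <- cbind(ctr[1] + rho * cos(theta), ctr[2] + rho * sin(theta))

  # Waisted neck margins: half-width minimal at s_mid, so the minimum-width
  # chord (and hence the neck midpoint) is well defined and lies on the axis.
  w <- spec$neck_half_width
  s0 <- sqrt(r^2 - w^2)
  s_mid <- s0 + 0.4 * r
  s_len <- 0.9 * r
  halfwidth <- function(s) w * (1 + 0.8 * ((s - s_mid) / r)^2)
  s_seq <- sort(unique(c(seq(s0, s0 + s_len, length.out = n_neck), s_mid)))
  u <- c(cos(deg2rad(phi)), sin(deg2rad(phi)))
  nrm <- c(-sin(deg2rad(phi)), cos(deg2rad(phi)))
  margin <- function(sign) {
    t(vapply(s_seq, function(s) {
      ctr + s * u + sign * halfwidth(s) * nrm
    }, numeric(2)))
  }
  sup <- margin(+1)   # superior margin: positive-t side
  inf <- margin(-1)

  # Counter-clockwise assembly, neck margins at the ends of the sequence.
  xy <- rbind(sup[rev(seq_len(nrow(sup))), , drop = FALSE], head_xy, inf)
  role <- c(rep("neck_superior", nrow(sup)), role_head,
            rep("neck_inferior", nrow(inf)))

  # Osteophyte displacement and flag, in neck-relative angle.
  flag <- integer(nrow(xy))
  if (!is.null(spec$osteophyte_arc)) {
    arc <- spec$osteophyte_arc
    rel <- rad2deg(atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])) - phi
    rel <- (rel %% 360)
    hit <- rel >= arc$start & rel <= arc$end
    if (any(hit)) {
      d <- sqrt((xy[hit, 1] - ctr[1])^2 + (xy[hit, 2] - ctr[2])^2)
      scale <- (d + arc$amplitude) / d
      xy[hit, 1] <- ctr[1] + (xy[hit, 1] - ctr[1]) * scale
      xy[hit, 2] <- ctr[2] + (xy[hit, 2] - ctr[2]) * scale
      flag[hit] <- 1L
    }
  }

  if (spec$noise_sd > 0) {
    xy <- xy + matrix(stats::rnorm(2 * nrow(xy), 0, spec$noise_sd),
                      ncol = 2)
  }

  out <- data.frame(point_index = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
                    landmark_role = role, osteophyte_flag = flag,
                    stringsAsFactors = FALSE)
  truth_alpha <- if (spec$cam_amplitude > 0) a0 else delta
  attr(out, "subject_id") <- subject_id
  attr(out, "truth") <- list(alpha_deg = truth_alpha, center = ctr,
                             radius = r, neck_axis_angle = phi)
  class(out) <- c("hip_outline", "data.frame")
  out
}

#' Draw a population of alpha angles
#'
#' Shifted log-normal model for the population distribution of the alpha
#' angle: positively skewed with a configurable mean, emulating the
#' right-skewed distribution seen in large imaging cohorts (population mean
#' near 48 degrees with a long upper tail).
#'
#' @param n Number of draws.
#' @param mean_aa Target population mean in degrees (default 47.8).
#' @param min_aa Lower shift of the distribution in degrees (default 31.8).
#' @param sdlog Log-scale standard deviation controlling the skew.
#' @param seed Integer seed.
#' @return Numeric vector of alpha angles in degrees.
#' @export
aa_population <- function(n, mean_aa = 47.8, min_aa = 31.8, sdlog = 0.35,
                          seed = 1) {
  check_num(n, "n", lower = 1, len = 1, integerish = TRUE)
  check_num(mean_aa, "mean_aa", lower = min_aa, strict_lower = TRUE, len = 1)
  check_num(sdlog, "sdlog", lower = 0, strict_lower = TRUE, len = 1)
  set.seed(seed)
  meanlog <- log(mean_aa - min_aa) - sdlog^2 / 2
  min_aa + stats::rlnorm(n, meanlog, sdlog)
}

#' Write / read hip outline files
#'
#' Tab-delimited text with header columns `point_index`, `x`, `y`,
#' `landmark_role`, `osteophyte_flag`.
#'
#' @param outline A `hip_outline` data frame.
#' @param path File path.
#' @export
write_outline <- function(outline, path) {
  utils::write.table(as.data.frame(outline)[, c("point_index", "x", "y",
                                                "landmark_role",
                                                "osteophyte_flag")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline
#' @param subject_id Subject identifier attached to the outline (defaults to
#'   the file name without extension).
#' @export
read_outline <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("outline file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot read outline file %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  need <- c("point_index", "x", "y", "landmark_role", "osteophyte_flag")
  if (!all(need %in% names(df))) {
    stop(sprintf("outline file %s missing columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  ok_roles <- c("head", "neck_superior", "neck_inferior", "apex")
  if (!all(df$landmark_role %in% ok_roles)) {
    stop(sprintf("outline file %s has invalid landmark_role values", path),
         call. = FALSE)
  }
  if (!all(df$osteophyte_flag %in% c(0L, 1L))) {
    stop(sprintf("outline file %s has invalid osteophyte_flag values", path),
         call. = FALSE)
  }
  if (!is.numeric(df$x) || !is.numeric(df$y) || anyNA(df$x) || anyNA(df$y)) {
    stop(sprintf("outline file %s has non-numeric coordinates", path),
         call. = FALSE)
  }
  attr(df, "subject_id") <- subject_id %||%
    tools::file_path_sans_ext(basename(path))
  class(df) <- c("hip_outline", "data.frame")
  df
}
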