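#' Algebraic least-squares circle fit
#'
#' Fits a circle by the Kasa method: linear least squares on
#' \eqn{x^2 + y^2 + Dx + Ey + F = 0}. Closed-form, deterministic, and exact
#' for points lying on a circle; adequate for dense femoral-head arcs. The
#' residual is the root-mean-square radial deviation, which callers can use
#' to detect poor fits.
#'
#' @param points Two-column matrix or data frame of x, y coordinates (>= 3
#'   non-collinear points).
#' @return List of class `circle_fit` with `center`, `radius`,
#'   `rms_residual`, `n_points_used`.
#' @export
fit_circle <- function(points) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3 || anyNA(pts)) {
    stop("circle fit needs at least 3 finite points", call. = FALSE)
  }
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  qr_A <- qr(A)
  if (qr_A$rank < 3) {
    stop("circle fit: points are collinear or degenerate", call. = FALSE)
  }
  coef <- qr.coef(qr_A, b)
  cx <- -coef[1] / 2
  cy <- -coef[2] / 2
  rad2 <- cx^2 + cy^2 - coef[3]
  if (!is.finite(rad2) || rad2 <= 0) {
    stop("circle fit: degenerate solution (non-positive radius)",
         call. = FALSE)
  }
  radius <- sqrt(rad2)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(list(center = unname(c(cx, cy)), radius = unname(radius),
                 rms_residual = sqrt(mean((d - radius)^2)),
                 n_points_used = nrow(pts)),
            class = "circle_fit")
}

#' Femoral neck midpoint
#'
#' Midpoint of the minimum-width chord between the superior and inferior neck
#' margins: the closest pair of points across the two margins, averaged.
#'
#' @param outline A `hip_outline` data frame.
#' @return Numeric length-2 point.
#' @export
neck_midpoint <- function(outline) {
  sup <- outline[outline$landmark_role == "neck_superior" &
                   outline$osteophyte_flag == 0, c("x", "y")]
  inf <- outline[outline$landmark_role == "neck_inferior" &
                   outline$osteophyte_flag == 0, c("x", "y")]
  if (nrow(sup) == 0 || nrow(inf) == 0) {
    stop("landmark error: both neck margins are required", call. = FALSE)
  }
  d2 <- outer(seq_len(nrow(sup)), seq_len(nrow(inf)), function(i, j) {
    (sup$x[i] - inf$x[j])^2 + (sup$y[i] - inf$y[j])^2
  })
  ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  c((sup$x[ij[1]] + inf$x[ij[2]]) / 2, (sup$y[ij[1]] + inf$y[ij[2]]) / 2)
}

# Number of consecutive supra-threshold contour points required before a
# departure is accepted; guards against isolated noise spikes.
DEPARTURE_PERSISTENCE <- 3L

#' Alpha angle from an outline point set
#'
#' Fits the osteophyte-excluding circle of best fit to the spherical-head
#' points, locates the femoral neck midpoint, then walks the contour from the
#' head apex toward the neck on the measurement side. The departure point is
#' the first contour location whose distance from the fitted centre exceeds
#' `radius * (1 + departure_tol)` and that starts a run of at least three
#' supra-threshold points (so single noisy points cannot fake a cam bump),
#' linearly interpolated between the bracketing contour points. If the
#' contour never exceeds the tolerance, the contour/circle crossing nearest
#' the neck is used instead. The alpha angle is the angle at the fitted
#' circle centre between the rays to the neck midpoint and to the departure
#' point.
#'
#' @param outline A `hip_outline` data frame.
#' @param departure_tol Departure tolerance as a fraction of the fitted
#'   radius (default 0.02).
#' @param cam_threshold_deg Cam-morphology threshold in degrees; `is_cam` is
#'   `TRUE` when `alpha_deg >= cam_threshold_deg` (default 60).
#' @return List of class `alpha_angle_result`: `alpha_deg`,
#'   `departure_point`, `neck_midpoint`, `circle`, `is_cam`, `method_flags`.
#' @export
compute_alpha_angle <- function(outline, departure_tol = 0.02,
                                cam_threshold_deg = 60) {
  check_num(departure_tol, "departure_tol", lower = 0, strict_lower = TRUE,
            len = 1)
  check_num(cam_threshold_deg, "cam_threshold_deg", lower = 0, upper = 180,
            len = 1)
  head_pts <- outline[outline$landmark_role %in% c("head", "apex") &
                        outline$osteophyte_flag == 0, c("x", "y")]
  if (nrow(head_pts) < 3) {
    stop("geometry error: fewer than 3 usable head points", call. = FALSE)
  }
  circ <- fit_circle(head_pts)
  nm <- neck_midpoint(outline)
  flags <- character(0)

  # Walk direction: from the apex toward the contour end that contains the
  # superior neck margin (the measurement side).
  usable <- outline$osteophyte_flag == 0
  apex_idx <- which(outline$landmark_role == "apex" & usable)
  if (length(apex_idx) == 0) {
    d_nm <- (outline$x - nm[1])^2 + (outline$y - nm[2])^2
    d_nm[!usable] <- -Inf
    apex_idx <- which.max(d_nm)
    flags <- c(flags, "apex_fallback_farthest_point")
  } else {
    apex_idx <- apex_idx[1]
  }
  sup_idx <- which(outline$landmark_role == "neck_superior")
  step <- if (length(sup_idx) && stats::median(sup_idx) < apex_idx) -1L else 1L
  walk <- seq(apex_idx, if (step < 0) 1L else nrow(outline), by = step)
  walk <- walk[usable[walk]]
  if (length(walk) < 2) {
    stop("measurement error: contour too short on the measurement side",
         call. = FALSE)
  }

  rho <- sqrt((outline$x[walk] - circ$center[1])^2 +
                (outline$y[walk] - circ$center[2])^2)
  thr <- circ$radius * (1 + departure_tol)
  exceed <- rho > thr

  run_start <- NA_integer_
  n <- length(walk)
  for (i in seq_len(n)) {
    if (!exceed[i]) next
    run_len <- 0L
    j <- i
    while (j <= n && exceed[j]) {
      run_len <- run_len + 1L
      j <- j + 1L
    }
    if (run_len >= DEPARTURE_PERSISTENCE || j > n) {
      run_start <- i
      break
    }
    i <- j  # skip the short spike (loop advances past it anyway)
  }

  if (!is.na(run_start)) {
    if (run_start == 1L) {
      departure <- c(outline$x[walk[1]], outline$y[walk[1]])
      flags <- c(flags, "departure_at_walk_start")
    } else {
      i0 <- walk[run_start - 1L]; i1 <- walk[run_start]
      f <- (thr - rho[run_start - 1L]) / (rho[run_start] - rho[run_start - 1L])
      f <- min(max(f, 0), 1)
      departure <- c(outline$x[i0] + f * (outline$x[i1] - outline$x[i0]),
                     outline$y[i0] + f * (outline$y[i1] - outline$y[i0]))
      flags <- c(flags, "interpolated_threshold_crossing")
    }
  } else {
    # No departure beyond tolerance: use the contour/circle crossing nearest
    # the neck (last sign change of rho - radius along the walk).
    s <- sign(rho - circ$radius)
    cross <- which(s[-1] * s[-n] < 0)
    if (length(cross) == 0) {
      stop("measurement error: contour never leaves nor crosses the fitted circle",
           call. = FALSE)
    }
    k <- max(cross)
    i0 <- walk[k]; i1 <- walk[k + 1L]
    f <- (circ$radius - rho[k]) / (rho[k + 1L] - rho[k])
    f <- min(max(f, 0), 1)
    departure <- c(outline$x[i0] + f * (outline$x[i1] - outline$x[i0]),
                   outline$y[i0] + f * (outline$y[i1] - outline$y[i0]))
    flags <- c(flags, "circle_crossing_fallback")
  }

  v1 <- nm - circ$center
  v2 <- departure - circ$center
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  alpha <- rad2deg(acos(min(max(cosang, -1), 1)))

  structure(list(alpha_deg = alpha, departure_point = departure,
                 neck_midpoint = nm, circle = circ,
                 is_cam = alpha >= cam_threshold_deg,
                 method_flags = flags,
                 departure_tol = departure_tol,
                 cam_threshold_deg = cam_threshold_deg),
            class = "alpha_angle_result")
}

#' Alpha angles for a batch of outlines
#'
#' Runs [compute_alpha_angle()] over a set of outlines (objects or file
#' paths). Failures are logged per subject and reported as missing rows,
#' never silently dropped.
#'
#' @param outlines List of `hip_outline` objects and/or outline file paths.
#' @param departure_tol,cam_threshold_deg Passed to [compute_alpha_angle()].
#' @return Data frame with one row per input: `subject`, `alpha_deg`,
#'   `is_cam`, `rms_residual`, `flags`, `error` (NA when successful).
#' @export
batch_alpha <- function(outlines, departure_tol = 0.02,
                        cam_threshold_deg = 60) {
  rows <- lapply(seq_along(outlines), function(i) {
    item <- outlines[[i]]
    subject <- if (is.character(item)) {
      tools::file_path_sans_ext(basename(item))
    } else {
      attr(item, "subject_id") %||% as.character(i)
    }
    res <- tryCatch({
      ol <- if (is.character(item)) read_outline(item) else item
      a <- compute_alpha_angle(ol, departure_tol, cam_threshold_deg)
      data.frame(subject = subject, alpha_deg = a$alpha_deg,
                 is_cam = a$is_cam, rms_residual = a$circle$rms_residual,
                 flags = paste(a$method_flags, collapse = ";"),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(subject = subject, alpha_deg = NA_real_, is_cam = NA,
                 rms_residual = NA_real_, flags = "",
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject = character(0), alpha_deg = numeric(0),
                      is_cam = logical(0), rms_residual = numeric(0),
                      flags = character(0), error = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}
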