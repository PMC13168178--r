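# Serrated-contour border irregularity.
#
# The border feature contrasts the true lesion contour with a coarse
# polygonal re-approximation of it ("serrated contour") built from radial
# rays: an ellipse is fitted to the contour, the contour points lying on the
# fitted ellipse define a set of intersection angles, and rays cast from the
# ellipse centre at the mean intersection angle step pick one contour point
# each. The signed area gap dA = A_contour - A_serrated grows with boundary
# serration and is the package's "B" feature.

#' Extract the external contour of the largest lesion component
#'
#' @param mask H x W 0/1 matrix with at least one foreground pixel.
#' @return A `contour` tibble with 0-based pixel coordinates `x` (column) and
#'   `y` (row), ordered counter-clockwise in the x-y coordinate frame
#'   (positive shoelace area).
#' @export
extract_contour <- function(mask) {
  assert_that_(sum(mask) > 0, "empty mask: no foreground pixels")
  comp <- largest_component(mask)
  oc <- EBImage::ocontour(as_ebimage(comp))[[1]]
  pts <- tibble::tibble(x = as.numeric(oc[, 1]), y = as.numeric(oc[, 2]))
  if (shoelace_signed(pts$x, pts$y) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
  class(pts) <- c("contour", class(pts))
  pts
}

shoelace_signed <- function(x, y) {
  j <- c(seq_along(x)[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Shoelace polygon area
#'
#' @param points Two-column matrix/data frame of vertex coordinates
#'   (at least 3 vertices).
#' @return Absolute enclosed area (px^2).
#' @export
polygon_area <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  assert_that_(nrow(pts) >= 3, "a polygon needs at least 3 points")
  abs(shoelace_signed(pts[, 1], pts[, 2]))
}

#' Direct least-squares ellipse fit
#'
#' Fitzgibbon-style conic fit constrained to an ellipse (Halir-Flusser
#' numerically stable formulation).
#'
#' @param points Contour (tibble/matrix with x, y), at least 5 points, not
#'   collinear.
#' @return An `ellipse_fit` list: `center` (x, y), `semi_axes` (major, minor,
#'   pixels), `rotation` (degrees, major-axis direction), and the conic
#'   coefficients.
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  assert_that_(nrow(pts) >= 5, "ellipse fit needs at least 5 points")
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e)
    abort("degenerate point set: ellipse fit failed"))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  ok <- which(cond > 0 & abs(Im(ev$values)) < 1e-8)
  assert_that_(length(ok) >= 1, "degenerate (collinear) points: no ellipse solution")
  a1 <- Re(ev$vectors[, ok[1]])
  coefs <- c(a1, as.vector(T_ %*% a1))  # A B C D E F in centred frame
  if (coefs[1] + coefs[3] < 0) coefs <- -coefs  # fix overall conic sign
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F_ <- coefs[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F_)
  root <- sqrt((A - C)^2 + B^2)
  axis1 <- -sqrt(num * (A + C + root)) / den
  axis2 <- -sqrt(num * (A + C - root)) / den
  semi <- sort(c(axis1, axis2), decreasing = TRUE)
  assert_that_(all(is.finite(semi)) && all(semi > 0),
               "degenerate conic: non-elliptical fit")
  # major-axis direction: eigenvector of the smaller eigenvalue of the
  # quadratic-form matrix [[A, B/2], [B/2, C]]
  eq <- eigen(matrix(c(A, B / 2, B / 2, C), 2))
  vmaj <- eq$vectors[, which.min(eq$values)]
  ang <- atan2(vmaj[2], vmaj[1])
  structure(list(center = c(x = cx + mx, y = cy + my),
                 semi_axes = c(major = semi[1], minor = semi[2]),
                 rotation = (ang * 180 / pi) %% 180,
                 conic = coefs),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> center (%.2f, %.2f), semi-axes %.2f / %.2f px, rotation %.1f deg\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$rotation))
  invisible(x)
}

# Radial distance of points to an ellipse boundary, measured along the ray
# from the ellipse centre (signed: positive outside).
ellipse_radial_distance <- function(fit, x, y) {
  phi <- -fit$rotation * pi / 180
  xr <- cos(phi) * (x - fit$center[1]) - sin(phi) * (y - fit$center[2])
  yr <- sin(phi) * (x - fit$center[1]) + cos(phi) * (y - fit$center[2])
  a <- fit$semi_axes[1]; b <- fit$semi_axes[2]
  ang <- atan2(yr, xr)
  r_ell <- a * b / sqrt((b * cos(ang))^2 + (a * sin(ang))^2)
  sqrt(xr^2 + yr^2) - r_ell
}

#' Contour-ellipse intersection set
#'
#' Contour points whose radial distance to the fitted ellipse boundary is at
#' most `tol` pixels, deduplicated to one representative per contiguous run
#' of touching points. Angles are measured at the ellipse centre with the
#' full-quadrant arctangent, mapped to `[0, 360)`.
#'
#' @param contour A [extract_contour()] result.
#' @param ellipse An [fit_ellipse()] result.
#' @param tol Distance tolerance in pixels (default 1.0).
#' @return An `intersection_set` list: `points` (tibble x, y, angle),
#'   `mu_theta` (circular mean angle, degrees in `[0, 360)`), `mean_gap`
#'   (360 / number of runs), `frac_on_ellipse` (fraction of all contour
#'   points within tolerance).
#' @export
intersections <- function(contour, ellipse, tol = 1.0) {
  pts <- as.data.frame(contour)
  d <- ellipse_radial_distance(ellipse, pts$x, pts$y)
  on_e <- abs(d) <= tol
  assert_that_(any(on_e),
               "degenerate geometry: contour never meets the fitted ellipse")
  n <- length(on_e)
  # contiguous circular runs of TRUE
  run_id <- cumsum(c(TRUE, diff(on_e) != 0))
  if (on_e[1] && on_e[n] && run_id[n] != run_id[1]) {
    run_id[run_id == run_id[n]] <- run_id[1]  # wrap-around merge
  }
  reps <- vapply(split(which(on_e), run_id[on_e]), function(idx) {
    idx[ceiling(length(idx) / 2)]
  }, numeric(1))
  reps <- sort(unname(reps))
  ang <- (atan2(pts$y[reps] - ellipse$center[2],
                pts$x[reps] - ellipse$center[1]) * 180 / pi) %% 360
  rad <- ang * pi / 180
  mu <- (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
  structure(list(
    points = tibble::tibble(x = pts$x[reps], y = pts$y[reps], angle = ang),
    mu_theta = mu,
    mean_gap = 360 / length(reps),
    frac_on_ellipse = mean(on_e)),
    class = "intersection_set")
}

#' Serrated contour from radial rays
#'
#' Casts rays from the centroid at angles `0, mu_theta, 2 mu_theta, ...`
#' (degrees, modulo 360) and keeps, per ray, the farthest crossing with the
#' contour polygon; the crossings joined in angular order form the serrated
#' contour.
#'
#' @param contour A [extract_contour()] result (or any closed polygon tibble).
#' @param centroid Numeric length-2 (x, y).
#' @param mu_theta Ray step in degrees, in `(0, 120]` so at least 3 rays
#'   result.
#' @return A `serrated_contour` tibble with columns x, y, angle.
#' @export
serrated_contour <- function(contour, centroid, mu_theta) {
  assert_that_(is_scalar_number(mu_theta) && mu_theta > 0 && mu_theta <= 120,
               "`mu_theta` must lie in (0, 120] degrees")
  pts <- as.matrix(as.data.frame(contour)[, c("x", "y")])
  n <- nrow(pts)
  p1 <- pts
  p2 <- pts[c(2:n, 1), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]
  ey <- p2[, 2] - p1[, 2]
  angles <- seq(0, 360, by = mu_theta)
  angles <- angles[angles < 360 - 1e-6]
  hits <- lapply(angles, function(a) {
    dx <- cos(a * pi / 180); dy <- sin(a * pi / 180)
    wx <- p1[, 1] - centroid[1]
    wy <- p1[, 2] - centroid[2]
    denom <- dx * ey - dy * ex
    valid <- abs(denom) > 1e-12
    t_ray <- (wx * ey - wy * ex) / denom   # distance along the ray
    u <- (wx * dy - wy * dx) / denom       # position along the edge
    valid <- valid & u >= 0 & u < 1 & t_ray > 1e-9
    if (!any(valid)) return(NULL)
    t_max <- max(t_ray[valid])
    c(x = centroid[1] + t_max * dx, y = centroid[2] + t_max * dy, angle = a)
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  assert_that_(!is.null(hits) && nrow(hits) >= 3,
               "fewer than 3 rays crossed the contour")
  colnames(hits) <- c("x", "y", "angle")
  out <- tibble::as_tibble(as.data.frame(hits))
  class(out) <- c("serrated_contour", class(out))
  out
}

#' Signed area difference between contour and serrated contour
#'
#' @param contour Closed polygon (the lesion contour).
#' @param serrated Closed polygon (the serrated contour).
#' @return `A_contour - A_serrated` in px^2 (signed; positive when the
#'   serrated polygon undercuts the true contour).
#' @export
area_difference <- function(contour, serrated) {
  polygon_area(contour) - polygon_area(serrated)
}

#' Full serrated-contour border irregularity of a mask
#'
#' Runs contour extraction, ellipse fit, intersection analysis, serration and
#' the area difference in one call. When the contour essentially coincides
#' with the fitted ellipse (>= 90% of contour points within tolerance), the
#' ray step is fixed at 10 degrees so the serration step stays well posed;
#' when the circular-mean angle falls outside the admissible `(0, 120]` ray
#' step range, the mean angular gap between intersection runs is used
#' instead.
#'
#' @param mask H x W 0/1 matrix.
#' @param tol Intersection tolerance in pixels.
#' @return A `border_irregularity` list: `delta_area`, `area_contour`,
#'   `area_serrated`, `mu_theta_used`, plus the intermediate `contour`,
#'   `ellipse`, `intersections` and `serrated` objects.
#' @export
border_irregularity <- function(mask, tol = 1.0) {
  contour <- extract_contour(mask)
  ellipse <- fit_ellipse(contour)
  inter <- intersections(contour, ellipse, tol = tol)
  step <- if (inter$frac_on_ellipse >= 0.9) {
    10
  } else if (inter$mu_theta > 0 && inter$mu_theta <= 120) {
    inter$mu_theta
  } else if (inter$mean_gap > 0 && inter$mean_gap <= 120) {
    inter$mean_gap
  } else {
    10
  }
  serr <- serrated_contour(contour, ellipse$center, step)
  a_c <- polygon_area(contour)
  a_s <- polygon_area(serr)
  structure(list(delta_area = a_c - a_s, area_contour = a_c,
                 area_serrated = a_s, mu_theta_used = step,
                 contour = contour, ellipse = ellipse,
                 intersections = inter, serrated = serr),
            class = "border_irregularity")
}

#' @export
print.border_irregularity <- function(x, ...) {
  cat(sprintf(
    "<border_irregularity> dA = %.1f px^2 (contour %.1f, serrated %.1f), ray step %.1f deg\n",
    x$delta_area, x$area_contour, x$area_serrated, x$mu_theta_used))
  invisible(x)
}

#' Plot a border-irregularity decomposition
#'
#' Shows the lesion contour, the fitted ellipse and the serrated contour.
#'
#' @param object A [border_irregularity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot border_irregularity
#' @export
autoplot.border_irregularity <- function(object, ...) {
  ell <- object$ellipse
  tt <- seq(0, 2 * pi, length.out = 181)
  phi <- ell$rotation * pi / 180
  ex <- ell$center[1] + ell$semi_axes[1] * cos(tt) * cos(phi) -
    ell$semi_axes[2] * sin(tt) * sin(phi)
  ey <- ell$center[2] + ell$semi_axes[1] * cos(tt) * sin(phi) +
    ell$semi_axes[2] * sin(tt) * cos(phi)
  df_c <- dplyr::mutate(as.data.frame(object$contour), what = "contour")
  df_s <- dplyr::mutate(as.data.frame(object$serrated)[, c("x", "y")],
                        what = "serrated")
  df_e <- data.frame(x = ex, y = ey, what = "ellipse fit")
  ggplot2::ggplot(rbind(df_c, df_s, df_e),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$what)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = sprintf("dA = %.1f px^2", object$delta_area),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
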