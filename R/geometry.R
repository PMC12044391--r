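#' Ellipse fit objects
#'
#' An `ellipse_fit` describes the moment-equivalent ellipse of a cell mask:
#' the unique ellipse such that a uniform elliptical disk with these
#' parameters has the same centroid and second central moments as the pixel
#' set. All lengths are in micrometres; `theta` is the orientation of the
#' major axis in radians, in `[0, pi)`, measured in the image frame
#' (x = column * pixel_size, y = row * pixel_size, y increasing downward).
#'
#' @param cx,cy Centre, in micrometres.
#' @param a,b Semi-major and semi-minor axes, micrometres (`a >= b > 0`).
#' @param theta Major-axis orientation, radians in `[0, pi)`.
#' @param degenerate Logical flag: `TRUE` when the pixel set was too small or
#'   collinear and a fallback disk of radius `pixel_size / 2` was used.
#' @return An object of class `ellipse_fit`.
#' @export
ellipse_fit <- function(cx, cy, a, b, theta, degenerate = FALSE) {
  stopifnot(a >= b, b > 0)
  theta <- theta %% pi
  structure(
    list(cx = cx, cy = cy, a = a, b = b, theta = theta,
         degenerate = degenerate),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> centre (%.3g, %.3g) um, a = %.3g, b = %.3g um, theta = %.3f rad%s\n",
    x$cx, x$cy, x$a, x$b, x$theta,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Fit a moment-equivalent ellipse to a cell's pixels
#'
#' Computes the ellipse whose uniform disk has the same second central
#' moments as the pixel set. Pixel coordinates are taken as pixel centres on
#' the 0-based (row, col) grid; each pixel contributes the covariance of a
#' unit square (the 1/12 correction), so a rasterized shape recovers the
#' continuous parameters closely even at small sizes.
#'
#' @param pixels Two-column matrix (or data frame) of 0-based (row, col)
#'   pixel coordinates of one cell.
#' @param pixel_size Pixel side length, micrometres per pixel.
#' @return An [ellipse_fit()]. Fewer than 3 pixels, or a collinear pixel set,
#'   yields a degenerate fit (`a = b = pixel_size / 2`) with a warning.
#' @export
fit_ellipse <- function(pixels, pixel_size) {
  stopifnot(pixel_size > 0)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0) stop("empty pixel set")
  # image frame: x from columns, y from rows
  x <- pixels[, 2]
  y <- pixels[, 1]
  cx <- mean(x)
  cy <- mean(y)
  n <- length(x)
  if (n < 3) {
    warning("fewer than 3 pixels; degenerate ellipse fit")
    return(ellipse_fit(cx * pixel_size, cy * pixel_size,
                       pixel_size / 2, pixel_size / 2, 0, degenerate = TRUE))
  }
  # second central moments + uniform-square pixel correction
  mxx_raw <- mean((x - cx)^2)
  myy_raw <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  # collinear set: the raw covariance is rank-deficient
  raw_det <- mxx_raw * myy_raw - mxy^2
  if (raw_det <= 1e-9 * max(mxx_raw, myy_raw, 1)) {
    warning("collinear pixel set; degenerate ellipse fit")
    return(ellipse_fit(cx * pixel_size, cy * pixel_size,
                       pixel_size / 2, pixel_size / 2, 0, degenerate = TRUE))
  }
  mxx <- mxx_raw + 1 / 12
  myy <- myy_raw + 1 / 12
  # eigen-decomposition of the 2x2 covariance, closed form
  tr <- mxx + myy
  det2 <- mxx * myy - mxy^2
  disc <- max(0, (tr / 2)^2 - det2)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  if (l2 <= 1e-12) {
    warning("collinear pixel set; degenerate ellipse fit")
    return(ellipse_fit(cx * pixel_size, cy * pixel_size,
                       pixel_size / 2, pixel_size / 2, 0, degenerate = TRUE))
  }
  theta <- if (abs(mxy) < 1e-14 && mxx >= myy) 0 else atan2(l1 - mxx, mxy)
  ellipse_fit(cx * pixel_size, cy * pixel_size,
              a = 2 * sqrt(l1) * pixel_size,
              b = 2 * sqrt(l2) * pixel_size,
              theta = theta)
}

#' Closest point on an ellipse boundary
#'
#' Orthogonal projection of a point onto the boundary of an ellipse. Solved
#' in the ellipse-aligned frame: rotate by `-theta`, reduce to the first
#' quadrant by symmetry, find the root of the distance derivative in the
#' boundary parameter by Brent's method, and map back.
#'
#' @param p Numeric length-2 point `(x, y)`, micrometres.
#' @param e An [ellipse_fit()].
#' @return Numeric length-2 boundary point. If `p` coincides with the centre
#'   the projection is ambiguous; the minor-axis endpoint (the nearest
#'   boundary distance) is returned with attribute `ambiguous = TRUE`.
#' @export
closest_point_on_ellipse <- function(p, e) {
  a <- e$a; b <- e$b
  ct <- cos(e$theta); st <- sin(e$theta)
  # to ellipse frame
  dx <- p[1] - e$cx; dy <- p[2] - e$cy
  ex <- ct * dx + st * dy
  ey <- -st * dx + ct * dy
  if (ex == 0 && ey == 0) {
    q <- c(0, b)
    out <- c(e$cx + ct * q[1] - st * q[2], e$cy + st * q[1] + ct * q[2])
    attr(out, "ambiguous") <- TRUE
    return(out)
  }
  sx <- sign(ex); sy <- sign(ey)
  if (sx == 0) sx <- 1
  if (sy == 0) sy <- 1
  x <- abs(ex); y <- abs(ey)
  if (abs(a - b) < 1e-12 * a) {
    # circle: radial projection
    r <- sqrt(x^2 + y^2)
    q <- c(a * x / r, a * y / r)
  } else if (x < 1e-10 * a) {
    # on the minor axis (to rotation roundoff): nearest point is its endpoint
    q <- c(0, b)
  } else if (y < 1e-10 * b) {
    xc <- (a^2 - b^2) / a
    if (x >= xc) {
      q <- c(a, 0)
    } else {
      cphi <- a * x / (a^2 - b^2)
      q <- c(a * cphi, b * sqrt(max(0, 1 - cphi^2)))
    }
  } else {
    # d/dphi of squared distance to (a cos phi, b sin phi), phi in (0, pi/2)
    h <- function(phi) {
      (b^2 - a^2) * sin(phi) * cos(phi) + x * a * sin(phi) - y * b * cos(phi)
    }
    root <- stats::uniroot(h, c(0, pi / 2), tol = 1e-14)$root
    q <- c(a * cos(root), b * sin(root))
  }
  q <- c(sx * q[1], sy * q[2])
  # back to image frame
  c(e$cx + ct * q[1] - st * q[2], e$cy + st * q[1] + ct * q[2])
}

#' Front direction of a polarized cell
#'
#' Cells of this kind move along their short axis, so the front is the unit
#' short-axis direction of the fitted ellipse, signed to agree with the
#' instantaneous velocity (`u . v >= 0`).
#'
#' @param e An [ellipse_fit()].
#' @param v Velocity vector, any consistent units; must be nonzero.
#' @return Unit length-2 vector. If `u . v == 0` exactly (motion exactly
#'   along the long axis) the tie is broken toward positive x, then positive
#'   y, and attribute `tie = TRUE` is set.
#' @export
front_direction <- function(e, v) {
  if (sqrt(sum(v^2)) == 0) stop("zero velocity: front undefined")
  u <- c(-sin(e$theta), cos(e$theta))
  d <- sum(u * v)
  if (d < 0) {
    u <- -u
  } else if (d == 0) {
    if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
    attr(u, "tie") <- TRUE
  }
  u
}

#' Angle between the cell front and a contact site
#'
#' The contact angle phi in `[0, pi]` between the front direction (see
#' [front_direction()]) and the direction from the ellipse centre to the
#' contact site: phi = 0 at the front pole, pi/2 at the sides, pi at the
#' rear. Left-right symmetric by construction.
#'
#' @param e An [ellipse_fit()].
#' @param v Focal-cell velocity (nonzero).
#' @param contact_point Length-2 point, typically the ellipse-projected
#'   contact site.
#' @return phi in radians, `[0, pi]`; `NA` if the contact point coincides
#'   with the centre.
#' @export
contact_angle <- function(e, v, contact_point) {
  r <- c(contact_point[1] - e$cx, contact_point[2] - e$cy)
  nr <- sqrt(sum(r^2))
  if (nr == 0) return(NA_real_)
  u <- front_direction(e, v)
  acos(max(-1, min(1, sum(u * r) / nr)))
}
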