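#' Sectioning-plane geometry
#'
#' An arbitrary virtual section through a volume is a plane perpendicular to a
#' line of sight fixed by two angles (pitch, yaw), with a third angle (roll)
#' spinning the section image in its own plane. The rotation centre is the
#' fixed point `f`, the plane sits at signed distance `d` along the viewing
#' axis, and a positive `scale` magnifies the section raster.
#'
#' The viewing transform is the affine map
#' \deqn{v' = s \, R_z(roll) R_y(pitch) R_z(yaw) (v - f)}
#' with angles in degrees, right-handed axes `x` = column, `y` = line (screen
#' rows grow downward, so screen-up is `-y`), `z` = plane; the section plane is
#' the set of view-frame points with `z' = d`. Elementary rotations here turn
#' the *frame* (so yaw = 90 maps the object-space `+x` axis to view-frame
#' `-y`).
#'
#' Viewing modes with fewer free parameters:
#' \describe{
#'   \item{absolute}{all three angles given explicitly.}
#'   \item{statue}{roll is fixed at 0; with nonzero pitch, changing yaw makes
#'     the section appear to rotate, as a statue on a turntable.}
#'   \item{up_is_up}{roll is derived so that a reference `up` vector (default
#'     `(0, 0, -1)`) projects onto the vertical screen axis, pointing up.}
#'   \item{fixed_line}{a second fixed point defines a line that must stay in
#'     the section plane; `line_angle` spends the one remaining degree of
#'     freedom (rotation about that line). The distance is 0 by construction
#'     (the plane passes through both fixed points).}
#' }
#'
#' @name view-geometry
NULL

#' Create a view specification
#'
#' @param fixed Fixed point `(k, l, p)`, the rotation centre; maps to the view
#'   frame origin.
#' @param pitch,yaw,roll Angles in decimal degrees (normalised to (-180, 180]).
#' @param dist Signed distance of the section plane from the fixed point along
#'   the viewing axis, in (scaled) view units.
#' @param scale Positive magnification of the section raster.
#' @param mode Viewing mode, one of `"absolute"`, `"statue"`, `"up_is_up"`,
#'   `"fixed_line"`.
#' @param up Reference up vector for `up_is_up` (default `(0, 0, -1)`).
#' @param fixed2 Second fixed point for `fixed_line`.
#' @param line_angle Free rotation (degrees) about the fixed line.
#' @return A `view_spec`.
#' @export
view_spec <- function(fixed = c(0, 0, 0), pitch = 0, yaw = 0, roll = 0,
                      dist = 0, scale = 1,
                      mode = c("absolute", "statue", "up_is_up", "fixed_line"),
                      up = c(0, 0, -1), fixed2 = NULL, line_angle = 0) {
  mode <- match.arg(mode)
  stopifnot(length(fixed) == 3L, scale > 0, length(up) == 3L)
  structure(list(fixed = as.numeric(fixed),
                 pitch = norm_angle(pitch), yaw = norm_angle(yaw),
                 roll = norm_angle(roll),
                 dist = as.numeric(dist), scale = as.numeric(scale),
                 mode = mode, up = as.numeric(up),
                 fixed2 = if (!is.null(fixed2)) as.numeric(fixed2),
                 line_angle = norm_angle(line_angle)),
            class = "view_spec")
}

#' Normalise an angle in degrees to (-180, 180]
#' @param a Numeric angle(s), degrees.
#' @export
norm_angle <- function(a) {
  a <- as.numeric(a) %% 360
  ifelse(a > 180, a - 360, a)
}

.deg2rad <- function(a) a * pi / 180

# frame rotations (transpose of the usual vector rotations): Rz(t) maps the
# object +x axis to (cos t, -sin t, 0) in the rotated frame.
.Rz <- function(t) {
  t <- .deg2rad(t); ct <- cos(t); st <- sin(t)
  matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3, 3)
}
.Ry <- function(t) {
  t <- .deg2rad(t); ct <- cos(t); st <- sin(t)
  matrix(c(ct, 0, st, 0, 1, 0, -st, 0, ct), 3, 3)
}

#' Resolve a viewing mode to concrete absolute angles
#'
#' Applies the mode rules: `statue` forces roll to 0; `up_is_up` solves for the
#' unique roll in (-180, 180] that maps the in-plane projection of the up
#' vector to the screen-up direction (`-y` of the section frame); `fixed_line`
#' derives pitch, yaw and roll from the line through the two fixed points plus
#' the free `line_angle`, and forces `dist` to 0 so both points lie on the
#' section plane; `absolute` is returned unchanged.
#'
#' @param view A `view_spec`.
#' @return A `view_spec` with `mode = "absolute"` and concrete angles.
#' @export
resolve_mode <- function(view) {
  stopifnot(inherits(view, "view_spec"))
  switch(view$mode,
    absolute = view,
    statue = {
      out <- view; out$roll <- 0; out$mode <- "absolute"; out
    },
    up_is_up = {
      R0 <- .Ry(view$pitch) %*% .Rz(view$yaw)
      w <- as.numeric(R0 %*% view$up)
      r <- sqrt(w[1]^2 + w[2]^2)
      if (r < 1e-12 * max(1, sqrt(sum(view$up^2)))) {
        stop("degenerate up vector: parallel to the viewing direction",
             call. = FALSE)
      }
      # want Rz(roll) %*% w to have x' = 0, y' < 0 (screen-up)
      phi <- atan2(w[2], w[1]) * 180 / pi
      out <- view; out$roll <- norm_angle(phi + 90); out$mode <- "absolute"
      out
    },
    fixed_line = {
      if (is.null(view$fixed2) || all(abs(view$fixed2 - view$fixed) < 1e-12)) {
        stop("degenerate fixed line: fixed2 missing or equal to fixed",
             call. = FALSE)
      }
      v <- view$fixed2 - view$fixed
      v <- v / sqrt(sum(v^2))
      # a stable vector perpendicular to v
      ref <- if (abs(v[1]) <= abs(v[2]) && abs(v[1]) <= abs(v[3])) {
        c(1, 0, 0)
      } else if (abs(v[2]) <= abs(v[3])) c(0, 1, 0) else c(0, 0, 1)
      w0 <- ref - sum(ref * v) * v
      w0 <- w0 / sqrt(sum(w0^2))
      w1 <- c(v[2] * w0[3] - v[3] * w0[2],
              v[3] * w0[1] - v[1] * w0[3],
              v[1] * w0[2] - v[2] * w0[1])
      th <- .deg2rad(view$line_angle)
      n <- cos(th) * w0 + sin(th) * w1      # plane normal, always
      # viewing direction (n) in spherical form: n = (sin p cos y, sin p sin y, cos p)
      pitch <- acos(max(-1, min(1, n[3]))) * 180 / pi
      yaw <- if (abs(n[1]) < 1e-15 && abs(n[2]) < 1e-15) 0 else
        atan2(n[2], n[1]) * 180 / pi
      # roll so the section-frame image of the fixed line is the +x screen axis
      R0 <- .Ry(pitch) %*% .Rz(yaw)
      wv <- as.numeric(R0 %*% v)
      roll <- atan2(wv[2], wv[1]) * 180 / pi
      out <- view
      out$pitch <- norm_angle(pitch); out$yaw <- norm_angle(yaw)
      out$roll <- norm_angle(roll); out$dist <- 0; out$mode <- "absolute"
      out
    })
}

#' Build the affine sectioning transform for a resolved view
#'
#' @param view A `view_spec`; non-absolute modes are resolved first.
#' @return A `view_transform` with the 3x3 rotation `R` (orthonormal, det +1),
#'   `scale`, `fixed` and `dist`. The forward map is
#'   `v' = scale * R %*% (v - fixed)`; the section plane is `z' = dist`.
#' @export
build_transform <- function(view) {
  view <- resolve_mode(view)
  R <- .Rz(view$roll) %*% .Ry(view$pitch) %*% .Rz(view$yaw)
  structure(list(R = R, scale = view$scale, fixed = view$fixed,
                 dist = view$dist, view = view),
            class = "view_transform")
}

#' Map object-space points to the view frame
#'
#' @param t A `view_transform`.
#' @param v Numeric 3-vector or 3-row/3-column matrix of points (one point per
#'   column if 3 x n).
#' @return Points in view-frame coordinates, same shape as input.
#' @export
to_view <- function(t, v) {
  if (is.matrix(v)) {
    t$scale * (t$R %*% (v - t$fixed))
  } else {
    as.numeric(t$scale * (t$R %*% (v - t$fixed)))
  }
}

#' Map view-frame points back to object space
#'
#' Exact inverse of [to_view()].
#'
#' @param t A `view_transform`.
#' @param v Numeric 3-vector or 3 x n matrix of view-frame points.
#' @return Object-space points, same shape as input.
#' @export
from_view <- function(t, v) {
  if (is.matrix(v)) {
    crossprod(t$R, v / t$scale) + t$fixed
  } else {
    as.numeric(crossprod(t$R, v / t$scale)) + t$fixed
  }
}

#' Viewing direction in object space
#'
#' The unit normal of the section plane, `t(R) %*% c(0, 0, 1)`. Roll never
#' changes it; only pitch and yaw do.
#'
#' @param t A `view_transform`.
#' @export
view_direction <- function(t) as.numeric(crossprod(t$R, c(0, 0, 1)))

#' Section frame for a bounding box under a view
#'
#' Transforms the 8 corners of the object bounding box and returns the raster
#' frame that covers every possible section: width/height span, integer pixel
#' offsets of the frame origin in view coordinates, and the distance range of
#' planes that intersect the box. The frame deliberately ignores the current
#' distance, so tile indices stay aligned while the user scrolls through the
#' volume.
#'
#' @param bbox Inclusive bounds `c(k1, l1, p1, k2, l2, p2)`.
#' @param t A `view_transform`.
#' @return List with `width`, `height`, `x_off`, `y_off`, `dist_min`,
#'   `dist_max`.
#' @export
section_frame <- function(bbox, t) {
  stopifnot(length(bbox) == 6L)
  corners <- as.matrix(expand.grid(k = bbox[c(1, 4)], l = bbox[c(2, 5)],
                                   p = bbox[c(3, 6)]))
  vc <- to_view(t, t(corners))
  x_off <- floor(min(vc[1, ]))
  y_off <- floor(min(vc[2, ]))
  list(width = ceiling(max(vc[1, ])) - x_off + 1,
       height = ceiling(max(vc[2, ])) - y_off + 1,
       x_off = x_off, y_off = y_off,
       dist_min = min(vc[3, ]), dist_max = max(vc[3, ]))
}

#' Project a 3D point onto the section frame
#'
#' @param view A `view_spec` or `view_transform`.
#' @param p Object-space point `(k, l, p)`.
#' @param frame Optional `section_frame` whose offsets are subtracted to give
#'   raster coordinates; with no frame, offsets are 0.
#' @return Numeric `(x, y, distance)`: section-frame coordinates and the
#'   signed distance of the point from the current section plane (`z' - d`).
#' @export
project_point <- function(view, p, frame = NULL) {
  t <- if (inherits(view, "view_transform")) view else build_transform(view)
  v <- to_view(t, as.numeric(p))
  xo <- if (is.null(frame)) 0 else frame$x_off
  yo <- if (is.null(frame)) 0 else frame$y_off
  c(x = v[1] - xo, y = v[2] - yo, distance = v[3] - t$dist)
}

#' Back-project a section-frame pixel to the unique 3D point on the plane
#'
#' The basis of the measurement tool: marking two points on the screen and
#' unprojecting both gives their true 3D separation.
#'
#' @param view A `view_spec` or `view_transform`.
#' @param x2 Section-frame coordinates `(x, y)`.
#' @param frame Optional `section_frame` (its offsets are added back).
#' @return Object-space point `(k, l, p)` on the section plane.
#' @export
unproject_point <- function(view, x2, frame = NULL) {
  t <- if (inherits(view, "view_transform")) view else build_transform(view)
  xo <- if (is.null(frame)) 0 else frame$x_off
  yo <- if (is.null(frame)) 0 else frame$y_off
  from_view(t, c(x2[1] + xo, x2[2] + yo, t$dist))
}
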