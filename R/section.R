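#' Cutting virtual sections
#'
#' A section is cut by inverse mapping: every output pixel centre in the
#' section frame is mapped back through the affine viewing transform into
#' object space and the volume is sampled there, nearest-neighbour by default
#' (trilinear on request for grey images; domain masks are always
#' nearest-neighbour, since interpolated labels are meaningless). Pixel
#' centres sit at integer section-frame coordinates; nearest-neighbour
#' rounding is `floor(v + 0.5)` per axis (ties towards +Inf).
#'
#' A resolution `level` samples the section-frame grid sparsely at steps of
#' `2^level` (pixel `(x, y)` of the level-`level` raster samples the
#' section-frame point `(x * 2^level + x_off, y * 2^level + y_off, d)`), so a
#' mosaic of tiles cut at any level is bit-identical to the full raster cut at
#' that level.
#'
#' @name sectioning
NULL

#' Cut a 2D section from a volume
#'
#' @param vol A `voxvol` with values (in-memory or lazy block store).
#' @param view A `view_spec`.
#' @param region Rectangle `c(x, y, w, h)` in level-0 section-frame pixels;
#'   default the whole section frame.
#' @param level Non-negative integer resolution level (power-of-two pyramid).
#' @param interp `"nearest"` (default) or `"trilinear"` (grey kinds only).
#' @param frame Optional precomputed [section_frame()]; pass one shared frame
#'   when sectioning several objects into a common raster.
#' @return A `section_image`: list with `pixels` (matrix `h x w`, or
#'   `h x w x 4` for rgba), `inside` (logical matrix, `FALSE` where the
#'   inverse-mapped voxel fell outside the domain), `frame`, `region`,
#'   `level`, `kind`, `background` and the resolved `view`.
#' @export
cut_section <- function(vol, view, region = NULL, level = 0,
                        interp = c("nearest", "trilinear"), frame = NULL) {
  stopifnot(inherits(vol, "voxvol"))
  if (!has_values(vol)) stop("cannot cut values from a domain-only object; use cut_domain_section()", call. = FALSE)
  interp <- match.arg(interp)
  ki <- kind_info(vol$kind)
  if (interp == "trilinear" && ki$channels == 4L) {
    stop("trilinear interpolation is only available for grey kinds", call. = FALSE)
  }
  rv <- resolve_mode(view)
  t <- build_transform(rv)
  if (is.null(frame)) frame <- section_frame(bounding_box(vol), t)
  g <- .section_grid(frame, region, level, t)
  samp <- if (interp == "nearest") {
    .sample_nearest(vol, g$obj)
  } else {
    .sample_trilinear(vol, g$obj)
  }
  pixels <- if (ki$channels == 4L) {
    a <- array(rep(vol$background, each = g$h * g$w), c(g$h, g$w, 4))
    for (ch in 1:4) {
      m <- a[, , ch]
      m[samp$inside] <- samp$values[samp$inside, ch]
      a[, , ch] <- m
    }
    a
  } else {
    m <- matrix(vol$background[1], g$h, g$w)
    m[samp$inside] <- samp$values[samp$inside]
    m
  }
  structure(list(pixels = pixels,
                 inside = matrix(samp$inside, g$h, g$w),
                 frame = frame, region = g$region, level = level,
                 kind = vol$kind, background = vol$background, view = rv),
            class = "section_image")
}

# shared pixel-grid construction: output raster dims, and the object-space
# sample points (3 x n, y fastest to match column-major raster fill)
.section_grid <- function(frame, region, level, t) {
  stopifnot(level >= 0, level == round(level))
  if (is.null(region)) region <- c(0, 0, frame$width, frame$height)
  stopifnot(length(region) == 4L, region[3] >= 1, region[4] >= 1)
  step <- 2^level
  w <- ceiling(region[3] / step)
  h <- ceiling(region[4] / step)
  xs <- region[1] + (seq_len(w) - 1) * step + frame$x_off
  ys <- region[2] + (seq_len(h) - 1) * step + frame$y_off
  pts <- rbind(rep(xs, each = h), rep(ys, times = w), t$dist)
  list(w = w, h = h, region = region, obj = from_view(t, pts))
}

.sample_nearest <- function(vol, obj) {
  ki <- floor(obj[1, ] + 0.5)
  li <- floor(obj[2, ] + 0.5)
  pi_ <- floor(obj[3, ] + 0.5)
  inside <- domain_contains(vol$domain, ki, li, pi_)
  values <- if (any(inside)) {
    v <- .values_lookup(vol, ki[inside], li[inside], pi_[inside])
    if (is.matrix(v)) {
      out <- matrix(0, length(ki), 4); out[inside, ] <- v; out
    } else {
      out <- numeric(length(ki)); out[inside] <- v; out
    }
  } else if (kind_info(vol$kind)$channels == 4L) {
    matrix(0, length(ki), 4)
  } else numeric(length(ki))
  list(inside = inside, values = values)
}

# trilinear for grey kinds: weights over the 8 voxel corners; out-of-domain
# corners contribute the background; a pixel is "inside" if its nearest voxel
# is in-domain (same test as nearest-neighbour, so masks agree).
.sample_trilinear <- function(vol, obj) {
  k0 <- floor(obj[1, ]); l0 <- floor(obj[2, ]); p0 <- floor(obj[3, ])
  fk <- obj[1, ] - k0; fl <- obj[2, ] - l0; fp <- obj[3, ] - p0
  acc <- numeric(ncol(obj))
  for (dk in 0:1) for (dl in 0:1) for (dp in 0:1) {
    wgt <- (if (dk) fk else 1 - fk) * (if (dl) fl else 1 - fl) *
           (if (dp) fp else 1 - fp)
    use <- wgt > 0
    if (!any(use)) next
    kq <- k0[use] + dk; lq <- l0[use] + dl; pq <- p0[use] + dp
    vin <- domain_contains(vol$domain, kq, lq, pq)
    vv <- rep(vol$background[1], sum(use))
    if (any(vin)) vv[vin] <- .values_lookup(vol, kq[vin], lq[vin], pq[vin])
    acc[use] <- acc[use] + wgt[use] * vv
  }
  inside <- domain_contains(vol$domain, floor(obj[1, ] + 0.5),
                            floor(obj[2, ] + 0.5), floor(obj[3, ] + 0.5))
  if (kind_info(vol$kind)$integer) acc <- floor(acc + 0.5)
  list(inside = inside, values = acc)
}

#' Cut a boolean section mask from a domain
#'
#' Same geometry pipeline as [cut_section()], but the result is the mask of
#' output pixels whose inverse-mapped voxel lies in the domain. This is how
#' each member of a compound object is sectioned individually before overlay
#' compositing.
#'
#' @param dom An `ivdom3d` (or a `voxvol`, whose domain is taken).
#' @param view A `view_spec`.
#' @inheritParams cut_section
#' @param voxel_size Unused placeholder for interface symmetry.
#' @return Logical matrix `h x w`.
#' @export
cut_domain_section <- function(dom, view, region = NULL, level = 0,
                               frame = NULL, voxel_size = c(1, 1, 1)) {
  if (inherits(dom, "voxvol")) dom <- dom$domain
  stopifnot(inherits(dom, "ivdom3d"))
  rv <- resolve_mode(view)
  t <- build_transform(rv)
  if (is.null(frame)) {
    if (is_empty_domain(dom)) {
      if (is.null(region)) stop("empty domain needs an explicit frame or region", call. = FALSE)
      frame <- list(width = region[3], height = region[4], x_off = 0, y_off = 0,
                    dist_min = 0, dist_max = 0)
    } else {
      frame <- section_frame(bounding_box(dom), t)
    }
  }
  g <- .section_grid(frame, region, level, t)
  ki <- floor(g$obj[1, ] + 0.5)
  li <- floor(g$obj[2, ] + 0.5)
  pi_ <- floor(g$obj[3, ] + 0.5)
  matrix(domain_contains(dom, ki, li, pi_), g$h, g$w)
}

#' Downscale a section image by powers of two
#'
#' Value rasters are reduced with a `2^levels` box filter (plain mean over
#' each window, edge windows clipped to the raster; integer kinds are
#' re-quantised round-half-up); the inside mask is reduced with any-true.
#'
#' @param section A `section_image`.
#' @param levels Number of pyramid levels to descend (>= 1).
#' @return A `section_image` at `level + levels`.
#' @export
downscale <- function(section, levels = 1) {
  stopifnot(inherits(section, "section_image"), levels >= 1)
  f <- 2^levels
  integerish <- kind_info(section$kind)$integer
  shrink <- function(m, how) {
    h <- nrow(m); w <- ncol(m)
    gr <- floor((seq_len(h) - 1) / f)
    gc <- floor((seq_len(w) - 1) / f)
    s <- t(rowsum(t(rowsum(m + 0, gr)), gc))
    if (how == "any") return(s > 0)
    cnt <- outer(as.numeric(table(gr)), as.numeric(table(gc)))
    s <- s / cnt
    if (integerish) s <- floor(s + 0.5)
    s
  }
  if (length(dim(section$pixels)) == 3L) {
    ch <- lapply(1:4, function(i) shrink(section$pixels[, , i], "mean"))
    px <- array(unlist(ch), c(dim(ch[[1]]), 4))
  } else {
    px <- shrink(section$pixels, "mean")
  }
  out <- section
  out$pixels <- px
  out$inside <- shrink(section$inside, "any")
  out$level <- section$level + levels
  out
}

#' Convert a grey section to display range 0..255
#'
#' Scales pixel values by the kind's nominal maximum (`u8` 255, `u16` 65535,
#' `u32` 2^32-1, `f32` clamped to \[0, 1\]) onto 0..255 for encoding and
#' colour filtering. RGBA sections are returned unchanged.
#'
#' @param section A `section_image`.
#' @return Numeric matrix (or `h x w x 4` array for rgba) in 0..255.
#' @export
section_display <- function(section) {
  if (length(dim(section$pixels)) == 3L) return(section$pixels)
  ki <- kind_info(section$kind)
  v <- section$pixels
  if (section$kind == "f32") v <- pmin(pmax(v, 0), 1) * 255
  else if (ki$max != 255) v <- v * (255 / ki$max)
  floor(pmin(pmax(v, 0), 255) + 0.5)
}
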