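#' Voxel volumes: interval domain + value table
#'
#' A `voxvol` couples an interval-coded spatial domain with an optional value
#' table, a physical voxel size and global coordinates, the standard object of
#' an atlas sectioning service. Value kinds are `u8`, `u16`, `u32`, `f32` and
#' `rgba`. Domain-only objects (no values) represent painted regions such as
#' anatomy delineations or expression domains.
#'
#' Values are held as a dense numeric array over the tight bounding box
#' (column fastest, then line, then plane, so plane reads are contiguous);
#' out-of-domain cells hold the background value and are never reported as
#' image data — lookups go through the interval membership test. RGBA volumes
#' use a 4th array dimension of extent 4 (r, g, b, alpha, each 0..255).
#'
#' @name voxel-volume
NULL

.KIND_INFO <- list(
  u8   = list(bytes = 1, max = 255,        integer = TRUE,  channels = 1),
  u16  = list(bytes = 2, max = 65535,      integer = TRUE,  channels = 1),
  u32  = list(bytes = 4, max = 4294967295, integer = TRUE,  channels = 1),
  f32  = list(bytes = 4, max = 1,          integer = FALSE, channels = 1),
  rgba = list(bytes = 4, max = 255,        integer = TRUE,  channels = 4)
)

kind_info <- function(kind) {
  ki <- .KIND_INFO[[kind]]
  if (is.null(ki)) stop("unknown value kind: ", kind, call. = FALSE)
  ki
}

#' Construct a voxel volume
#'
#' @param domain An `ivdom3d`.
#' @param values Dense numeric array over the domain's bounding box with dims
#'   `(nk, nl, np)` (grey kinds) or `(nk, nl, np, 4)` (rgba), or `NULL` for a
#'   domain-only object.
#' @param kind Value kind, one of `"u8"`, `"u16"`, `"u32"`, `"f32"`, `"rgba"`.
#' @param voxel_size Positive physical spacings `(sx, sy, sz)` per voxel step.
#' @param background Value returned outside the domain (length 1, or 4 for
#'   rgba; default 0, i.e. transparent for rgba).
#' @return A `voxvol`.
#' @export
voxvol <- function(domain, values = NULL, kind = "u8",
                   voxel_size = c(1, 1, 1), background = NULL) {
  stopifnot(inherits(domain, "ivdom3d"))
  ki <- kind_info(kind)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(background)) background <- rep(0, ki$channels)
  background <- rep_len(as.numeric(background), ki$channels)
  if (!is.null(values)) {
    if (is_empty_domain(domain)) stop("values supplied for an empty domain")
    bb <- domain$bbox
    want <- c(bb[4] - bb[1] + 1, bb[5] - bb[2] + 1, bb[6] - bb[3] + 1)
    if (ki$channels == 4L) want <- c(want, 4)
    if (!identical(as.integer(dim(values)), as.integer(want))) {
      stop(sprintf("values dims (%s) do not match domain bbox dims (%s)",
                   paste(dim(values), collapse = "x"),
                   paste(want, collapse = "x")), call. = FALSE)
    }
    storage.mode(values) <- "double"
  }
  structure(list(domain = domain, values = values, kind = kind,
                 voxel_size = as.numeric(voxel_size), background = background,
                 lazy = NULL),
            class = "voxvol")
}

#' Build a volume from a dense array and a mask
#'
#' @param arr Dense array of values, dims `(nk, nl, np)` or `(nk, nl, np, 4)`.
#' @param origin Global coordinate of `arr[1, 1, 1(, )]`.
#' @param mask Optional logical array marking in-domain voxels; default all.
#' @inheritParams voxvol
#' @export
voxvol_from_array <- function(arr, origin = c(0, 0, 0), mask = NULL,
                              kind = "u8", voxel_size = c(1, 1, 1),
                              background = NULL) {
  ki <- kind_info(kind)
  d3 <- dim(arr)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d3)
  dom <- domain_from_mask(mask, origin)
  if (is_empty_domain(dom)) {
    return(voxvol(dom, NULL, kind, voxel_size, background))
  }
  bb <- dom$bbox
  sel_k <- (bb[1] - origin[1] + 1):(bb[4] - origin[1] + 1)
  sel_l <- (bb[2] - origin[2] + 1):(bb[5] - origin[2] + 1)
  sel_p <- (bb[3] - origin[3] + 1):(bb[6] - origin[3] + 1)
  if (is.null(background)) background <- rep(0, ki$channels)
  msk <- mask[sel_k, sel_l, sel_p, drop = FALSE]
  # out-of-domain cells of the dense table hold the background value, so the
  # representation of a volume is unique given (domain, in-domain values)
  if (ki$channels == 4L) {
    values <- arr[sel_k, sel_l, sel_p, , drop = FALSE]
    for (ch in 1:4) {
      m <- values[, , , ch]
      m[!msk] <- rep_len(background, 4)[ch]
      values[, , , ch] <- m
    }
  } else {
    values <- arr[sel_k, sel_l, sel_p, drop = FALSE]
    values[!msk] <- background[1]
  }
  voxvol(dom, values, kind, voxel_size, background)
}

#' @export
print.voxvol <- function(x, ...) {
  vs <- volume_stats(x)
  cat(sprintf("<voxvol %s%s: %s voxels, voxel size %s, %s>\n",
              x$kind,
              if (is.null(x$values) && is.null(x$lazy)) " (domain-only)" else "",
              format(vs$voxel_count), paste(x$voxel_size, collapse = "x"),
              if (is_empty_domain(x$domain)) "empty"
              else paste(bounding_box(x), collapse = " ")))
  invisible(x)
}

#' @export
bounding_box.voxvol <- function(x) bounding_box(x$domain)

#' @export
bounding_box.compound3d <- function(x) {
  bbs <- lapply(x$members, function(m) bounding_box(m))
  bbs <- do.call(rbind, bbs)
  stats::setNames(c(apply(bbs[, 1:3, drop = FALSE], 2, min),
                    apply(bbs[, 4:6, drop = FALSE], 2, max)),
                  c("k1", "l1", "p1", "k2", "l2", "p2"))
}

#' Does a volume carry image values?
#' @param vol A `voxvol`.
#' @export
has_values <- function(vol) !is.null(vol$values) || !is.null(vol$lazy)

#' Voxel count and physical volume of an object
#'
#' Physical volume is `voxel_count * sx * sy * sz` in the cube of the voxel
#' size unit.
#'
#' @param obj A `voxvol` or `ivdom3d` (unit voxel size for a bare domain).
#' @return List with `voxel_count` and `physical_volume`.
#' @export
volume_stats <- function(obj) {
  if (inherits(obj, "ivdom3d")) {
    n <- domain_voxel_count(obj)
    return(list(voxel_count = n, physical_volume = n))
  }
  n <- domain_voxel_count(obj$domain)
  list(voxel_count = n, physical_volume = n * prod(obj$voxel_size))
}

# raw value lookup in global coordinates, ignoring the domain; callers pair it
# with domain_contains(). Returns a numeric vector (grey) or n x 4 matrix.
.values_lookup <- function(vol, k, l, p) {
  if (!is.null(vol$lazy)) return(.store_values_lookup(vol, k, l, p))
  bb <- vol$domain$bbox
  nk <- bb[4] - bb[1] + 1; nl <- bb[5] - bb[2] + 1; np <- bb[6] - bb[3] + 1
  ki <- kind_info(vol$kind)
  inbb <- k >= bb[1] & k <= bb[4] & l >= bb[2] & l <= bb[5] &
          p >= bb[3] & p <= bb[6]
  idx <- (k - bb[1] + 1) + nk * (l - bb[2]) + nk * nl * (p - bb[3])
  if (ki$channels == 4L) {
    out <- matrix(rep(vol$background, each = length(k)), ncol = 4)
    plane_stride <- nk * nl * np
    for (ch in 1:4) {
      out[inbb, ch] <- vol$values[idx[inbb] + (ch - 1) * plane_stride]
    }
  } else {
    out <- rep(vol$background[1], length(k))
    out[inbb] <- vol$values[idx[inbb]]
  }
  out
}

#' Image value at a 3D point
#'
#' @param vol A value-bearing `voxvol`.
#' @param point Integer voxel coordinate `(k, l, p)` in the global frame.
#' @return For an in-domain point, the grey value (or length-4 rgba vector);
#'   for an out-of-domain point, `NULL` with attribute handling left to the
#'   caller — concretely, a list `list(inside = FALSE, value = NULL)`. In-domain
#'   points give `list(inside = TRUE, value = <numeric>)`.
#' @export
value_at <- function(vol, point) {
  stopifnot(inherits(vol, "voxvol"), length(point) == 3L)
  if (!has_values(vol)) {
    stop("object has no values (domain-only object)", call. = FALSE)
  }
  inside <- domain_contains(vol$domain, point[1], point[2], point[3])
  if (!inside) return(list(inside = FALSE, value = NULL))
  v <- .values_lookup(vol, point[1], point[2], point[3])
  if (is.matrix(v)) v <- v[1, ]
  list(inside = TRUE, value = as.numeric(v))
}

#' Compound objects: indexed, possibly overlapping members
#'
#' An ordered list of volumes (value-bearing or domain-only) sharing one
#' global coordinate frame. Members are addressed by integer index starting at
#' 0; overlap is permitted and the index space is unbounded (it is not an
#' 8-bit label image).
#'
#' @param members List of `voxvol` objects.
#' @param names Optional character names per member (e.g. anatomy terms).
#' @return A `compound3d`.
#' @export
compound3d <- function(members, names = NULL) {
  stopifnot(length(members) >= 1L,
            all(vapply(members, inherits, TRUE, "voxvol")))
  if (!is.null(names)) stopifnot(length(names) == length(members))
  structure(list(members = members, names = names), class = "compound3d")
}

#' @export
print.compound3d <- function(x, ...) {
  cat(sprintf("<compound3d: %d members, indices 0..%d>\n",
              length(x$members), length(x$members) - 1L))
  invisible(x)
}

#' Number of members of a compound object
#' @param comp A `compound3d`.
#' @export
n_members <- function(comp) length(comp$members)

#' Member of a compound object by 0-based index
#' @param comp A `compound3d`.
#' @param index Integer index, 0-based.
#' @export
member <- function(comp, index) {
  if (index < 0 || index >= length(comp$members)) {
    stop("member index out of range: ", index, call. = FALSE)
  }
  comp$members[[index + 1L]]
}

#' Indices of members whose domain contains a point
#'
#' Because members may overlap, the answer is in general a list of indices,
#' not a single label.
#'
#' @param comp A `compound3d`.
#' @param point Integer voxel coordinate `(k, l, p)`.
#' @return Ascending integer vector of 0-based member indices (possibly empty).
#' @export
members_at <- function(comp, point) {
  stopifnot(inherits(comp, "compound3d"), length(point) == 3L)
  hit <- vapply(comp$members, function(m) {
    domain_contains(m$domain, point[1], point[2], point[3])
  }, logical(1))
  which(hit) - 1L
}
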