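#' Synthetic phantoms
#'
#' Deterministic test volumes with closed-form answers: a separable gradient
#' (any mis-ordered axis shows up in every pixel), a digital sphere with
#' distance-coded grey values, compound objects with controlled overlaps and
#' member counts well beyond 8-bit index images, and an RGB ramp volume. They
#' stand in for atlas reconstructions and whole-body colour volumes in every
#' test of this package.
#'
#' @name phantoms
NULL

#' Gradient phantom
#'
#' `value(k, l, p) = (k + 10*l + 100*p) mod (kind max + 1)`, full-box domain
#' at the origin. The coefficient triple (1, 10, 100) makes every voxel value
#' unique (for dims up to 10) so a single transposed axis or off-by-one is
#' visible in any one pixel.
#'
#' @param dims Integer extents `(nk, nl, np)`.
#' @param kind Grey value kind, default `"u16"`.
#' @param voxel_size Physical voxel size, default isotropic 1.
#' @return A `voxvol`.
#' @export
make_gradient_volume <- function(dims, kind = "u16", voxel_size = c(1, 1, 1)) {
  stopifnot(length(dims) == 3L, all(dims >= 1))
  ki <- kind_info(kind)
  k <- (seq_len(dims[1]) - 1)
  l <- (seq_len(dims[2]) - 1)
  p <- (seq_len(dims[3]) - 1)
  arr <- outer(outer(k, 10 * l, `+`), 100 * p, `+`)
  if (ki$integer) arr <- arr %% (ki$max + 1)
  voxvol_from_array(arr, kind = kind, voxel_size = voxel_size)
}

#' Digital sphere phantom
#'
#' Domain = voxels whose Euclidean distance from the centre is at most
#' `radius`; values are the rounded distance (distance-coded grey, 0 at the
#' centre). Voxels outside the sphere are outside the domain even though they
#' are inside the bounding box.
#'
#' @param dims Integer extents `(nk, nl, np)` of the enclosing grid.
#' @param centre Sphere centre (defaults to the grid midpoint).
#' @param radius Sphere radius in voxels.
#' @param kind Grey kind, default `"u8"`.
#' @param voxel_size Physical voxel size.
#' @return A `voxvol` whose domain is the digital ball.
#' @export
make_sphere_phantom <- function(dims, centre = NULL, radius = min(dims) / 3,
                                kind = "u8", voxel_size = c(1, 1, 1)) {
  stopifnot(length(dims) == 3L)
  if (is.null(centre)) centre <- floor((dims - 1) / 2)
  k <- (seq_len(dims[1]) - 1) - centre[1]
  l <- (seq_len(dims[2]) - 1) - centre[2]
  p <- (seq_len(dims[3]) - 1) - centre[3]
  d2 <- outer(outer(k^2, l^2, `+`), p^2, `+`)
  mask <- d2 <= radius^2
  ki <- kind_info(kind)
  vals <- pmin(floor(sqrt(d2) + 0.5), ki$max)
  voxvol_from_array(vals, mask = mask, kind = kind, voxel_size = voxel_size)
}

#' Compound phantom with controlled overlaps
#'
#' Builds `n_members` domain-only ball members laid out along a space-filling
#' raster. Consecutive members are shifted so that each pair overlaps by
#' roughly the requested fraction of a member diameter (`overlap = 0` gives
#' pairwise disjoint members). Member count is unbounded — hundreds of members
#' exercise index values beyond any 8-bit label image.
#'
#' @param dims Grid extents `(nk, nl, np)` the members are laid into.
#' @param n_members Number of members (>= 1).
#' @param overlap Fraction in \[0, 1) of the member spacing removed, pushing
#'   consecutive members into each other.
#' @param radius Member ball radius (default chosen from `dims`).
#' @return A `compound3d` of domain-only members, indices `0..n_members-1`.
#' @export
make_compound_phantom <- function(dims, n_members = 2, overlap = 0.5,
                                  radius = NULL) {
  stopifnot(n_members >= 1, overlap >= 0, overlap < 1)
  if (is.null(radius)) radius <- max(2, floor(min(dims) / 8))
  # a digital ball of radius r spans 2r+1 voxels, so centres 2r+1 apart are
  # pairwise disjoint; overlap shrinks the spacing proportionally
  spacing <- max(1, round((2 * radius + 1) * (1 - overlap)))
  per_row <- max(1, floor((dims[1] - 2 * radius) / spacing) + 1)
  per_plane <- per_row * max(1, floor((dims[2] - 2 * radius) / spacing) + 1)
  members <- vector("list", n_members)
  for (i in seq_len(n_members) - 1L) {
    ix <- i %% per_row
    iy <- (i %/% per_row) %% (per_plane %/% per_row)
    iz <- i %/% per_plane
    centre <- c(radius + ix * spacing, radius + iy * spacing,
                radius + iz * spacing)
    members[[i + 1L]] <- .ball_domain_vol(centre, radius)
  }
  compound3d(members)
}

.ball_domain_vol <- function(centre, radius) {
  r <- ceiling(radius)
  k <- (-r):r
  d2 <- outer(outer(k^2, k^2, `+`), k^2, `+`)
  dom <- domain_from_mask(d2 <= radius^2, origin = centre - r)
  voxvol(dom, NULL, kind = "u8")
}

#' RGB ramp phantom
#'
#' Red ramps along columns, green along lines, blue along planes (each
#' mod 256), alpha 255 everywhere in the full-box domain: the channels are
#' separable, so colour filtering and per-channel sectioning have closed-form
#' answers.
#'
#' @param dims Integer extents `(nk, nl, np)`.
#' @param voxel_size Physical voxel size.
#' @return An rgba `voxvol`.
#' @export
make_rgb_phantom <- function(dims, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dims) == 3L)
  arr <- array(0, c(dims, 4))
  k <- (seq_len(dims[1]) - 1) %% 256
  l <- (seq_len(dims[2]) - 1) %% 256
  p <- (seq_len(dims[3]) - 1) %% 256
  arr[, , , 1] <- k
  arr[, , , 2] <- rep(rep(l, each = dims[1]), times = dims[3])
  arr[, , , 3] <- rep(p, each = dims[1] * dims[2])
  arr[, , , 4] <- 255
  voxvol_from_array(arr, kind = "rgba", voxel_size = voxel_size)
}

#' Random blobby test domain
#'
#' Union of a few random balls inside a grid; used by property tests that need
#' arbitrary sparse domains. Deterministic for a given seed.
#'
#' @param dims Grid extents.
#' @param n_blobs Number of balls.
#' @param seed Integer seed.
#' @param origin Global coordinate of the grid corner.
#' @return An `ivdom3d` (possibly empty).
#' @export
random_blob_domain <- function(dims, n_blobs = 3, seed = 1,
                               origin = c(0, 0, 0)) {
  set.seed(seed)
  mask <- array(FALSE, dims)
  idx <- list(k = seq_len(dims[1]) - 1, l = seq_len(dims[2]) - 1,
              p = seq_len(dims[3]) - 1)
  for (b in seq_len(n_blobs)) {
    c0 <- c(stats::runif(1, 0, dims[1] - 1), stats::runif(1, 0, dims[2] - 1),
            stats::runif(1, 0, dims[3] - 1))
    r <- stats::runif(1, 1, max(2, min(dims) / 3))
    d2 <- outer(outer((idx$k - c0[1])^2, (idx$l - c0[2])^2, `+`),
                (idx$p - c0[3])^2, `+`)
    mask <- mask | (d2 <= r^2)
  }
  domain_from_mask(mask, origin)
}
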