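#' Interval-coded 3D spatial domains
#'
#' A 3D domain is an arbitrary point-set of voxel space, stored as a planewise
#' stack of per-line column intervals rather than a dense grid. Each interval
#' is a maximal run `[k_first, k_last]` (inclusive, global coordinates) of
#' in-domain columns on one line of one plane. Planes and lines with no voxels
#' are simply absent. This run-length form keeps storage proportional to the
#' boundary complexity of the region, not to its bounding box, and reduces
#' binary set operations to interval comparisons.
#'
#' Internally a domain is a list with
#' \describe{
#'   \item{ivs}{numeric matrix with columns `p`, `l`, `k1`, `k2`, one row per
#'     interval, sorted by (p, l, k1), maximally merged (adjacent intervals on
#'     a line are coalesced), so equal point-sets have identical structure.}
#'   \item{bbox}{tight inclusive bounds `c(k1, l1, p1, k2, l2, p2)`, or `NULL`
#'     for the empty domain.}
#' }
#'
#' Coordinates are integers: `k` = column, `l` = line, `p` = plane, any sign.
#'
#' @name interval-domain
NULL

new_ivdom <- function(ivs) {
  ivs <- matrix(as.numeric(ivs), ncol = 4,
                dimnames = list(NULL, c("p", "l", "k1", "k2")))
  if (nrow(ivs) == 0L) {
    return(structure(list(ivs = ivs, bbox = NULL), class = "ivdom3d"))
  }
  stopifnot(all(ivs[, "k1"] <= ivs[, "k2"]))
  ord <- order(ivs[, "p"], ivs[, "l"], ivs[, "k1"])
  ivs <- ivs[ord, , drop = FALSE]
  # maximal merge: coalesce overlapping or adjacent intervals on the same line.
  # Per-line running max of k2 via the offset trick (offsets dominate k range),
  # so the whole normalisation stays vectorised.
  n <- nrow(ivs)
  same <- c(FALSE,
            ivs[-1L, "p"] == ivs[-n, "p"] & ivs[-1L, "l"] == ivs[-n, "l"])
  line_id <- cumsum(!same)
  big <- max(ivs[, "k2"]) - min(ivs[, "k1"]) + 2
  runmax <- cummax(ivs[, "k2"] + line_id * big) - line_id * big
  newgrp <- !same | ivs[, "k1"] > c(-Inf, runmax[-n]) + 1
  if (!all(newgrp)) {
    grp <- cumsum(newgrp)
    k2 <- as.numeric(tapply(ivs[, "k2"], grp, max))
    first <- newgrp
    ivs <- cbind(p = ivs[first, "p"], l = ivs[first, "l"],
                 k1 = ivs[first, "k1"], k2 = k2)
  }
  bbox <- c(min(ivs[, "k1"]), min(ivs[, "l"]), min(ivs[, "p"]),
            max(ivs[, "k2"]), max(ivs[, "l"]), max(ivs[, "p"]))
  structure(list(ivs = ivs, bbox = bbox), class = "ivdom3d")
}

#' Create an empty interval domain
#' @return An `ivdom3d` containing no voxels.
#' @export
empty_domain <- function() new_ivdom(matrix(numeric(0), ncol = 4))

#' Is a domain empty?
#' @param dom An `ivdom3d`.
#' @export
is_empty_domain <- function(dom) is.null(dom$bbox)

#' @export
print.ivdom3d <- function(x, ...) {
  if (is_empty_domain(x)) {
    cat("<ivdom3d: empty>\n")
  } else {
    cat(sprintf("<ivdom3d: %d intervals, %s voxels, bbox k %d..%d l %d..%d p %d..%d>\n",
                nrow(x$ivs), format(domain_voxel_count(x)),
                x$bbox[1], x$bbox[4], x$bbox[2], x$bbox[5], x$bbox[3], x$bbox[6]))
  }
  invisible(x)
}

#' Build an interval domain from a dense logical mask
#'
#' @param mask 3D logical array, dimensions (k, l, p) with column fastest.
#' @param origin integer vector `(k, l, p)` giving the global coordinate of
#'   `mask[1, 1, 1]`.
#' @return An `ivdom3d` containing exactly the `TRUE` voxels.
#' @export
domain_from_mask <- function(mask, origin = c(0, 0, 0)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, length(origin) == 3L)
  mode(mask) <- "logical"
  d <- dim(mask)
  if (!any(mask)) return(empty_domain())
  prev <- array(FALSE, d)
  if (d[1] > 1L) prev[-1L, , ] <- mask[-d[1], , ]
  nxt <- array(FALSE, d)
  if (d[1] > 1L) nxt[-d[1], , ] <- mask[-1L, , ]
  si <- which(mask & !prev, arr.ind = TRUE)
  ei <- which(mask & !nxt, arr.ind = TRUE)
  # which() returns column-major order: starts and ends pair up per line
  new_ivdom(cbind(p  = origin[3] + si[, 3] - 1,
                  l  = origin[2] + si[, 2] - 1,
                  k1 = origin[1] + si[, 1] - 1,
                  k2 = origin[1] + ei[, 1] - 1))
}

#' Densify an interval domain to a logical mask over its tight bounding box
#'
#' Exact inverse of [domain_from_mask()] over the bounding box.
#'
#' @param dom An `ivdom3d`.
#' @return List with `mask` (logical array, dims (k, l, p)) and `origin`
#'   (global coordinate of `mask[1, 1, 1]`). Empty domain gives a 0x0x0 mask.
#' @export
domain_to_mask <- function(dom) {
  if (is_empty_domain(dom)) {
    return(list(mask = array(logical(0), c(0L, 0L, 0L)), origin = c(0, 0, 0)))
  }
  bb <- dom$bbox
  nk <- bb[4] - bb[1] + 1; nl <- bb[5] - bb[2] + 1; np <- bb[6] - bb[3] + 1
  mask <- array(FALSE, c(nk, nl, np))
  iv <- dom$ivs
  lens <- iv[, "k2"] - iv[, "k1"] + 1
  kk <- sequence(lens, from = iv[, "k1"] - bb[1] + 1)
  ll <- rep(iv[, "l"] - bb[2], lens)
  pp <- rep(iv[, "p"] - bb[3], lens)
  mask[kk + nk * (ll + nl * pp)] <- TRUE
  list(mask = mask, origin = c(bb[1], bb[2], bb[3]))
}

#' Number of voxels in a domain
#' @param dom An `ivdom3d`.
#' @export
domain_voxel_count <- function(dom) {
  if (is_empty_domain(dom)) return(0)
  sum(dom$ivs[, "k2"] - dom$ivs[, "k1"] + 1)
}

#' Translate a domain by an integer offset
#' @param dom An `ivdom3d`.
#' @param dk,dl,dp integer shifts along column, line and plane.
#' @export
domain_translate <- function(dom, dk = 0, dl = 0, dp = 0) {
  if (is_empty_domain(dom)) return(dom)
  iv <- dom$ivs
  iv[, "p"] <- iv[, "p"] + dp
  iv[, "l"] <- iv[, "l"] + dl
  iv[, "k1"] <- iv[, "k1"] + dk
  iv[, "k2"] <- iv[, "k2"] + dk
  new_ivdom(iv)
}

# Encode intervals / query points on a common linearised axis so that all
# per-line interval work becomes one sorted sweep. Stride nk + 1 leaves a
# one-cell gap between lines, so adjacency can never leak across lines.
.dom_encoding <- function(bb) {
  nk <- bb[4] - bb[1] + 1
  nl <- bb[5] - bb[2] + 1
  list(k0 = bb[1], l0 = bb[2], p0 = bb[3], nk = nk, nl = nl, stride = nk + 1)
}

.encode_ivs <- function(dom, enc) {
  iv <- dom$ivs
  key <- ((iv[, "p"] - enc$p0) * enc$nl + (iv[, "l"] - enc$l0)) * enc$stride
  cbind(s = key + (iv[, "k1"] - enc$k0), e = key + (iv[, "k2"] - enc$k0))
}

.decode_ivs <- function(se, enc) {
  key <- floor(se[, 1] / enc$stride)
  l <- key %% enc$nl
  p <- (key - l) / enc$nl
  cbind(p = p + enc$p0, l = l + enc$l0,
        k1 = se[, 1] - key * enc$stride + enc$k0,
        k2 = se[, 2] - key * enc$stride + enc$k0)
}

#' Binary set operations on interval domains
#'
#' Computes the voxelwise union, intersection or difference of two domains by
#' merging their sorted interval lists; neither operand is densified.
#'
#' @param a,b `ivdom3d` objects in the same global coordinate frame.
#' @param op One of `"union"`, `"intersect"`, `"difference"`.
#' @return An `ivdom3d` in maximal-merge normal form.
#' @export
domain_binary_op <- function(a, b, op = c("union", "intersect", "difference")) {
  op <- match.arg(op)
  if (is_empty_domain(a)) {
    return(if (op == "union") b else empty_domain())
  }
  if (is_empty_domain(b)) {
    return(if (op == "intersect") empty_domain() else a)
  }
  bb <- c(pmin(a$bbox[1:3], b$bbox[1:3]), pmax(a$bbox[4:6], b$bbox[4:6]))
  bb <- bb[c(1, 2, 3, 4, 5, 6)]
  enc <- .dom_encoding(bb)
  ea <- .encode_ivs(a, enc)
  eb <- .encode_ivs(b, enc)
  # breakpoints where membership of either operand can change
  bp <- sort(unique(c(ea[, 1], ea[, 2] + 1, eb[, 1], eb[, 2] + 1)))
  seg_s <- bp[-length(bp)]
  seg_e <- bp[-1L] - 1
  in_a <- .covered(seg_s, ea)
  in_b <- .covered(seg_s, eb)
  keep <- switch(op,
                 union = in_a | in_b,
                 intersect = in_a & in_b,
                 difference = in_a & !in_b)
  if (!any(keep)) return(empty_domain())
  s <- seg_s[keep]; e <- seg_e[keep]
  # merge adjacent kept segments (same line by construction of the stride gap)
  brk <- c(TRUE, s[-1L] != e[-length(e)] + 1)
  grp <- cumsum(brk)
  s <- s[brk]
  e <- as.numeric(tapply(e, grp, max))
  new_ivdom(.decode_ivs(cbind(s, e), enc))
}

# is each sorted query position covered by one of the sorted intervals `se`?
.covered <- function(pos, se) {
  i <- findInterval(pos, se[, 1])
  i > 0 & pos <= se[pmax(i, 1L), 2]
}

#' Point-in-domain test
#'
#' Vectorised membership test against the interval representation (binary
#' search on encoded interval starts; the dense grid is never built).
#'
#' @param dom An `ivdom3d`.
#' @param k,l,p equal-length integer vectors of global voxel coordinates.
#' @return Logical vector.
#' @export
domain_contains <- function(dom, k, l, p) {
  n <- length(k)
  if (is_empty_domain(dom) || n == 0L) return(rep(FALSE, n))
  bb <- dom$bbox
  inbb <- k >= bb[1] & k <= bb[4] & l >= bb[2] & l <= bb[5] &
          p >= bb[3] & p <= bb[6]
  out <- rep(FALSE, n)
  if (!any(inbb)) return(out)
  enc <- .dom_encoding(bb)
  se <- .encode_ivs(dom, enc)
  pos <- ((p[inbb] - enc$p0) * enc$nl + (l[inbb] - enc$l0)) * enc$stride +
    (k[inbb] - enc$k0)
  i <- findInterval(pos, se[, 1])
  out[inbb] <- i > 0 & pos <= se[pmax(i, 1L), 2]
  out
}

#' Tight bounding box of a domain or volume
#'
#' @param x An `ivdom3d`, `voxvol` or `compound3d`.
#' @return Named numeric vector `c(k1, l1, p1, k2, l2, p2)`, inclusive global
#'   bounds.
#' @export
bounding_box <- function(x) UseMethod("bounding_box")

#' @export
bounding_box.ivdom3d <- function(x) {
  if (is_empty_domain(x)) stop("empty domain has no bounding box", call. = FALSE)
  stats::setNames(x$bbox, c("k1", "l1", "p1", "k2", "l2", "p2"))
}
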