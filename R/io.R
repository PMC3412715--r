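#' Importers and exporters
#'
#' Supported interchange formats: TIFF stacks (one file per plane,
#' lexicographic file order = ascending plane) and NIfTI-1 volumes for single
#' images; integer-labelled volumes (each distinct nonzero label becomes one
#' compound member) and JSON manifests of per-member mask files for compound
#' objects — the manifest route is required when members overlap, which a
#' label image cannot express.
#'
#' Plane arrays on disk are row = line (l), column = column (k); internally
#' the column axis comes first, so planes are transposed on the way in/out.
#'
#' @name volume-io
NULL

.tiff_kind <- function(m, bps) {
  if (length(dim(m)) == 3L && dim(m)[3] >= 3L) return("rgba")
  if (is.double(m) && max(m, na.rm = TRUE) <= 1 && bps >= 32) return("f32")
  if (bps <= 8) "u8" else if (bps <= 16) "u16" else "u32"
}

# one plane as stored internally: (k, l) matrix or (k, l, 4) array
.read_tiff_plane <- function(path) {
  # suppress libtiff's cosmetic ExtraSamples note on alpha channels
  m <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE, info = TRUE))
  bps <- attr(m, "bits.per.sample")
  if (is.null(bps)) bps <- 8L
  # multi-channel images come back rescaled to [0, 1] regardless of as.is
  if (is.double(m) && bps <= 16 && max(m) <= 1 &&
      (length(dim(m)) == 3L || isTRUE(attr(m, "sample.format") != "float"))) {
    m[] <- round(m * (2^bps - 1))
  }
  if (length(dim(m)) == 3L) {
    a <- aperm(m, c(2, 1, 3))
    if (dim(a)[3] == 3L) {
      a2 <- array(255, c(dim(a)[1:2], 4))
      a2[, , 1:3] <- a
      a <- a2
    }
    list(plane = a, kind = "rgba")
  } else {
    list(plane = t(m), kind = .tiff_kind(m, bps))
  }
}

#' Read a TIFF stack directory as a volume
#'
#' @param path Directory of single-plane TIFF files (lexicographic order =
#'   ascending plane) or a character vector of files in plane order.
#' @param voxel_size Physical voxel size to attach.
#' @param origin Global coordinate of the first voxel.
#' @param background Background/threshold value: voxels equal to it are left
#'   out of the domain when `threshold = TRUE`.
#' @param threshold If `TRUE`, build the domain from non-background voxels
#'   instead of the full box.
#' @return A `voxvol`.
#' @export
read_tiff_stack <- function(path, voxel_size = c(1, 1, 1),
                            origin = c(0, 0, 0), background = 0,
                            threshold = FALSE) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                    ignore.case = TRUE))
  } else path
  if (length(files) == 0L) stop("no TIFF planes found in ", path, call. = FALSE)
  first <- .read_tiff_plane(files[[1]])
  kind <- first$kind
  d2 <- dim(first$plane)[1:2]
  np <- length(files)
  ki <- kind_info(kind)
  arr <- if (ki$channels == 4L) array(0, c(d2, np, 4)) else array(0, c(d2, np))
  for (i in seq_len(np)) {
    pl <- if (i == 1L) first else .read_tiff_plane(files[[i]])
    if (!identical(dim(pl$plane)[1:2], d2)) {
      stop("inconsistent plane dimensions at plane ", i, call. = FALSE)
    }
    if (ki$channels == 4L) arr[, , i, ] <- pl$plane else arr[, , i] <- pl$plane
  }
  mask <- if (threshold) {
    if (ki$channels == 4L) {
      apply(arr != rep(background, each = prod(c(d2, np))), c(1, 2, 3), any)
    } else arr != background
  } else NULL
  voxvol_from_array(arr, origin = origin, mask = mask, kind = kind,
                    voxel_size = voxel_size,
                    background = rep_len(background, ki$channels))
}

#' Write a volume as a TIFF stack
#'
#' One file per plane, `plane_%04d.tif`, 8- or 16-bit grey or 8-bit RGBA.
#' Out-of-domain voxels are written as the background value (the interval
#' domain itself is not representable in TIFF).
#'
#' @param vol A `voxvol` with values (`u8`, `u16`, `f32` or `rgba`).
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_tiff_stack <- function(vol, dir) {
  stopifnot(inherits(vol, "voxvol"))
  if (!is.null(vol$lazy)) vol <- store_to_memory(vol)
  if (is.null(vol$values)) stop("domain-only object cannot be a TIFF stack",
                                call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bb <- vol$domain$bbox
  np <- bb[6] - bb[3] + 1
  files <- character(np)
  for (i in seq_len(np)) {
    f <- file.path(dir, sprintf("plane_%04d.tif", i - 1))
    if (vol$kind == "rgba") {
      pl <- aperm(vol$values[, , i, , drop = FALSE][, , 1, ], c(2, 1, 3)) / 255
      tiff::writeTIFF(pl, f, bits.per.sample = 8)
    } else {
      ki <- kind_info(vol$kind)
      bits <- if (vol$kind == "u8") 8L else 16L
      mx <- if (vol$kind == "f32") 1 else (2^bits - 1)
      if (vol$kind == "u32") stop("u32 TIFF export is not supported", call. = FALSE)
      pl <- t(vol$values[, , i]) / mx
      tiff::writeTIFF(pmin(pmax(pl, 0), 1), f, bits.per.sample = bits)
    }
    files[i] <- f
  }
  invisible(files)
}

.nifti_kind <- function(datatype) {
  switch(as.character(datatype),
         "2" = "u8", "4" = "u16", "8" = "u32", "512" = "u16", "768" = "u32",
         "16" = "f32", "64" = "f32", "f32")
}

#' Read a NIfTI-1 volume
#'
#' Array axes i, j, k are taken as column, line, plane; `pixdim` becomes the
#' voxel size.
#'
#' @inheritParams read_tiff_stack
#' @param path A `.nii` / `.nii.gz` file.
#' @return A `voxvol`.
#' @export
read_nifti_volume <- function(path, origin = c(0, 0, 0), background = 0,
                              threshold = FALSE) {
  img <- RNifti::readNifti(path)
  # the on-disk datatype: the in-memory array is always promoted, so the
  # header has to come from the file itself
  hdr <- RNifti::niftiHeader(path)
  kind <- .nifti_kind(hdr$datatype)
  arr <- array(as.numeric(img), dim(img)[1:3])
  vs <- abs(hdr$pixdim[2:4])
  vs[vs <= 0] <- 1
  mask <- if (threshold) arr != background else NULL
  voxvol_from_array(arr, origin = origin, mask = mask, kind = kind,
                    voxel_size = vs, background = background)
}

#' Write a grey volume as NIfTI-1
#'
#' @param vol A grey `voxvol`.
#' @param path Output `.nii.gz` path.
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxvol"))
  if (!is.null(vol$lazy)) vol <- store_to_memory(vol)
  if (vol$kind == "rgba") stop("rgba NIfTI export is not supported", call. = FALSE)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path,
                     datatype = switch(vol$kind, u8 = "uint8", u16 = "uint16",
                                       u32 = "double", f32 = "float"))
  invisible(path)
}

#' Import an integer-labelled volume as a compound object
#'
#' Each distinct nonzero label becomes one domain-only member, ordered by
#' label value (index 0 = smallest label). A label image cannot express
#' overlapping members — use a manifest ([read_compound_manifest()]) for
#' those.
#'
#' @param path NIfTI file or TIFF stack directory of integer labels.
#' @param voxel_size Physical voxel size (NIfTI pixdim wins if present).
#' @return A `compound3d` with member names `"label_<value>"`.
#' @export
read_labelled_volume <- function(path, voxel_size = c(1, 1, 1)) {
  vol <- if (dir.exists(path)) {
    read_tiff_stack(path, voxel_size = voxel_size)
  } else {
    read_nifti_volume(path)
  }
  arr <- vol$values
  labels <- sort(unique(as.vector(arr)))
  labels <- labels[labels != 0]
  if (length(labels) == 0L) stop("no nonzero labels in ", path, call. = FALSE)
  bb <- vol$domain$bbox
  members <- lapply(labels, function(lb) {
    dom <- domain_from_mask(arr == lb, origin = bb[1:3])
    voxvol(dom, NULL, "u8", vol$voxel_size)
  })
  compound3d(members, names = paste0("label_", labels))
}

#' Read a compound object from a JSON manifest
#'
#' The manifest lists one mask file per member (any nonzero voxel is
#' in-domain), so members may overlap freely and the member count is
#' unbounded:
#' \preformatted{
#' {"voxel_size": [1, 1, 1],
#'  "members": [{"path": "m0.nii.gz", "name": "cortex", "origin": [0,0,0]},
#'              ...]}
#' }
#' Paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest JSON file.
#' @return A `compound3d`.
#' @export
read_compound_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  vs <- if (!is.null(man$voxel_size)) as.numeric(unlist(man$voxel_size)) else c(1, 1, 1)
  members <- lapply(man$members, function(m) {
    f <- m$path
    if (!file.exists(f)) f <- file.path(base, m$path)
    org <- if (!is.null(m$origin)) as.numeric(unlist(m$origin)) else c(0, 0, 0)
    v <- if (dir.exists(f)) {
      read_tiff_stack(f, voxel_size = vs, origin = org, threshold = TRUE)
    } else {
      read_nifti_volume(f, origin = org, threshold = TRUE)
    }
    voxvol(v$domain, NULL, "u8", vs)
  })
  nms <- vapply(man$members, function(m) {
    if (is.null(m$name)) NA_character_ else m$name
  }, character(1))
  compound3d(members, names = if (!all(is.na(nms))) nms)
}

#' Write a compound object as per-member masks plus a JSON manifest
#'
#' @param comp A `compound3d`.
#' @param dir Output directory.
#' @return Manifest path, invisibly.
#' @export
write_compound_manifest <- function(comp, dir) {
  stopifnot(inherits(comp, "compound3d"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", n_members(comp))
  for (i in seq_len(n_members(comp))) {
    m <- comp$members[[i]]
    dm <- domain_to_mask(m$domain)
    f <- sprintf("member_%04d.nii.gz", i - 1)
    img <- RNifti::asNifti(array(as.numeric(dm$mask), dim(dm$mask)))
    RNifti::writeNifti(img, file.path(dir, f), datatype = "uint8")
    entries[[i]] <- list(path = f, origin = dm$origin,
                         name = if (!is.null(comp$names)) comp$names[i] else
                           sprintf("member_%d", i - 1))
  }
  man <- list(voxel_size = comp$members[[1]]$voxel_size, members = entries)
  mp <- file.path(dir, "compound.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Convert an image volume to a block store, streaming plane by plane
#'
#' TIFF stacks are converted in two passes (one to build the domain, one to
#' fill blocks) holding at most one block-slab of planes in memory, so the
#' conversion is bounded by slab size, not volume size. NIfTI input is read
#' through its reader (which loads the array) and then streamed through the
#' same writer.
#'
#' @param input TIFF stack directory, NIfTI file, or a `voxvol`.
#' @param output Store file path.
#' @param block_shape Block extents, default [default_block_shape()].
#' @param background Background value; with `threshold = TRUE`, voxels equal
#'   to it stay outside the domain, so they are not stored.
#' @param threshold Build the domain from non-background voxels.
#' @param voxel_size Voxel size for TIFF input (NIfTI carries its own).
#' @return `output`, invisibly.
#' @export
convert_to_store <- function(input, output, block_shape = NULL,
                             background = 0, threshold = FALSE,
                             voxel_size = c(1, 1, 1)) {
  if (inherits(input, "voxvol")) {
    return(write_store(input, output, block_shape))
  }
  if (length(input) == 1L && !dir.exists(input) && !grepl("\\.tiff?$", input,
                                                          ignore.case = TRUE)) {
    vol <- read_nifti_volume(input, background = background,
                             threshold = threshold)
    return(write_store(vol, output, block_shape))
  }
  .convert_tiff_stream(input, output, block_shape, background, threshold,
                       voxel_size)
}

.convert_tiff_stream <- function(path, output, block_shape, background,
                                 threshold, voxel_size) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                    ignore.case = TRUE))
  } else path
  if (length(files) == 0L) stop("no TIFF planes found in ", path, call. = FALSE)
  first <- .read_tiff_plane(files[[1]])
  kind <- first$kind
  ki <- kind_info(kind)
  if (is.null(block_shape)) block_shape <- default_block_shape(kind)
  block_shape <- as.integer(block_shape)
  .check_block_shape(block_shape, kind)
  d2 <- dim(first$plane)[1:2]
  np <- length(files)
  # pass 1: per-plane domain runs
  all_ivs <- vector("list", np)
  for (i in seq_len(np)) {
    pl <- if (i == 1L) first else .read_tiff_plane(files[[i]])
    if (!identical(dim(pl$plane)[1:2], d2)) {
      stop("inconsistent plane dimensions at plane ", i, call. = FALSE)
    }
    msk <- if (threshold) {
      if (ki$channels == 4L) {
        apply(pl$plane[, , 1:4, drop = FALSE] !=
                rep(rep_len(background, 4), each = prod(d2)), c(1, 2), any)
      } else pl$plane != background
    } else {
      matrix(TRUE, d2[1], d2[2])
    }
    d <- domain_from_mask(array(msk, c(d2, 1)), origin = c(0, 0, i - 1))
    all_ivs[[i]] <- d$ivs
  }
  dom <- new_ivdom(do.call(rbind, all_ivs))
  if (is_empty_domain(dom)) stop("thresholding left no foreground voxels",
                                 call. = FALSE)
  bb <- dom$bbox
  geo <- .store_geometry(bb, block_shape)
  present <- logical(geo$total)
  iv <- dom$ivs
  bi_p <- (iv[, "p"] - bb[3]) %/% block_shape[3]
  bi_l <- (iv[, "l"] - bb[2]) %/% block_shape[2]
  b_k1 <- (iv[, "k1"] - bb[1]) %/% block_shape[1]
  b_k2 <- (iv[, "k2"] - bb[1]) %/% block_shape[1]
  for (r in seq_len(nrow(iv))) {
    ids <- 1 + (b_k1[r]:b_k2[r]) +
      geo$nblocks[1] * (bi_l[r] + geo$nblocks[2] * bi_p[r])
    present[ids] <- TRUE
  }
  lut <- integer(geo$total)
  lut[present] <- seq_len(sum(present))
  bg <- rep_len(background, ki$channels)
  vol_stub <- list(domain = dom, kind = kind,
                   voxel_size = as.numeric(voxel_size), background = bg,
                   values = NULL)
  con <- file(output, "wb")
  on.exit(close(con))
  .write_store_header(con, vol_stub, bb, block_shape, 4096L, lut)
  # pass 2: stream one slab of block_shape[3] planes at a time
  for (bk in 0:(geo$nblocks[3] - 1)) {
    p_lo <- bb[3] + bk * block_shape[3]
    p_hi <- min(p_lo + block_shape[3] - 1, bb[6])
    slab_np <- p_hi - p_lo + 1
    slab <- if (ki$channels == 4L) {
      array(rep(bg, each = geo$ext[1] * geo$ext[2] * slab_np),
            c(geo$ext[1], geo$ext[2], slab_np, 4))
    } else {
      array(bg[1], c(geo$ext[1], geo$ext[2], slab_np))
    }
    for (p in p_lo:p_hi) {
      pl <- .read_tiff_plane(files[[p + 1L]])$plane  # planes are 0-based global
      sel_k <- (bb[1] + 1):(bb[4] + 1)
      sel_l <- (bb[2] + 1):(bb[5] + 1)
      if (ki$channels == 4L) {
        slab[, , p - p_lo + 1, ] <- pl[sel_k, sel_l, , drop = FALSE]
      } else {
        slab[, , p - p_lo + 1] <- pl[sel_k, sel_l]
      }
    }
    slab_ids <- which(present &
                        (seq_len(geo$total) - 1) %/% (geo$nblocks[1] * geo$nblocks[2]) == bk)
    for (id in slab_ids) {
      id0 <- id - 1
      bi <- id0 %% geo$nblocks[1]
      bj <- (id0 %/% geo$nblocks[1]) %% geo$nblocks[2]
      ks <- (bi * block_shape[1] + 1):min((bi + 1) * block_shape[1], geo$ext[1])
      ls <- (bj * block_shape[2] + 1):min((bj + 1) * block_shape[2], geo$ext[2])
      if (ki$channels == 4L) {
        blk <- array(rep(bg, each = prod(block_shape)), c(block_shape, 4))
        blk[seq_along(ks), seq_along(ls), seq_len(slab_np), ] <-
          slab[ks, ls, , , drop = FALSE]
      } else {
        blk <- array(bg[1], block_shape)
        blk[seq_along(ks), seq_along(ls), seq_len(slab_np)] <- slab[ks, ls, ]
      }
      .write_block(con, blk, kind)
    }
  }
  invisible(output)
}
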