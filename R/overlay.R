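#' Indexed overlays and layer compositing
#'
#' A SEL entry selects one member of a compound object by index and assigns it
#' a colour and opacity: domain members are painted with the RGB colour at the
#' given alpha; value-bearing layers are colour-filtered channelwise. An
#' ordered stack of such layers is combined with the source-over operator in
#' request order, so overlapping regions blend and the blend depends on the
#' order — exactly the behaviour wanted for anatomy overlays where regions may
#' overlap and the index space is unbounded.
#'
#' @name overlay-compositing
NULL

#' Parse a SEL command's arguments
#'
#' The general form is `index,r,g,b,a` with channels 0..255. Simplified forms
#' default omitted channels to 255: 4 arguments are `index,r,g,b` (alpha 255),
#' 2 arguments are `index,alpha` (colour white), 1 argument is the bare index
#' (opaque white).
#'
#' @param args Character or numeric vector of 1, 2, 4 or 5 integers.
#' @return A `sel_entry`: list with `index`, `r`, `g`, `b`, `a`.
#' @export
parse_sel <- function(args) {
  if (length(args) == 1L && is.character(args) && grepl(",", args)) {
    args <- strsplit(args, ",", fixed = TRUE)[[1]]
  }
  vals <- suppressWarnings(as.numeric(args))
  if (anyNA(vals) || any(vals != floor(vals))) {
    stop("SEL arguments must be integers: ", paste(args, collapse = ","),
         call. = FALSE)
  }
  n <- length(vals)
  if (!n %in% c(1L, 2L, 4L, 5L)) {
    stop("SEL takes 1, 2, 4 or 5 arguments, got ", n, call. = FALSE)
  }
  if (vals[1] < 0) stop("SEL index must be >= 0", call. = FALSE)
  ent <- switch(as.character(n),
    "1" = c(vals[1], 255, 255, 255, 255),
    "2" = c(vals[1], 255, 255, 255, vals[2]),
    "4" = c(vals, 255),
    "5" = vals)
  if (any(ent[-1] < 0 | ent[-1] > 255)) {
    stop("SEL channel values must be 0..255", call. = FALSE)
  }
  structure(list(index = ent[1], r = ent[2], g = ent[3], b = ent[4],
                 a = ent[5]),
            class = "sel_entry")
}

#' Paint a section mask with a SEL colour
#'
#' In-mask pixels get `(r, g, b, a)`; everything else is fully transparent.
#'
#' @param mask Logical matrix from [cut_domain_section()].
#' @param entry A `sel_entry`.
#' @return RGBA array `h x w x 4` with channels 0..255.
#' @export
colour_domain_layer <- function(mask, entry) {
  stopifnot(is.matrix(mask), inherits(entry, "sel_entry"))
  out <- array(0, c(dim(mask), 4))
  col <- c(entry$r, entry$g, entry$b, entry$a)
  for (ch in 1:4) {
    m <- out[, , ch]
    m[mask] <- col[ch]
    out[, , ch] <- m
  }
  out
}

#' Colour-filter a value section into an RGBA layer
#'
#' Grey sections are spread through the filter colour: a display grey `g0`
#' becomes `(floor(g0 * r / 255), floor(g0 * g / 255), floor(g0 * b / 255), a)`
#' on in-domain pixels — `(255,255,255,255)` is the identity filter. RGBA
#' sections are filtered channelwise, alpha included. Out-of-domain pixels are
#' fully transparent.
#'
#' @param section A `section_image` with values.
#' @param entry A `sel_entry`.
#' @return RGBA array `h x w x 4`, channels 0..255.
#' @export
filter_value_layer <- function(section, entry) {
  stopifnot(inherits(section, "section_image"), inherits(entry, "sel_entry"))
  inside <- section$inside
  out <- array(0, c(dim(inside), 4))
  fil <- c(entry$r, entry$g, entry$b, entry$a)
  if (length(dim(section$pixels)) == 3L) {
    for (ch in 1:4) {
      m <- floor(section$pixels[, , ch] * fil[ch] / 255)
      m[!inside] <- 0
      out[, , ch] <- m
    }
  } else {
    g0 <- section_display(section)
    for (ch in 1:3) {
      m <- floor(g0 * fil[ch] / 255)
      m[!inside] <- 0
      out[, , ch] <- m
    }
    a <- matrix(0, nrow(inside), ncol(inside))
    a[inside] <- fil[4]
    out[, , 4] <- a
  }
  out
}

#' Composite a stack of RGBA layers with the source-over operator
#'
#' Layers are combined in list order, later entries over earlier ones.
#' Arithmetic is done in premultiplied float and quantised to 8 bits
#' (round-half-up) only at the end, avoiding cumulative integer bias; the
#' operator is associative in this form.
#'
#' @param stack List of RGBA arrays `h x w x 4` (channels 0..255), all the
#'   same shape.
#' @return A single RGBA array `h x w x 4`, channels 0..255.
#' @export
composite <- function(stack) {
  stopifnot(is.list(stack), length(stack) >= 1L)
  dims <- dim(stack[[1]])
  for (lay in stack) {
    if (!identical(dim(lay), dims)) {
      stop("layer shape mismatch in composite()", call. = FALSE)
    }
  }
  # premultiplied accumulation: C = Cs + Cd * (1 - as)
  acc <- array(0, dims)
  premul <- function(lay) {
    a <- lay[, , 4] / 255
    out <- lay
    for (ch in 1:3) out[, , ch] <- lay[, , ch] / 255 * a
    out[, , 4] <- a
    out
  }
  acc <- premul(stack[[1]])
  for (i in seq_along(stack)[-1L]) {
    src <- premul(stack[[i]])
    keep <- 1 - src[, , 4]
    for (ch in 1:4) acc[, , ch] <- src[, , ch] + acc[, , ch] * keep
  }
  out <- array(0, dims)
  a <- acc[, , 4]
  nz <- a > 0
  for (ch in 1:3) {
    m <- matrix(0, dims[1], dims[2])
    m[nz] <- acc[, , ch][nz] / a[nz]
    out[, , ch] <- floor(pmin(pmax(m, 0), 1) * 255 + 0.5)
  }
  out[, , 4] <- floor(pmin(pmax(a, 0), 1) * 255 + 0.5)
  out
}

#' Render a SEL stack against a resource into one RGBA raster
#'
#' For a compound resource each selected member is sectioned individually with
#' the shared frame and painted (domain-only members) or colour-filtered
#' (value-bearing members); the layers are then composited in SEL order. For a
#' plain volume resource every entry colour-filters the volume's own section
#' (the index must then be 0).
#'
#' @param resource A `voxvol` or `compound3d`.
#' @param sel_stack List of `sel_entry` objects, request order.
#' @param view A `view_spec`.
#' @inheritParams cut_section
#' @return RGBA array `h x w x 4`, channels 0..255.
#' @export
render_sel_stack <- function(resource, sel_stack, view, region = NULL,
                             level = 0, frame = NULL) {
  stopifnot(length(sel_stack) >= 1L)
  rv <- resolve_mode(view)
  t <- build_transform(rv)
  if (is.null(frame)) frame <- section_frame(bounding_box(resource), t)
  layers <- lapply(sel_stack, function(entry) {
    obj <- if (inherits(resource, "compound3d")) {
      member(resource, entry$index)
    } else {
      if (entry$index != 0) {
        stop("SEL index ", entry$index, " out of range for a plain volume",
             call. = FALSE)
      }
      resource
    }
    if (has_values(obj)) {
      sec <- cut_section(obj, rv, region = region, level = level, frame = frame)
      filter_value_layer(sec, entry)
    } else {
      msk <- cut_domain_section(obj$domain, rv, region = region, level = level,
                                frame = frame)
      colour_domain_layer(msk, entry)
    }
  })
  composite(layers)
}
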