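# iip3d — arbitrary-plane virtual sectioning and tiled delivery of 3D biological images

Atlas-scale biomedical volumes (histology reconstructions, embryo models,
whole-body colour scans) are too large to download or hold in RAM, yet what a
user looks at is always a 2D section at screen resolution. `iip3d` is an R
implementation of the full server-side stack for that workflow:

* **Interval-coded image objects** — the spatial domain of an image (an
  arbitrary point-set of 3D space) is stored as run-length *intervals* per
  line, separately from the value table, so sparse regions cost what their
  boundary costs and binary set operations reduce to interval merging.
  Value kinds: 8/16/32-bit grey, float, RGBA. Compound objects hold any
  number of possibly **overlapping** indexed members (not an 8-bit label
  image).
* **Sectioning geometry** — the affine viewing transform
  `v' = s·Rz(roll)·Ry(pitch)·Rz(yaw)·(v − f)` with the section plane
  `z' = d`, plus the navigation modes *absolute*, *statue* (roll = 0),
  *up-is-up* (roll solved so a reference up vector lands on the vertical
  screen axis) and *fixed-line* (a line through two fixed points stays in
  the plane, one rotational degree of freedom left).
* **Section cutting** — inverse mapping with nearest-neighbour (default) or
  trilinear sampling, power-of-two resolution levels, and box-filter
  downscaling; tile mosaics are bit-identical to one-shot cuts.
* **Indexed overlays** — `SEL` entries colour/filter individual members
  with per-region RGBA; stacks composite with source-over in request order
  (premultiplied float, quantised once).
* **An IIP-style protocol** — `CMD=value` query strings (`WLZ`, `PIT`,
  `YAW`, `ROL`, `DST`, `FXP`, `SCL`, `MOD`, `SEL`, tile commands
  `JTL`/`PTL`/`TIL`, full-section `CVT`, object queries `OBJ` with probe
  points `PRT`/`PAB`), three-level LRU caching (tiles, objects,
  transforms), substring proxy routing, and a plain-HTTP server loop.
* **A chunked block store** — values in fixed-size cuboidal blocks behind a
  lookup table, aligned to filesystem blocks; the domain loads eagerly,
  values lazily, so sectioning a larger-than-memory volume touches only the
  blocks the plane intersects (instrumented and asserted in tests).
* **Phantom generators** — gradient, sphere, RGB-ramp and
  overlapping-compound test volumes with closed-form answers.

## Worked example

```r
library(iip3d)

root <- tempfile(); dir.create(root)
emb <- make_sphere_phantom(c(60, 60, 60), radius = 25, kind = "u8")
write_store(emb, file.path(root, "embryo.blk"))     # chunked lazy-read store

srv <- iip3d_server(root = root)
cat(handle_request(srv, "WLZ=/embryo.blk&OBJ=Wlz-3d-bounding-box")$body)
#> Wlz-3d-bounding-box:4 4 4 54 54 54
cat(handle_request(srv, "WLZ=/embryo.blk&OBJ=Wlz-volume")$body)
#> Wlz-volume:65267
cat(handle_request(srv, "WLZ=/embryo.blk&PAB=29,29,29&OBJ=Wlz-grey-value")$body)
#> Wlz-grey-value:0

q <- "WLZ=/embryo.blk&MOD=up_is_up&PIT=30&YAW=40&FXP=29,29,29&DST=0"
cat(handle_request(srv, paste0(q, "&OBJ=Wlz-sectioning-angles"))$body)
#> Wlz-sectioning-angles:30 40 90
cat(handle_request(srv, paste0(q, "&OBJ=Max-size"))$body)
#> Max-size:73 89
r <- handle_request(srv, paste0(q, "&PTL=0,0"))
cat(r$mime, length(r$body), "bytes\n")
#> image/png 1258 bytes
```

Reading the output: the digital ball of radius 25 occupies voxels 4–54 on
each axis and contains 65,267 voxels (`Wlz-volume` is the voxel count;
multiply by the voxel-size product from `Wlz-true-voxel-size` for physical
volume). The grey value at the centre is 0 because the phantom codes each
voxel's distance from the centre. Under *up-is-up* with pitch 30°/yaw 40°
the solved roll is 90°, the oblique section frame is 73×89 px, and the
first PNG tile of that section is 1,258 bytes — with alpha 0 wherever the
plane leaves the ball's domain.

The same machinery is scriptable from a shell via `inst/exec/iip3d`
(subcommands `serve`, `query`, `cut`, `convert`, `fixtures`).

## Documentation

The methods vignette (`vignettes/virtual-sectioning.Rmd`) describes the
domain model, the transform conventions and mode constructions, sampling
and pyramid semantics, the protocol and cache design, the block-store byte
layout, and what the phantom-based tests do and do not establish.
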