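---
title: "Virtual sectioning of large 3D images: models, geometry and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual sectioning of large 3D images: models, geometry and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iip3d)
```

Biomedical volumes — histology reconstructions, embryo atlases,
whole-body colour scans — now routinely exceed what a desktop can hold in
memory or a user can download. What a biologist usually needs, though, is a
single 2D *virtual section* at an arbitrary orientation, delivered at screen
resolution. `iip3d` implements the full stack behind that idea: a compact
spatial-domain model, the sectioning geometry, overlay compositing for
indexed anatomy regions, a tiled delivery protocol with caching, and a
chunked on-disk store so volumes far larger than memory can be sectioned by
touching only a handful of disk blocks.

## Interval-coded domains

An image object here is not a rectangular array. Its *domain* — the
arbitrary point-set of 3D space where the image is defined — is stored
separately from its values, as a planewise stack of per-line column
*intervals* (maximal runs `[k_first, k_last]`). Planes or lines without
foreground are simply absent. The representation has three consequences the
rest of the package leans on:

* storage scales with the region's boundary complexity, not its bounding
  box (a test asserts `interval count <= voxel count` on every random
  domain it draws);
* binary set operations (union, intersection, difference) reduce to
  interval merging — `domain_binary_op()` never densifies its operands; an
  encoded one-axis sweep with a one-cell guard gap between lines handles
  all three operations in one pass;
* regions with no values at all (anatomy delineations, expression domains)
  are first-class objects.

Coordinates are integer triples `(k, l, p)` (column, line, plane), inclusive
on both ends, any sign. Equal point-sets have structurally equal interval
tables because intervals are kept in maximal-merge normal form, so domain
equality is cheap and exact.

Value tables are held as dense numeric arrays over the tight bounding box
(column fastest, then line, then plane). This is a deliberate deviation from
packing values per interval: vectorised sampling in R indexes an array far
faster than it can walk runs, and the domain — where the compactness
argument actually matters — stays interval-coded. Out-of-domain cells hold
the background value and are unreachable except through the interval
membership test, so the representation of a volume is unique given
(domain, in-domain values). Supported value kinds are `u8`, `u16`, `u32`,
`f32` and `rgba`; `u32` values live in doubles (exact below 2^53).

A *compound object* is an ordered list of members sharing one coordinate
frame. Members may overlap and the index space is unbounded — it is not an
8-bit label image — which is exactly what atlas annotation needs: a voxel
can belong to `cortex` and to `forebrain` at once, and `members_at()`
therefore returns a list of indices, not one label.

## The sectioning transform

A section is specified by a fixed point $f$ (the rotation centre), three
angles in degrees, a signed distance $d$ and a magnification $s > 0$:

$$ v' = s\, R_z(\mathrm{roll})\, R_y(\mathrm{pitch})\, R_z(\mathrm{yaw})\,(v - f), $$

with the section plane $z' = d$. Axes are right-handed with `x` = column,
`y` = line, `z` = plane; rows grow downward so screen-up is $-y$. The
elementary rotations turn the *frame* (yaw 90° maps object $+x$ to view
$-y$); the composition order and signs are pinned by unit tests against an
independent axis-angle (Rodrigues) construction, because no two atlas tools
agree on Euler conventions and silent convention drift is the classic
failure mode here. Note that $d$ is measured in *view* units: doubling $s$
doubles the $z'$ of every object point.

Four viewing modes trade freedom for usability:

* **absolute** — all three angles explicit;
* **statue** — roll pinned to 0; with nonzero pitch, changing yaw makes the
  section appear to rotate like a statue on a turntable;
* **up-is-up** — roll is solved so the in-plane projection of a reference
  up vector (default $(0,0,-1)$) lands on the screen-up axis. Writing the
  rotated up vector's in-plane part as $r(\cos\phi, \sin\phi)$, the unique
  solution in $(-180°, 180°]$ is $\mathrm{roll} = \phi + 90°$; it exists iff
  the up vector is not parallel to the viewing axis (that degenerate case is
  a hard error, not a fallback);
* **fixed-line** — two fixed points define a line that must stay in the
  section plane, leaving one degree of freedom (`line_angle`). We construct
  the plane normal by rotating a reference perpendicular around the line,
  read pitch and yaw from its spherical coordinates, and choose roll so the
  line's screen image is the $+x$ axis — hence the image of the fixed line
  is invariant under `line_angle`, which the tests assert across a sweep.
  The distance is forced to 0 so both points actually lie on the plane.
  The exact parametrisation of this mode is a design choice of this
  package; only the invariant (line in plane, one residual rotation) is
  externally imposed.

`section_frame()` bounds the raster by transforming the eight corners of the
object bounding box, with the frame deliberately independent of $d$: tile
indices and offsets must not change while a user scrolls through depth.
`project_point()` / `unproject_point()` convert between screen and object
space; unprojecting two marked screen points and taking the 3D distance is
the measurement tool.

## Cutting sections

`cut_section()` inverse-maps every output pixel centre through the affine
transform and samples the volume. Choices that matter:

* **Sampling.** Nearest-neighbour by default — histology atlases expect
  unaltered grey values — with trilinear as an opt-in for grey kinds.
  Domain masks are always nearest-neighbour; interpolating labels is
  meaningless. Rounding is `floor(v + 0.5)` per axis, ties toward $+\infty$,
  stated once and shared with the test oracles.
* **Levels.** Resolution level $\ell$ samples the section grid sparsely at
  steps of $2^\ell$ (pixel $x$ samples section coordinate
  $x\,2^\ell + x_\mathrm{off}$). Because each pixel's sample point depends
  only on its absolute coordinates, a mosaic of tiles equals the one-shot
  cut bit-for-bit at every level.
* **Downscaling.** `downscale()` reduces by a $2^\ell$ box filter (plain
  mean, integer kinds re-quantised round-half-up) for values and any-true
  for masks. Note the two pyramid paths differ by construction: on a linear
  ramp the box filter returns the window-centre value while sparse sampling
  returns the window corner, a gap of $((2^\ell - 1)/2)$ per unit slope —
  the tests assert this closed form rather than pretending the paths agree.
  The service's full-section (`CVT`) levels use the box-filter path (one
  reduced image of the whole frame); tile levels use sparse sampling (so
  tiles mosaic exactly).
* **Outside.** Out-of-volume and out-of-domain pixels both report
  `inside = FALSE`; encoders turn that into alpha 0 (PNG) or background
  (JPEG).

## Overlays

A `SEL` entry selects member `index` and assigns `r,g,b,a` (0–255).
Domain-only members are painted with the colour at the given alpha;
value-bearing layers are colour-filtered: display grey $g_0$ becomes
$(\lfloor g_0 r/255\rfloor, \lfloor g_0 g/255\rfloor, \lfloor g_0
b/255\rfloor, a)$, RGBA input is filtered channelwise. Layers composite with
source-over in request order; arithmetic runs in premultiplied float and is
quantised to 8 bits only once at the end, which keeps the operator
associative and avoids cumulative integer bias. Abbreviated `SEL` forms
default omitted channels to 255; the two-argument form is read as
`(index, alpha)` — colour defaults to white and per-layer opacity is the
control users actually reach for. An out-of-range index is a loud protocol
error, not a silent skip: atlas curation errors should fail visibly.

## The protocol

Requests are `&`-separated `CMD=value` pairs (tokens case-insensitive):
`WLZ` names the resource under the server's object root (traversal outside
the root is rejected), `FXP/PIT/YAW/ROL/DST/SCL/MOD/UPV/FX2/LNA` set the
view, any number of `SEL`s set overlays, and exactly one of `JTL`/`PTL`/
`TIL` (jpeg/png/raw tile, value `level,index`), `CVT` (full section,
`png|jpeg[,level]`) or `OBJ` (query) asks for something. Probe points ride
along as `PRT=x,y` (section-frame pixels) or `PAB=k,l,p` (3D). Replies to
queries are `Name:value` lines, values space-separated — e.g.
`Wlz-grey-value:73` — and an out-of-domain grey query answers
`Wlz-grey-value:outside`. `Wlz-volume` reports the voxel count; physical
volume is the count times the voxel-size product, available via
`volume_stats()` and the `Wlz-true-voxel-size` query, so both readings of
"volume" are a one-liner for callers.

Three LRU caches back the service: encoded tiles keyed by (resource,
resolved view, SEL stack, level, tile, format, quality); opened objects by
path; resolved transforms by view digest. Every response is a pure function
of (resource bytes, query, configuration) — the tests compare cached,
recomputed and cache-bypassed responses byte for byte, and perturbing yaw
by a random fraction of a degree must miss the cache yet still match the
per-pixel oracle. The proxy is purely string-level: an ordered substring
table routes a request to the first matching backend, else the default, so
it can front any mixture of servers without parsing.

Transport is plain HTTP (`serve_iip3d()`, a minimal blocking socket loop);
the protocol logic lives entirely in `handle_request()`, which is what the
tests exercise. JPEG encoder quality is pinned in the server configuration
so byte-determinism holds per installation.

## The block store

`write_store()`/`open_store()` implement a simple chunked container: header,
the full interval domain, a block lookup table, then fixed-size cuboidal
value blocks. Design points:

* block byte size must be a multiple of the filesystem block (default
  4096 B); defaults per kind are 32×32×32 (1-byte), 32×32×16 (2-byte) and
  32×32×8 (4-byte and rgba), all 32 KiB;
* blocks wholly outside the domain are absent — a LUT zero — and occupy no
  bytes; edge blocks are stored full-size, background-padded, so every
  offset is computable without per-block size fields;
* opening a store loads header, domain and LUT eagerly and nothing else;
  values are fetched block-by-block on demand and cached. An instrumented
  counter reports the distinct blocks each operation touched: one voxel
  touches 1 block, an axis-aligned plane of a 100³/32³ store touches at
  most 16 of 64, and the full test matrix asserts lazy and in-memory
  volumes are bit-identical in every query, section and overlay.

The byte layout is documented in `?block-store`. TIFF-stack conversion
streams planes in two passes (domain, then blocks) holding one block-slab in
memory; NIfTI conversion goes through `RNifti`, which reads the array whole
— acceptable because NIfTI files of the sizes that need streaming should be
converted once to the store format anyway.

## Phantoms, and what passing tests do not show

All tests run on synthetic phantoms with closed-form answers:
`make_gradient_volume()` (value $= k + 10l + 100p$, coefficients chosen so
any single transposed axis or off-by-one corrupts every pixel visibly),
`make_sphere_phantom()` (digital ball, distance-coded greys),
`make_compound_phantom()` (members with controlled pairwise overlap, member
counts in the hundreds), and `make_rgb_phantom()` (separable channel ramps).
All are reproducible from their parameters; tests pin digests.

These phantoms exercise geometry, coding and protocol exactly, but they are
not histology: no texture, no noise, no anisotropic point-spread, no
registration error. Passing this suite shows the machinery is correct, not
that nearest-neighbour sampling is the right aesthetic for a given stained
section — that remains the operator's choice (use `interp = "trilinear"`
for smoother grey imagery). One phantom subtlety is intentional: the
sphere's centre voxel has grey 0, so converting it with background-0
thresholding drops that one voxel from the domain — the conversion tests
assert against the honest nonzero-count oracle.

Test problem sizes (12³–100³ volumes, 20 random views for the bit-exact
oracle comparison, 1000 random geometry round-trips, 100 random domain
pairs) were chosen so the whole suite runs in well under a minute while
still crossing every block boundary and mode branch; the oracle loops are
deliberately naive per-pixel R code.

## Numerical and degenerate-input policy

Angles normalise to $(-180°, 180°]$. Rotations are orthonormal to 1e-9 and
round-trip object points to 1e-6 (asserted over 1000 random views). Empty
domains are representable everywhere; `bounding_box()` of an empty domain is
an explicit error rather than a sentinel. Degenerate view modes (up parallel
to the viewing axis, coincident fixed points) raise errors naming the
degeneracy. The over-operator quantises once, round-half-up. Tile grids use
ceiling arithmetic with cropped edge tiles; a 700×400 section at 256-px
tiles is exactly 3×2 = 6 requests.

## Known limitations

No perspective or curved sections; no thick-slab projections; no in-block
compression or multi-file sharding; no HTTP cache negotiation or
authentication; JPEG byte-determinism is per-installation (libjpeg version
pinned by the environment, not by this package). The `u32` TIFF export path
is unsupported (TIFF stacks carry 8/16-bit and float); use NIfTI or the
block store for 32-bit data.
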