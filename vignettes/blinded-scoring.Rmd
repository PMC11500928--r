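---
title: "Blinded segment scoring: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blinded segment scoring: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many experiments end in a human watching videos or inspecting images and
assigning categories: which well's animal seized first, which culture
migrated, which habitat photo shows disturbance. When the scorer knows the
experimental condition attached to each recording — even indirectly — the
scores drift toward expectation (confirmation, hindsight and anchoring
biases). The classical remedy, handing the data to a naive colleague, costs
personnel and only dilutes the knowledge.

`blindcut` removes the knowledge instead. The workflow is:

1. **Segment.** Each source video or image is cut into labeled rectangular
   regions (typically one well of a multi-well plate per region). Segments
   from many source files of the same media type are pooled.
2. **Randomize.** The pooled segments are shuffled exactly once with an
   explicit Fisher-Yates pass, and each segment receives a blinded ID that
   encodes only its presentation rank.
3. **Score.** Segments are presented in shuffled order, by blinded ID and
   media content alone. Free-text notes are collected for each user-named
   stage. Scoring can be paused and resumed at any time; the order never
   changes.
4. **Unblind.** After the last segment, scores are joined back to labels
   and source files and written as a results table (CSV and XLSX).

The same researcher who ran the experiment can therefore score it blind:
during step 3 nothing visible carries the label (`B7`), the source filename
(`plate_15mM_PTZ.avi`) or anything derived from them.

## Randomization

`fisher_yates_shuffle(n, seed)` is the textbook backward loop: for
`i = n, n-1, ..., 2` draw `j` uniformly on `1..i` and swap positions `i`
and `j`. Each of the `n!` permutations has probability `1/n!` provided the
per-step draws are uniform; the draws use `sample.int()` on R's default
Mersenne-Twister generator, which is unbiased for this purpose. The test
suite verifies uniformity empirically: 24,000 independently seeded shuffles
of 4 segments, a chi-square test over the 24 permutation counts (23 df),
requiring `p > 0.001`.

The shuffle runs once, in `create_session()`, only after *all* media have
been segmented — shuffling per file would leak block structure. The
permutation and the blinded IDs are immutable for the life of the session;
`resume_session()` re-validates them and refuses to load (rather than
re-randomize) anything corrupt.

The underlying tool this package models is not seedable; seedability here
is an addition for reproducibility and testing. When no seed is given one
is drawn from the ambient RNG and recorded in the state file for audit.
Library code always restores the caller's RNG state.

## Blinded identifiers

Blinded IDs are `"S"` plus the zero-padded presentation rank (`S001` is
scored first). Rank is the one thing the scorer can see anyway, so the ID
carries zero additional information. The pad width is chosen as
`max(3, ndigits(n) + 1)`, which guarantees a leading zero in every ID.
Because segment labels (`[A-Z]` followed by `1`-`36`, no leading zeros) can
never contain a letter followed by `0`, no blinded ID can contain any valid
label as a substring, for any session size. `create_session()` additionally
scans every ID against all labels and source-file stems and rejects the
(pathological) colliding cases outright.

The label-to-ID mapping lives only in `session.json`, which the review
machinery never prints; blinded media are written under `blind/` named by
ID only, re-encoded from decoded pixels so no container metadata (source
name tags, creation time) can ride along.

## Segmentation geometry

Rectangles use 0-based, half-open pixel coordinates: `rect_spec(x, y, w, h)`
covers columns `[x, x+w)` and rows `[y, y+h)`. Rectangles must lie fully
inside the frame; out-of-bounds input is an error, never clamped, because
silent clamping would alter segment content invisibly. Overlap between
rectangles is allowed. Cropping is a pure subarray copy — output pixel
`(r, c)` of frame `t` equals source pixel `(y+r, x+c)` of frame `t` —
so crops are bit-exact and resolution is preserved by construction.

Labels follow the well-plate convention (`A1` .. `Z36`). The grammar is
deliberately strict — one uppercase letter, then `1`-`36` without leading
zeros — and uniqueness is enforced across the *whole* analysis, since
segments from all batched files end up in one shuffled pool. Letter-only or
number-only labels are excluded by the grammar. `plate_grid()` expands a
(rows, cols, origin, pitch, well size) shorthand into the full labeled grid
for plate layouts.

## Media formats

Supported inputs are `.mp4`/`.avi` video and `.png`/`.jpg`/`.jpeg`/`.bmp`
images. Internally every frame is an integer array `height x width x
channels` in 0..255.

* PNG and JPEG go through the `png` and `jpeg` packages. PNG and BMP are
  lossless and round-trip bit-exactly; JPEG is lossy and contracts only on
  dimensions.
* AVI is read and written by a container codec in this package supporting
  raw 24-bit DIB frames (lossless; the default for blinded segments, so
  the scorer sees exactly the cropped pixels) and MJPEG. BMP shares the
  same DIB pixel layout.
* MP4 files are probed structurally (box tree: `tkhd` dimensions, `stsz`
  sample count, `mdhd` timescale) so batch selection can report them, but
  compressed MP4 payloads cannot be decoded; converting to AVI is required
  for segmentation. Segment output for video is always AVI.

Re-encoding rather than stream-copying is a deliberate blinding choice:
a stream copy would preserve container metadata that can identify the
source.

## Session persistence

The session state is a single pretty-printed JSON document with a
`schema_version` field, containing the stages, segment definitions, the
1-based permutation, the blinded IDs, the per-ID score records and the
cursor. Every `record_score()` rewrites it atomically
(write-temporary-then-rename), so a crash loses at most the segment being
scored, and notes commit per segment — a draft for a half-scored segment
does not survive a pause, which keeps the resume semantics exact.
`resume_session()` re-checks every invariant (permutation validity, ID
distinctness, cursor/scores consistency, stage coverage) and raises a load
error on any mismatch.

One R-dialect note: frame indices (`read_frame`) and permutations are
1-based, as everywhere in R; rectangle pixel coordinates remain 0-based as
defined above because they live in language-neutral JSON configs.

## Unblinded output

`unblind()` produces one row per segment — label, source filename, then
one column per stage in definition order — sorted by source file and then
natural well order (`A2` before `A10`; letter first, then numeric value).
The sort is a readability choice; the join itself is order-free and tested
to be shuffle-invariant. CSV is the canonical output (UTF-8, RFC-4180
quoting, byte-stable across repeated exports); the XLSX written alongside
is a minimal single-sheet workbook with inline strings, cell-for-cell
identical to the CSV, for spreadsheet-based downstream analysis. Partial
export (`partial = TRUE`) fills unscored rows with `"pending"` rather than
dropping them, so row count always equals segment count.

## The synthetic plate generator

`plate_spec()` / `generate_plate_video()` emulate the kind of recording
this workflow targets: a multi-well plate filmed from above, one animal
per well, with motion amplitude depending on an assigned condition. Each
well holds one bright filled disk (radius `well_size/8`) on a dark field
with faint well outlines. Per frame, the disk center takes a step of fixed
length equal to the well's *activity level* (pixels/frame) in a uniformly
random direction, reflecting off the well walls, so the blob never leaves
its well and per-frame displacement never exceeds the level. Everything is
deterministic given the seed, and the generator returns exact ground truth
(well rectangles, conditions, full trajectories).

Defaults are one fixed set of study conditions: a 3x4-well plate, 40 px
wells on a 48 px pitch, 200 frames at 25 fps, and activity levels
{0, 2, 6} px/frame assigned to whole rows — a stationary control plus two
motion amplitudes separated enough (3x) that any reasonable
intensity-difference scorer must order them. These sizes keep a full
end-to-end run (generate, segment, blind-score, export) comfortably small
while leaving dozens of pixels of travel per blob.

`activity_score()` is the deterministic stand-in for the human scorer: the
mean over consecutive frame pairs of the mean absolute per-pixel
difference. It is 0 exactly when all frames are identical and increases
with blob motion until steps are large relative to the blob.

What the generator does *not* emulate: real animal kinematics (burst
swimming, turning statistics, seizure stages), sensor noise, illumination
drift, shadows or occlusion, or between-well optical crosstalk. Passing
the end-to-end recovery test therefore demonstrates that the *pipeline* —
cropping, blinding, order bookkeeping, unblinding joins — is faithful, not
that frame differencing is a good behavioral assay for real recordings.
Notably, control wells score exactly 0 only because the synthetic
background is static and the segment codec lossless; real video noise
would put a positive floor under every well.

## Problem sizes and numerical choices

The test suite and acceptance checks use: 24,000 shuffles of `n = 4` for
the uniformity chi-square; 100 random rectangles (plus a 10-frame video)
for crop exactness; a 60-segment session (labels `A1`-`E12`) for
resume-equivalence and the output contract; and the 3x4 plate at 200
frames for condition recovery. These sizes were chosen so every property
is exercised with comfortable statistical margin while the whole suite
runs in well under a minute of compute on one core.

Other fixed choices: the fallback frame rate when a source reports none is
25 fps; segment videos inherit the source fps; JPEG/MJPEG quality is 0.95;
the XLSX writer stamps fixed file times inside the archive so repeated
exports are byte-identical.

## Known limitations

* No GUI and no embedded player: review prints the blinded media path and
  delegates playback to the user's player (batch scoring via CSV exists so
  pipelines and tests can drive review headlessly).
* MP4 is probe-only; `.mov`, TIFF and multi-page formats are unsupported.
* Rectangles only — by design, since free-form outlining reintroduces
  selection bias.
* Labels are capped at 26 rows x 36 columns by the grammar.
* Stage names and labels are immutable once the session exists; there is
  deliberately no re-randomization command.
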