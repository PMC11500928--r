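# blindcut

Blinded segmentation, randomization and scoring of video and image data.

## The problem

Scoring videos or images by eye — which zebrafish larva seized first,
which well's culture migrated, which habitat photo shows disturbance — is
vulnerable to the scorer's expectations. If the person watching knows that
column 1 of the plate got 15 mM PTZ and column 12 got none, the scores
drift toward the expected dose-response. `blindcut` lets a single
researcher score their own experiment blind:

1. **segment** — cut each source video/image into labeled rectangular
   regions (e.g. one well per region; labels are well-style, `A1`..`Z36`,
   unique across all batched files);
2. **randomize** — shuffle the pooled segments once with an explicit
   Fisher-Yates pass (for `i = n..2`, swap `i` with a uniform draw from
   `1..i`, so all `n!` orders are equally likely) and write each segment
   to a blinded media file named only `S001`, `S002`, ... by presentation
   rank;
3. **review** — score the segments in shuffled order, entering free-text
   notes for each user-named stage; pause and resume freely, the order is
   immutable and persisted;
4. **export** — unblind: join the notes back to labels and source files
   and write `results.csv` + `results.xlsx`.

During review nothing visible — filenames, presentation bundles, the
transcript — contains any label or source-filename substring. A synthetic
multi-well-plate generator (moving blob per well, motion amplitude set by
an assigned activity level, exact ground truth) plus a frame-differencing
`activity_score()` make the whole pipeline testable end-to-end without any
real recordings.

## Worked example

```r
library(blindcut)

td <- tempfile(); dir.create(td)

# a synthetic 2x3-well plate, 20 frames; row A still, row B moving
synth <- file.path(td, "synth")
cmd_synth(synth, rows = 2, cols = 3, frame_count = 20, levels = c(0, 3), seed = 5)

# segment + shuffle + blind (the shuffle happens exactly once, here)
res <- file.path(td, "res")
cmd_segment(file.path(synth, "plate.avi"), file.path(synth, "segmentation.json"),
            stages = c("activity"), results_dir = res, seed = 6)
list.files(file.path(res, "blind"))
#> [1] "S001.avi" "S002.avi" "S003.avi" "S004.avi" "S005.avi" "S006.avi"

# blinded scoring with the automated frame-difference scorer
ids <- sprintf("S%03d", 1:6)
obs <- sapply(ids, function(id)
  activity_score(read_frames(file.path(res, "blind", paste0(id, ".avi")))))
cmd_review(res, scores = data.frame(blinded_id = ids, activity = round(obs, 2)))
#> [1/6] S001 blind/S001.avi scored
#> ...
#> session complete (6/6 scored)

# unblind
paths <- cmd_export(res)
read_results_csv(paths["csv"])
#>   label source_file activity
#> 1    A1   plate.avi        0
#> 2    A2   plate.avi        0
#> 3    A3   plate.avi        0
#> 4    B1   plate.avi     7.08
#> 5    B2   plate.avi     7.88
#> 6    B3   plate.avi     7.86
```

Row A (activity level 0) scores exactly 0 — its blobs never move and the
blinded AVI segments are lossless; row B (level 3 px/frame) scores high.
The notes entered under each blinded ID landed on the correct labels even
though they were scored in shuffled order.

The same workflow is available from the shell via the installed script
(`system.file("exec", "blindcut", package = "blindcut")`):

```sh
blindcut synth   --out synth --rows 2 --cols 3 --frames 20 --levels 0,3 --seed 5
blindcut segment --source synth/plate.avi --config synth/segmentation.json \
                 --stages activity --out res --seed 6
blindcut review  --dir res --scores scores.csv
blindcut export  --dir res
```

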