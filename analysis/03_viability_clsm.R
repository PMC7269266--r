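#!/usr/bin/env Rscript
# Stained-slice viability: Otsu-binarize the green and red channels of each
# simulated slice, close and fill, intersect into live/dead/overlap regions
# and report the live ratio, alongside the generator's analytic truth.

suppressMessages(library(pelletmetrics))

DATA <- "results/data"; OUT <- "results/clsm"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)
if (!dir.exists(DATA)) stop("no simulated data found - run analysis/01_simulate.R first")

rows <- list()
for (cn in c("no_beads", "beads")) {
  cdir <- file.path(DATA, cn)
  green <- read_pellet_tiff(file.path(cdir, "slice_green.tif"))
  red <- read_pellet_tiff(file.path(cdir, "slice_red.tif"))
  sh <- analyze_slice(green, red,
                      overlay_png = file.path(OUT, sprintf("overlay_%s.png", cn)))
  truth <- read.csv(file.path(cdir, "slice_truth.csv"))
  rows[[cn]] <- data.frame(condition = cn, live_share = sh$live_share,
                           dead_share = sh$dead_share,
                           overlap_share = sh$overlap_share,
                           live_ratio = sh$live_ratio,
                           total_area_um2 = sh$total_area_um2,
                           true_live_share = truth$live_share,
                           true_dead_share = truth$dead_share)
  cat(sprintf("[%s] live ratio %.3f (truth %.3f), dead %.3f, overlap %.3f\n",
              cn, sh$live_ratio, truth$live_share, sh$dead_share,
              sh$overlap_share))
}
write.csv(do.call(rbind, rows), file.path(OUT, "viability_shares.csv"),
          row.names = FALSE)
cat("slice viability written to", OUT, "\n")
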