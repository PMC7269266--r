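#!/usr/bin/env Rscript
# Generate the synthetic raw data for the whole analysis: brightfield
# fields, stained-slice channel pairs, flow-cytometry pulse profiles and
# cultivation series for two conditions ("no_beads" = unsupplemented,
# "beads" = glass-bead supplemented). Everything is seeded, and written in
# the package's interchange formats so later scripts exercise the same IO a
# real dataset would.

suppressMessages(library(pelletmetrics))

SEED <- 20260923L
DATA <- "results/data"
dir.create(DATA, recursive = TRUE, showWarnings = FALSE)

conditions <- list(
  no_beads = list(meanlog = 5.088, sdlog = 0.344, ecc = 0.75,
                  clsm = c(outer = 260, core_frac = 0.95, overlap = 12),
                  shell_frac = 0.32, core_frac = 0.55, flg_gain = 13,
                  P_max = 38, prod_rate = 0.8),
  beads = list(meanlog = 4.57, sdlog = 0.42, ecc = 0.5,
               clsm = c(outer = 170, core_frac = 0.88, overlap = 10),
               shell_frac = 0.41, core_frac = 0.42, flg_gain = 14,
               P_max = 95, prod_rate = 1.2))

set.seed(SEED)
seeds <- sample.int(2^31 - 2L, 100L); si <- 0L
nxt <- function() { si <<- si + 1L; seeds[si] }

for (cn in names(conditions)) {
  cc <- conditions[[cn]]
  cdir <- file.path(DATA, cn)
  dir.create(file.path(cdir, "pulses"), recursive = TRUE, showWarnings = FALSE)

  # three brightfield fields with ground truth
  for (k in 1:3) {
    g <- generate_pellet_image(image_gen_params(
      image_width_px = 1024L, image_height_px = 768L, n_pellets = 30L,
      diameter_lognormal_mu = cc$meanlog, diameter_lognormal_sigma = cc$sdlog,
      eccentricity_max = cc$ecc, seed = nxt()))
    write_pellet_tiff(g$image, file.path(cdir, sprintf("field_%02d.tif", k)))
    write.csv(g$truth, file.path(cdir, sprintf("field_%02d_truth.csv", k)),
              row.names = FALSE)
  }

  # one stained equatorial slice
  cl <- cc$clsm
  pair <- generate_clsm_pair(cl[["outer"]],
                             cl[["core_frac"]] * cl[["outer"]] - 2 * cl[["overlap"]],
                             cl[["overlap"]], pixel_size_um = 2,
                             noise_sd = 0.04, seed = nxt())
  write_pellet_tiff(pair$green, file.path(cdir, "slice_green.tif"))
  write_pellet_tiff(pair$red, file.path(cdir, "slice_red.tif"))
  write.csv(as.data.frame(unclass(pair$truth)),
            file.path(cdir, "slice_truth.csv"), row.names = FALSE)

  # a stained pulse population in the CSV/JSON dialect
  pop <- generate_pulse_population(
    n = 60L, base_params = pulse_gen_params(flg_gain = cc$flg_gain),
    diameter_meanlog = cc$meanlog, diameter_sdlog = cc$sdlog,
    viable_shell_frac = cc$shell_frac, dead_core_frac = cc$core_frac,
    seed = nxt())
  for (i in seq_along(pop$profiles))
    write_pulse_profile(pop$profiles[[i]],
                        file.path(cdir, "pulses", sprintf("p%03d.csv", i)))
  write.csv(pop$truth, file.path(cdir, "pulses_truth.csv"), row.names = FALSE)

  # cultivation series
  s <- generate_cultivation_series(
    cultivation_gen_params(P_max = cc$P_max, production_rate = cc$prod_rate,
                           seed = nxt()), condition = cn)
  write.csv(as.data.frame(s), file.path(cdir, "cultivation.csv"),
            row.names = FALSE)
  cat(sprintf("[%s] 3 fields, 1 slice pair, %d pulses, %d culture points -> %s\n",
              cn, length(pop$profiles), nrow(s), cdir))
}
cat("synthetic raw data complete\n")
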