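#' Live/dead/overlap area shares of a stained pellet slice
#'
#' Container for the three-region decomposition of a dual-stained slice:
#' solely-green (live), solely-red (dead) and doubly stained (overlap) areas,
#' each as a fraction of the total stained area (the union of both masks).
#' The live ratio is living area over total area; under the solely-green
#' convention adopted here it equals `live_share`. Set
#' `live_includes_overlap = TRUE` to count doubly stained area as living.
#'
#' @param live_share,dead_share,overlap_share Area fractions in \[0, 1\]
#'   summing to 1.
#' @param total_area_um2 Stained (union) area in um^2.
#' @param live_includes_overlap Alternative live-ratio convention.
#' @return A `viability_shares` record (list).
#' @export
viability_shares <- function(live_share, dead_share, overlap_share,
                             total_area_um2, live_includes_overlap = FALSE) {
  s <- c(live_share, dead_share, overlap_share)
  if (any(s < -1e-9 | s > 1 + 1e-9) || abs(sum(s) - 1) > 1e-9)
    stop("shares must lie in [0, 1] and sum to 1")
  structure(list(live_share = live_share, dead_share = dead_share,
                 overlap_share = overlap_share,
                 live_ratio = if (live_includes_overlap)
                   live_share + overlap_share else live_share,
                 total_area_um2 = total_area_um2),
            class = "viability_shares")
}

#' @export
print.viability_shares <- function(x, ...) {
  cat(sprintf("<viability_shares> live %.3f | dead %.3f | overlap %.3f | live ratio %.3f | total %.4g um^2\n",
              x$live_share, x$dead_share, x$overlap_share, x$live_ratio,
              x$total_area_um2))
  invisible(x)
}

#' Global Otsu binarization of a fluorescence channel
#'
#' Thresholds the channel at the gray level maximizing the between-class
#' variance of the 256-bin intensity histogram; foreground is everything
#' above the threshold (fluorescent signal on a dark background).
#'
#' @param channel A [pellet_image()] or numeric matrix.
#' @return Logical matrix, `TRUE` = foreground, with the chosen threshold
#'   attached as attribute `threshold`.
#' @export
binarize_otsu <- function(channel) {
  x <- unclass(channel)
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate histogram: channel is constant")
  thr <- EBImage::otsu(EBImage::Image(x), range = rng, levels = 256L)
  structure(x > thr, threshold = as.numeric(thr))
}

#' Morphological closing and hole filling of a binary mask
#'
#' Closes the mask with a disk-shaped structuring element of the given
#' diameter, then floods enclosed holes up to `max_hole_px` pixels — the
#' residual specks closing cannot bridge. The fill is bounded on purpose: a
#' genuinely unstained interior (a dead core absent from the green channel)
#' is a real region of the slice, not a defect, and must survive so the
#' three-region decomposition can see it. The output is a superset of the
#' input.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param se_diameter_px Structuring-element diameter in pixels (default 5).
#' @param max_hole_px Largest enclosed hole (in px) that is flood-filled;
#'   defaults to `se_diameter_px^2`.
#' @return Logical matrix.
#' @export
close_and_fill <- function(mask, se_diameter_px = 5L,
                           max_hole_px = se_diameter_px^2) {
  m <- (unclass(mask) > 0) * 1
  brush <- EBImage::makeBrush(as.integer(se_diameter_px), shape = "disc")
  out <- EBImage::closing(m, brush) > 0
  holes <- EBImage::bwlabel(!out)
  hl <- matrix(as.integer(holes), nrow(out), ncol(out))
  border <- unique(c(hl[1L, ], hl[nrow(hl), ], hl[, 1L], hl[, ncol(hl)]))
  sizes <- tabulate(hl)
  fill_ids <- setdiff(which(sizes > 0 & sizes <= max_hole_px), border)
  if (length(fill_ids)) out[hl %in% fill_ids] <- TRUE
  matrix(out, nrow(m), ncol(m))
}

#' Three-region decomposition of green/red masks into viability shares
#'
#' Total stained area is the union of the two masks; overlap is their
#' intersection; live is solely green; dead is solely red. Shares are region
#' pixel areas over the union area.
#'
#' @param green_mask,red_mask Logical matrices of equal shape.
#' @param pixel_size_um Calibration, um per pixel.
#' @param live_includes_overlap Passed to [viability_shares()].
#' @return A [viability_shares()] record.
#' @export
region_shares <- function(green_mask, red_mask, pixel_size_um,
                          live_includes_overlap = FALSE) {
  g <- unclass(green_mask) > 0; r <- unclass(red_mask) > 0
  if (!all(dim(g) == dim(r))) stop("channel masks differ in shape")
  total <- sum(g | r)
  if (total == 0) stop("empty union: no stained area in either channel")
  viability_shares(live_share = sum(g & !r) / total,
                   dead_share = sum(r & !g) / total,
                   overlap_share = sum(g & r) / total,
                   total_area_um2 = total * pixel_size_um^2,
                   live_includes_overlap = live_includes_overlap)
}

#' Quantify a dual-channel stained slice
#'
#' Full slice pipeline: per-channel Otsu binarization, closing and hole
#' filling, then the three-region live/dead/overlap decomposition. Optionally
#' writes an RGB overlay (green = live, red = dead, yellow = overlap) for
#' visual quality control.
#'
#' A channel whose Otsu split separates the two classes by less than
#' `min_separation` pooled within-class standard deviations is treated as
#' signal-free (empty mask): thresholding pure sensor noise would otherwise
#' invent a foreground covering a third of the frame.
#'
#' @param green,red Co-registered [pellet_image()]s of equal shape and
#'   calibration.
#' @param se_diameter_px Structuring element for [close_and_fill()].
#' @param live_includes_overlap Live-ratio convention switch.
#' @param min_separation Minimum Otsu class separation (in pooled
#'   within-class sds) for a channel to count as stained; default 4.
#' @param overlay_png Optional path; if given an RGB overlay PNG is written.
#' @return A [viability_shares()] record.
#' @export
analyze_slice <- function(green, red, se_diameter_px = 5L,
                          live_includes_overlap = FALSE, min_separation = 4,
                          overlay_png = NULL) {
  if (!all(dim(green) == dim(red))) stop("channel images differ in shape")
  if (abs(pixel_size(green) - pixel_size(red)) > 1e-12)
    stop("channel images differ in calibration")
  channel_mask <- function(channel) {
    m <- binarize_otsu(channel)
    x <- unclass(channel)
    mu_fg <- mean(x[m]); mu_bg <- mean(x[!m])
    sd_pooled <- sqrt((sum((x[m] - mu_fg)^2) + sum((x[!m] - mu_bg)^2)) /
                        max(1, length(x) - 2))
    if (!is.finite(sd_pooled) || sd_pooled == 0 ||
        (mu_fg - mu_bg) / sd_pooled >= min_separation)
      close_and_fill(m, se_diameter_px)
    else matrix(FALSE, nrow(x), ncol(x))
  }
  g <- channel_mask(green)
  r <- channel_mask(red)
  shares <- region_shares(g, r, pixel_size(green), live_includes_overlap)
  if (!is.null(overlay_png)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to write overlays")
    rgb <- array(0, c(dim(g), 3L))
    rgb[, , 1L] <- r * 1       # red + yellow
    rgb[, , 2L] <- g * 1       # green + yellow
    png::writePNG(rgb, overlay_png)
  }
  shares
}
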