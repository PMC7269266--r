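# Box local mean with symmetric (reflective) border padding, via an
# integral image; w must be odd.
local_mean_filter <- function(x, w) {
  h <- (w - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  ri <- c(h:1, 1:H, H:(H - h + 1L))[seq_len(H + 2L * h)]
  ci <- c(h:1, 1:W, W:(W - h + 1L))[seq_len(W + 2L * h)]
  pad <- x[ri, ci, drop = FALSE]
  S <- rbind(0, apply(pad, 2L, cumsum))
  S <- cbind(0, t(apply(S, 1L, cumsum)))
  r2 <- (1:H) + 2L * h; r1 <- 1:H
  c2 <- (1:W) + 2L * h; c1 <- 1:W
  (S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]) / w^2
}

#' Adaptive local-mean binarization of a brightfield image
#'
#' Each pixel is compared against the mean intensity of its `window_px` x
#' `window_px` neighbourhood (symmetric border padding). A pixel is
#' foreground when it is darker than that local mean by more than
#' `sensitivity` times the image dynamic range (`polarity = "dark"`, the
#' default for dark pellets on a bright background), or brighter by the same
#' margin (`polarity = "bright"`). The offset rule makes dark-mode on an
#' image and bright-mode on its intensity inversion exactly symmetric.
#'
#' @param image A [pellet_image()] or numeric matrix.
#' @param window_px Odd neighbourhood size in px (default 65).
#' @param sensitivity Offset as a fraction of the image dynamic range, in
#'   \[0, 1\] (default 0.1).
#' @param polarity `"dark"` or `"bright"` foreground.
#' @return Logical matrix, `TRUE` = foreground.
#' @export
binarize_local_mean <- function(image, window_px = 65L, sensitivity = 0.1,
                                polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  x <- unclass(image)
  window_px <- as.integer(window_px)
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("`window_px` must be an odd integer >= 3")
  if (window_px > min(dim(x)))
    stop("`window_px` larger than the image")
  stopifnot(sensitivity >= 0, sensitivity <= 1)
  lm <- local_mean_filter(x, window_px)
  offset <- pmax(sensitivity * diff(range(x)), 1e-9)
  if (polarity == "dark") (lm - x) > offset else (x - lm) > offset
}

#' Watershed splitting of a binary pellet mask
#'
#' Fills holes inside foreground blobs (pellet interiors may binarize
#' bright), then splits touching pellets at their necks by watershed on the
#' Euclidean distance transform, with catchment basins seeded at regional
#' maxima surviving h-maxima suppression of depth `h_min` px. Every
#' foreground pixel receives exactly one label.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param h_min Minimum distance-transform prominence (px) for a blob to be
#'   split; default 2.
#' @param fill_holes Fill enclosed holes before splitting (default `TRUE`).
#' @param opening_px Diameter of a disk opening applied first to strip
#'   ragged single-pixel fringes (hyphal corona speckle) off blob outlines;
#'   0 (the default) disables, [analyze_pellet_image()] passes 3.
#' @return Integer label matrix, 0 = background, 1..n = objects; attribute
#'   `n_objects` holds n.
#' @export
segment_watershed <- function(mask, h_min = 2, fill_holes = TRUE,
                              opening_px = 0L) {
  m <- (unclass(mask) > 0) * 1
  if (opening_px > 0 && any(m > 0))
    m <- EBImage::opening(m, EBImage::makeBrush(as.integer(opening_px), "disc"))
  if (!any(m > 0)) {
    lab <- matrix(0L, nrow(m), ncol(m))
    attr(lab, "n_objects") <- 0L
    return(lab)
  }
  if (fill_holes) m <- EBImage::fillHull(m)
  d <- EBImage::distmap(m)
  w <- EBImage::watershed(d, tolerance = h_min, ext = 1L)
  lab <- matrix(as.integer(w), nrow(m), ncol(m))
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    nz <- lab > 0L
    lab[nz] <- remap[lab[nz]]
  }
  attr(lab, "n_objects") <- length(ids)
  lab
}

# Moore-neighbour boundary trace of a single-object logical matrix (padded
# internally). Returns the closed chain of boundary pixel coordinates
# (row, col), or NULL for a single-pixel object. Termination uses the
# repeated-first-transition criterion (re-entering the start pixel and
# leaving it towards the same successor), which is robust to one-pixel
# spurs passing through the start.
trace_boundary <- function(M) {
  H <- nrow(M); W <- ncol(M)
  P <- matrix(FALSE, H + 2L, W + 2L)
  P[2:(H + 1L), 2:(W + 1L)] <- M
  idx <- which(P, arr.ind = TRUE)
  s <- idx[order(idx[, 1L], idx[, 2L])[1L], ]            # topmost-leftmost
  # clockwise 8-neighbourhood starting at W
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dir_of <- matrix(NA_integer_, 3L, 3L)                  # delta (dr, dc) -> index
  for (j in 1:8) dir_of[dr[j] + 2L, dc[j] + 2L] <- j
  cur <- c(s[1L], s[2L])
  back <- c(s[1L], s[2L] - 1L)                           # W neighbour, background
  chain <- matrix(0L, 4L * (H * W) + 8L, 2L); nch <- 0L
  second <- NULL
  repeat {
    d0 <- dir_of[back[1L] - cur[1L] + 2L, back[2L] - cur[2L] + 2L]
    found <- FALSE
    for (k in 1:8) {
      j <- ((d0 - 1L + k) %% 8L) + 1L
      r <- cur[1L] + dr[j]; c <- cur[2L] + dc[j]
      if (P[r, c]) {
        jprev <- ((d0 - 1L + k - 1L) %% 8L) + 1L         # last background scanned
        if (!is.null(second) && cur[1L] == s[1L] && cur[2L] == s[2L] &&
            r == second[1L] && c == second[2L]) {
          return(chain[seq_len(nch), , drop = FALSE])
        }
        back <- c(cur[1L] + dr[jprev], cur[2L] + dc[jprev])
        nch <- nch + 1L; chain[nch, ] <- c(r, c)
        if (nch == 1L) second <- c(r, c)
        cur <- c(r, c)
        found <- TRUE
        break
      }
    }
    if (!found) return(NULL)                             # isolated pixel
    if (nch >= 4L * H * W) return(chain[seq_len(nch), , drop = FALSE])
  }
}

# Perimeter (in px) of a single-object mask via its boundary chain, with
# Vossepoel-Smeulders step weights (0.948 straight, 1.340 diagonal), which
# remove most of the digitization bias of raw chain length.
perimeter_px <- function(M) {
  if (sum(M) == 1L) return(4 * 0.948)
  ch <- trace_boundary(M)
  if (is.null(ch) || nrow(ch) < 2L) return(4 * 0.948)
  d <- abs(diff(rbind(ch, ch[1L, , drop = FALSE])))
  diag <- d[, 1L] > 0L & d[, 2L] > 0L
  0.948 * sum(!diag) + 1.340 * sum(diag)
}

# Min/max Feret diameters (px) of a region given its pixel coordinates
# (0-based rows/cols), via rotating calipers on the convex hull of the pixel
# corner points.
feret_px <- function(rows, cols) {
  corners <- cbind(c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5),
                   c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  n <- nrow(hull)
  if (n == 1L) return(c(0, 0))
  dmax <- 0
  for (i in seq_len(n - 1L)) {
    dd <- sqrt((hull[(i + 1L):n, 1L] - hull[i, 1L])^2 +
               (hull[(i + 1L):n, 2L] - hull[i, 2L])^2)
    dmax <- max(dmax, dd)
  }
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2L], e[1L]) / len
    width <- max(abs((hull[, 1L] - hull[i, 1L]) * nrm[1L] +
                     (hull[, 2L] - hull[i, 2L]) * nrm[2L]))
    dmin <- min(dmin, width)
  }
  if (!is.finite(dmin)) dmin <- 0
  c(dmin, dmax)
}

#' Per-object shape measurement of a label map
#'
#' For every labelled object computes the projected area (pixel count times
#' pixel area), perimeter (weighted boundary-step estimator on the traced
#' contour), area-equivalent circle diameter `sqrt(4 * A / pi)`, circularity
#' `4 * pi * A / P^2`, min/max Feret diameters (rotating calipers on the
#' convex hull of the pixel corners) and whether the object touches the
#' raster border.
#'
#' @param labels Integer label matrix from [segment_watershed()].
#' @param pixel_size_um Calibration, um per pixel.
#' @return Data frame with one row per label: `label`, `area_um2`,
#'   `perimeter_um`, `equivalent_diameter_um`, `circularity`, `feret_min_um`,
#'   `feret_max_um`, `feret_ratio`, `touches_edge`, `centroid_x_px`,
#'   `centroid_y_px` (0-based).
#' @export
measure_regions <- function(labels, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  lab <- unclass(labels)
  n <- max(0L, max(lab))
  out <- vector("list", n)
  if (n == 0L) {
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      circularity = numeric(0), feret_min_um = numeric(0),
                      feret_max_um = numeric(0), feret_ratio = numeric(0),
                      touches_edge = logical(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0)))
  }
  H <- nrow(lab); W <- ncol(lab)
  pix <- which(lab > 0L)
  grp <- split(pix, lab[pix])
  for (k in seq_len(n)) {
    id <- grp[[as.character(k)]]
    r <- ((id - 1L) %% H)          # 0-based row
    c <- ((id - 1L) %/% H)         # 0-based col
    npx <- length(id)
    area <- npx * pixel_size_um^2
    M <- matrix(FALSE, diff(range(r)) + 1L, diff(range(c)) + 1L)
    M[cbind(r - min(r) + 1L, c - min(c) + 1L)] <- TRUE
    per <- perimeter_px(M) * pixel_size_um
    fer <- feret_px(r, c) * pixel_size_um
    out[[k]] <- data.frame(
      label = k, area_um2 = area, perimeter_um = per,
      equivalent_diameter_um = sqrt(4 * area / pi),
      circularity = circularity(area, per),
      feret_min_um = fer[1L], feret_max_um = fer[2L],
      feret_ratio = if (fer[2L] > 0) fer[1L] / fer[2L] else NA_real_,
      touches_edge = any(r == 0L | r == H - 1L | c == 0L | c == W - 1L),
      centroid_x_px = mean(c), centroid_y_px = mean(r))
  }
  do.call(rbind, out)
}

#' Circularity of a shape
#'
#' `4 * pi * Area / Perimeter^2`; 1 for an ideal circle, smaller for
#' elongated or rough outlines. Not clipped at 1: the value inherits the
#' bias of whatever perimeter estimator produced the input, which is why the
#' package's perimeter uses bias-corrected boundary-step weights.
#'
#' @param area_um2,perimeter_um Positive area and perimeter.
#' @return Dimensionless circularity.
#' @export
circularity <- function(area_um2, perimeter_um) {
  if (any(area_um2 <= 0) || any(perimeter_um <= 0))
    stop("area and perimeter must be positive")
  4 * pi * area_um2 / perimeter_um^2
}

#' Remove small and border-touching objects
#'
#' Drops objects with projected area below `min_area_um2` (default 200 um^2)
#' and, when `exclude_edge` is `TRUE`, objects with at least one pixel on the
#' raster border. Survivors are relabelled contiguously in both the table
#' and the label map; removal counts are attached as attribute `removed` and
#' reported via `message()`.
#'
#' @param measurements Data frame from [measure_regions()].
#' @param labels Matching label matrix.
#' @param min_area_um2 Area cut-off in um^2.
#' @param exclude_edge Drop border-touching objects.
#' @param quiet Suppress the log message.
#' @return List with `measurements` and `labels`, filtered and relabelled.
#' @export
filter_regions <- function(measurements, labels, min_area_um2 = 200,
                           exclude_edge = TRUE, quiet = FALSE) {
  small <- measurements$area_um2 < min_area_um2
  edge <- if (exclude_edge) measurements$touches_edge else rep(FALSE, nrow(measurements))
  keep <- !small & !edge
  lab <- unclass(labels)
  old <- measurements$label
  remap <- integer(max(c(0L, old)))
  remap[old[keep]] <- seq_len(sum(keep))
  nz <- lab > 0L
  lab[nz] <- ifelse(lab[nz] <= length(remap), remap[lab[nz]], 0L)
  meas <- measurements[keep, , drop = FALSE]
  if (nrow(meas)) meas$label <- seq_len(nrow(meas))
  rownames(meas) <- NULL
  attr(lab, "n_objects") <- nrow(meas)
  removed <- c(small = sum(small), edge = sum(edge & !small))
  attr(meas, "removed") <- removed
  if (!quiet)
    message(sprintf("filter_regions: removed %d small (< %g um^2) and %d edge objects, kept %d",
                    removed[["small"]], min_area_um2, removed[["edge"]], nrow(meas)))
  list(measurements = meas, labels = lab)
}

#' Number- and volume-weighted size density distributions
#'
#' Histograms the equivalent diameters into bins of width `bin_width_um`
#' starting at 0 and returns the number-density distribution q0 (counts per
#' bin over n times bin width) and the volume-density distribution q3
#' (d^3-weighted, spherical volume weighting), both normalized to unit
#' integral.
#'
#' @param diameters_um Positive diameters, non-empty.
#' @param bin_width_um Bin width in um (default 20).
#' @return List of class `size_distribution`: `bin_edges_um`,
#'   `bin_centers_um`, `q0`, `q3` (densities, 1/um), `n_objects`.
#' @export
size_distributions <- function(diameters_um, bin_width_um = 20) {
  d <- diameters_um
  if (length(d) == 0) stop("no diameters supplied")
  stopifnot(all(d > 0), bin_width_um > 0)
  edges <- seq(0, (max(d) %/% bin_width_um + 1) * bin_width_um, by = bin_width_um)
  bin <- findInterval(d, edges, rightmost.closed = FALSE, left.open = TRUE)
  bin[bin == 0L] <- 1L
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  w3 <- tapply(d^3, factor(bin, levels = seq_len(length(edges) - 1L)), sum)
  w3[is.na(w3)] <- 0
  structure(list(bin_edges_um = edges,
                 bin_centers_um = (edges[-1L] + edges[-length(edges)]) / 2,
                 q0 = counts / (sum(counts) * bin_width_um),
                 q3 = as.numeric(w3) / (sum(d^3) * bin_width_um),
                 n_objects = length(d)),
            class = "size_distribution")
}

#' One-call segmentation and measurement of a brightfield image
#'
#' Convenience pipeline: [binarize_local_mean()] then [segment_watershed()]
#' then [measure_regions()] then [filter_regions()].
#'
#' @param image A [pellet_image()].
#' @param window_px,sensitivity Passed to [binarize_local_mean()].
#' @param h_min,opening_px Passed to [segment_watershed()].
#' @param min_area_um2,exclude_edge Passed to [filter_regions()].
#' @return The filtered `list(measurements, labels)`.
#' @export
analyze_pellet_image <- function(image, window_px = 65L, sensitivity = 0.1,
                                 h_min = 2, opening_px = 3L,
                                 min_area_um2 = 200, exclude_edge = TRUE) {
  mask <- binarize_local_mean(image, window_px, sensitivity)
  lab <- segment_watershed(mask, h_min, opening_px = opening_px)
  meas <- measure_regions(lab, pixel_size(image))
  filter_regions(meas, lab, min_area_um2, exclude_edge, quiet = TRUE)
}
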