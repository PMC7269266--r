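#' Parameters for the synthetic brightfield pellet-image generator
#'
#' Defaults emulate the cultivation micrographs the pipeline was designed
#' for: a 9.2 x 6.9 mm field imaged at 4.5 um per pixel, dark roughly
#' elliptical pellet cores with a fuzzy hyphal corona on a bright background,
#' and a log-normal pellet diameter distribution whose mean (172 um) and
#' spread (sd 61 um) match an unsupplemented shake-flask culture of
#' *Lentzea aerocolonigenes*.
#'
#' @param image_width_px,image_height_px Raster dimensions in pixels.
#' @param pixel_size_um Pixel edge length in um (default 4.5).
#' @param n_pellets Number of pellet cores to place.
#' @param diameter_lognormal_mu,diameter_lognormal_sigma Log-space mean and
#'   sd of the pellet core diameter in um. Defaults reproduce an arithmetic
#'   mean of 172 um with sd 61 um.
#' @param corona_fraction Width of the fuzzy hyphal halo as a fraction of the
#'   core radius, in \[0, 1\].
#' @param eccentricity_max Upper bound of the per-pellet ellipse
#'   eccentricity, in \[0, 1).
#' @param background_level,foreground_level Background and core intensities
#'   (images are generated in \[0, 1\]).
#' @param noise_sd Additive Gaussian pixel noise sd.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A validated parameter list of class `image_gen_params`.
#' @export
image_gen_params <- function(image_width_px = 2044L, image_height_px = 1533L,
                             pixel_size_um = 4.5, n_pellets = 30L,
                             diameter_lognormal_mu = 5.088,
                             diameter_lognormal_sigma = 0.344,
                             corona_fraction = 0.35, eccentricity_max = 0.6,
                             background_level = 0.85, foreground_level = 0.2,
                             noise_sd = 0.02, seed = 1L) {
  p <- list(image_width_px = as.integer(image_width_px),
            image_height_px = as.integer(image_height_px),
            pixel_size_um = pixel_size_um, n_pellets = as.integer(n_pellets),
            diameter_lognormal_mu = diameter_lognormal_mu,
            diameter_lognormal_sigma = diameter_lognormal_sigma,
            corona_fraction = corona_fraction,
            eccentricity_max = eccentricity_max,
            background_level = background_level,
            foreground_level = foreground_level,
            noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(p$image_width_px >= 8L, p$image_height_px >= 8L,
            p$pixel_size_um > 0, p$n_pellets >= 0L,
            p$corona_fraction >= 0, p$corona_fraction <= 1,
            p$eccentricity_max >= 0, p$eccentricity_max < 1,
            p$noise_sd >= 0)
  class(p) <- "image_gen_params"
  p
}

# Normalised elliptical radius of pixel-centre grid points for an ellipse at
# (cx, cy) with semi-axes a, b (px) rotated by theta.
ellipse_rho <- function(xs, ys, cx, cy, a, b, theta) {
  X <- outer(rep(1, length(ys)), xs) - cx
  Y <- outer(ys, rep(1, length(xs))) - cy
  u <- (X * cos(theta) + Y * sin(theta)) / a
  v <- (-X * sin(theta) + Y * cos(theta)) / b
  sqrt(u * u + v * v)
}

# Sub-pixel area coverage of an ellipse over a pixel grid, by s x s
# supersampling of boundary pixels only. Returns a list with the coverage
# matrix (rows = y of `ys`, cols = x of `xs`).
ellipse_coverage <- function(xs, ys, cx, cy, a, b, theta, s = 8L) {
  rho <- ellipse_rho(xs, ys, cx, cy, a, b, theta)
  slack <- 1.5 / min(a, b)
  cov <- matrix(0, length(ys), length(xs))
  cov[rho <= 1 - slack] <- 1
  bnd <- which(rho > 1 - slack & rho < 1 + slack, arr.ind = TRUE)
  if (nrow(bnd) > 0) {
    off <- (seq_len(s) - 0.5) / s - 0.5
    sub <- expand.grid(dx = off, dy = off)
    for (i in seq_len(nrow(bnd))) {
      px <- xs[bnd[i, 2L]]; py <- ys[bnd[i, 1L]]
      u <- ((px + sub$dx - cx) * cos(theta) + (py + sub$dy - cy) * sin(theta)) / a
      v <- (-(px + sub$dx - cx) * sin(theta) + (py + sub$dy - cy) * cos(theta)) / b
      cov[bnd[i, 1L], bnd[i, 2L]] <- mean(u * u + v * v <= 1)
    }
  }
  cov
}

#' Generate a synthetic brightfield pellet image with ground truth
#'
#' Renders dark elliptical pellet cores with a speckled, radially decaying
#' hyphal corona on a bright background and returns an exact per-object truth
#' table. Core placement uses rejection sampling so that cores never overlap
#' (minimum centre distance = sum of semi-major axes + 2 px) and every core,
#' corona included, lies fully inside the frame. The *core* ellipse is the
#' object the ground truth describes; the corona is texture, not object, a
#' convention the downstream segmentation is expected to respect.
#'
#' The rendered core mask is area-matched to the analytic ellipse: pixels are
#' ranked by sub-pixel coverage and the top `round(sum(coverage))` form the
#' mask, so counting mask pixels reproduces the tabulated area to better than
#' one pixel area.
#'
#' @param params An [image_gen_params()] list.
#' @return A list with `image` (a [pellet_image()]) and `truth`, a data frame
#'   with one row per object: `id`, `center_x_px`, `center_y_px` (0-based),
#'   `true_area_um2`, `true_equivalent_diameter_um`, `true_circularity`,
#'   `true_feret_min_um`, `true_feret_max_um`, `touches_edge`.
#' @export
generate_pellet_image <- function(params) {
  stopifnot(inherits(params, "image_gen_params"))
  p <- params
  W <- p$image_width_px; H <- p$image_height_px; ps <- p$pixel_size_um
  local_seed(p$seed, {
    img <- matrix(p$background_level, H, W)
    n <- p$n_pellets
    truth <- data.frame(id = integer(0), center_x_px = numeric(0),
                        center_y_px = numeric(0), true_area_um2 = numeric(0),
                        true_equivalent_diameter_um = numeric(0),
                        true_circularity = numeric(0),
                        true_feret_min_um = numeric(0),
                        true_feret_max_um = numeric(0),
                        touches_edge = logical(0))
    if (n > 0L) {
      d_um <- stats::rlnorm(n, p$diameter_lognormal_mu, p$diameter_lognormal_sigma)
      ecc <- stats::runif(n, 0, p$eccentricity_max)
      theta <- stats::runif(n, 0, pi)
      ax <- (1 - ecc^2)^(-1/4)               # area-preserving axis stretch
      a_um <- (d_um / 2) * ax; b_um <- (d_um / 2) / ax
      a_px <- a_um / ps; b_px <- b_um / ps
      ord <- order(a_px, decreasing = TRUE)  # place big pellets first
      cx <- cy <- rep(NA_real_, n)
      for (i in ord) {
        marg <- a_px[i] * (1 + p$corona_fraction) + 3
        if (2 * marg >= W || 2 * marg >= H)
          stop(sprintf("cannot place %d pellets in a %d x %d px image: object larger than frame",
                       n, W, H))
        rejections <- 0L
        repeat {
          x0 <- stats::runif(1, marg, W - 1 - marg)
          y0 <- stats::runif(1, marg, H - 1 - marg)
          placed <- which(!is.na(cx))
          ok <- !length(placed) ||
            all(sqrt((cx[placed] - x0)^2 + (cy[placed] - y0)^2) >
                  a_px[placed] + a_px[i] + 2)
          if (ok) { cx[i] <- x0; cy[i] <- y0; break }
          rejections <- rejections + 1L
          if (rejections >= 1000L)
            stop(sprintf("cannot place %d pellets in a %d x %d px image: 1000 consecutive placement rejections",
                         n, W, H))
        }
      }
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        rext <- a_px[i] * (1 + p$corona_fraction) + 2
        xs <- max(0, floor(cx[i] - rext)):min(W - 1, ceiling(cx[i] + rext))
        ys <- max(0, floor(cy[i] - rext)):min(H - 1, ceiling(cy[i] + rext))
        cov <- ellipse_coverage(xs, ys, cx[i], cy[i], a_px[i], b_px[i], theta[i])
        k <- round(sum(cov))
        sel <- order(cov, decreasing = TRUE)[seq_len(k)]
        core <- matrix(FALSE, length(ys), length(xs)); core[sel] <- TRUE
        rho <- ellipse_rho(xs, ys, cx[i], cy[i], a_px[i], b_px[i], theta[i])
        halo <- !core & rho > 1 & rho <= 1 + p$corona_fraction
        sub <- img[ys + 1L, xs + 1L, drop = FALSE]
        if (any(halo)) {
          fall <- (1 - (rho[halo] - 1) / p$corona_fraction)^2
          speck <- stats::runif(sum(halo))
          sub[halo] <- sub[halo] *
            (1 - 0.45 * (1 - p$foreground_level / p$background_level) * fall * speck)
        }
        sub[core] <- p$foreground_level
        img[ys + 1L, xs + 1L] <- sub
        area_um2 <- sum(cov) * ps^2
        m <- 1 - (b_um[i] / a_um[i])^2
        perim_um <- 4 * a_um[i] * pracma::ellipke(m)$e
        edge <- any(core & (outer(ys, rep(1, length(xs))) %in% c(0, H - 1) |
                              outer(rep(1, length(ys)), xs) %in% c(0, W - 1)))
        rows[[i]] <- data.frame(
          id = i, center_x_px = cx[i], center_y_px = cy[i],
          true_area_um2 = area_um2,
          true_equivalent_diameter_um = sqrt(4 * area_um2 / pi),
          true_circularity = 4 * pi * (pi * a_um[i] * b_um[i]) / perim_um^2,
          true_feret_min_um = 2 * b_um[i], true_feret_max_um = 2 * a_um[i],
          touches_edge = edge)
      }
      truth <- do.call(rbind, rows)
    }
    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, p$noise_sd), H, W)
    img <- pmin(pmax(img, 0), 1)
    list(image = pellet_image(img, ps), truth = truth)
  })
}

#' Generate a co-registered green/red stained-slice image pair
#'
#' Emulates a confocal image of an equatorial slice through a pellet with a
#' dead core: green (all-cell / viable) fluorescence covers the whole disk
#' except the solely-dead core, red (membrane-compromised) fluorescence
#' covers the core plus an annular overlap band where both stains report.
#' Ground-truth area shares come from the concentric geometry analytically.
#'
#' @param outer_diameter_um Slice (disk) diameter.
#' @param dead_core_diameter_um Diameter of the solely-red core.
#' @param overlap_band_um Width of the annulus stained by both channels.
#' @param pixel_size_um Calibration of the rendered rasters.
#' @param noise_sd Additive Gaussian noise sd (intensity units, images in
#'   \[0, 1\]).
#' @param seed Integer seed.
#' @return List with `green` and `red` ([pellet_image()]s) and `truth`, a
#'   [viability_shares()] record of the analytic live/dead/overlap shares.
#' @export
generate_clsm_pair <- function(outer_diameter_um, dead_core_diameter_um = 0,
                               overlap_band_um = 0, pixel_size_um = 2,
                               noise_sd = 0, seed = 1L) {
  stopifnot(outer_diameter_um > 0, dead_core_diameter_um >= 0,
            overlap_band_um >= 0, pixel_size_um > 0, noise_sd >= 0)
  if (dead_core_diameter_um + 2 * overlap_band_um > outer_diameter_um + 1e-9)
    stop("non-physical slice geometry: dead core plus overlap band exceeds the outer diameter")
  R <- outer_diameter_um / 2
  r_core <- dead_core_diameter_um / 2
  r_ov <- r_core + overlap_band_um
  side <- 2L * ceiling(R / pixel_size_um * 1.15) + 9L
  c0 <- (side - 1) / 2
  xs <- 0:(side - 1)
  rho_px <- sqrt((outer(rep(1, side), xs) - c0)^2 + (outer(xs, rep(1, side)) - c0)^2)
  rho_um <- rho_px * pixel_size_um
  green <- matrix(0.05, side, side); red <- matrix(0.05, side, side)
  green[rho_um <= R & rho_um > r_core] <- 0.8
  red[rho_um <= r_ov] <- 0.8
  local_seed(seed, {
    if (noise_sd > 0) {
      green <- green + matrix(stats::rnorm(side^2, 0, noise_sd), side, side)
      red <- red + matrix(stats::rnorm(side^2, 0, noise_sd), side, side)
    }
    green <- pmin(pmax(green, 0), 1); red <- pmin(pmax(red, 0), 1)
    total <- pi * R^2
    dead <- pi * r_core^2
    overlap <- pi * (r_ov^2 - r_core^2)
    live <- total - dead - overlap
    truth <- viability_shares(live_share = live / total, dead_share = dead / total,
                              overlap_share = overlap / total,
                              total_area_um2 = total)
    list(green = pellet_image(green, pixel_size_um),
         red = pellet_image(red, pixel_size_um), truth = truth)
  })
}
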