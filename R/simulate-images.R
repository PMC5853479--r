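# Synthetic dual-excitation ratio image pairs: ring-shaped membrane
# fluorescence whose 438/531 nm excitation ratio maps linearly onto an
# assigned membrane potential.

#' Specification for a synthetic ratio image pair
#'
#' Each protoplast contributes a ring (membrane) of fluorescence to both
#' excitation channels. The 531 nm channel carries a fixed membrane
#' amplitude; the 438 nm channel carries `ratio * amplitude` where the true
#' ratio follows the linear map `ratio = intercept + slope * potential`.
#' The slope is positive so a more negative (hyperpolarized) potential gives
#' a smaller ratio, matching the behaviour of dual-excitation potentiometric
#' dyes with the 438 nm excitation in the numerator. Uniform background and
#' Gaussian noise are added per channel.
#'
#' @param width,height Image size, px.
#' @param centers n x 2 matrix of protoplast centres (columns x, y), px.
#' @param radii Protoplast radii, px.
#' @param potentials_mV Assigned membrane potentials, mV.
#' @param group Optional group labels (e.g. "BSC"/"MC"), recorded in the
#'   truth table.
#' @param ratio_intercept,ratio_slope Linear ratio-potential map
#'   (slope must be > 0, per mV).
#' @param ring_px Ring (membrane) thickness, px.
#' @param amp_531 Membrane amplitude in the 531 nm channel, counts.
#' @param background Uniform background level per channel, counts.
#' @param noise_sd Gaussian noise SD per channel, counts.
#' @return An object of class `ratio_image_spec`. Overlapping protoplasts
#'   (centre distance <= r_i + r_j + ring_px) are rejected.
#' @export
ratio_image_spec <- function(width = 360, height = 360,
                             centers, radii, potentials_mV,
                             group = NULL,
                             ratio_intercept = 1.0, ratio_slope = 0.005,
                             ring_px = 4, amp_531 = 20000,
                             background = 500, noise_sd = 50) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  stopifnot(length(radii) == n, length(potentials_mV) == n)
  if (ratio_slope <= 0) {
    stop("ratio_slope must be positive (hyperpolarization -> smaller ratio)")
  }
  if (any(radii <= 0)) stop("radii must be positive")
  if (n > 1) {
    d <- as.matrix(stats::dist(centers))
    lim <- outer(radii, radii, "+") + ring_px
    diag(d) <- Inf
    if (any(d <= lim)) stop("protoplasts overlap")
  }
  if (is.null(group)) group <- rep(NA_character_, n)
  structure(list(width = width, height = height, centers = centers,
                 radii = radii, potentials_mV = potentials_mV,
                 group = as.character(group),
                 ratio_intercept = ratio_intercept,
                 ratio_slope = ratio_slope, ring_px = ring_px,
                 amp_531 = amp_531, background = background,
                 noise_sd = noise_sd),
            class = "ratio_image_spec")
}

#' Default two-population ratio image specification
#'
#' A field of `n_per_group` BSC-like and `n_per_group` MC-like protoplasts on
#' a jittered grid. BSC-like cells are assigned more negative membrane
#' potentials (default mean -130 mV) than MC-like cells (default -90 mV),
#' with Gaussian cell-to-cell jitter; radii reflect the smaller BSC
#' protoplasts. Setting both means equal emulates a depolarizing
#' (vanadate-style) control in which the group difference is abolished.
#'
#' @param seed RNG seed for placement and potential jitter.
#' @param n_per_group Protoplasts per population.
#' @param potential_bsc,potential_mc Mean assigned potentials, mV.
#' @param potential_sd Cell-to-cell SD of assigned potentials, mV.
#' @param ... Passed on to [ratio_image_spec()].
#' @return A `ratio_image_spec`.
#' @export
default_ratio_image_spec <- function(seed, n_per_group = 4,
                                     potential_bsc = -130,
                                     potential_mc = -90,
                                     potential_sd = 5, ...) {
  .with_seed(seed, {
    n <- 2L * n_per_group
    ncol_grid <- ceiling(sqrt(n))
    nrow_grid <- ceiling(n / ncol_grid)
    pitch <- 85
    idx <- seq_len(n) - 1L
    gx <- 55 + (idx %% ncol_grid) * pitch + stats::runif(n, -8, 8)
    gy <- 55 + (idx %/% ncol_grid) * pitch + stats::runif(n, -8, 8)
    grp <- rep(c("BSC", "MC"), each = n_per_group)[sample.int(n)]
    radii <- ifelse(grp == "BSC", 14, 20)
    pot <- ifelse(grp == "BSC", potential_bsc, potential_mc) +
      stats::rnorm(n, 0, potential_sd)
    ratio_image_spec(width = 55 + ncol_grid * pitch,
                     height = 55 + nrow_grid * pitch,
                     centers = cbind(gx, gy), radii = radii,
                     potentials_mV = pot, group = grp, ...)
  })
}

#' Simulate a registered dual-excitation image pair
#'
#' @param spec A `ratio_image_spec`.
#' @param seed RNG seed (required).
#' @return An object of class `ratio_image_pair`: list with `ch438` and
#'   `ch531` (height x width integer matrices, 16-bit range 0..65535) and
#'   `truth` (data.frame `id`, `x`, `y`, `radius`, `potential_mV`,
#'   `true_ratio`, `group`).
#' @export
simulate_ratio_images <- function(spec, seed) {
  stopifnot(inherits(spec, "ratio_image_spec"))
  if (missing(seed)) stop("a seed must be supplied")
  .with_seed(seed, {
    h <- spec$height; w <- spec$width
    ch438 <- matrix(0, h, w)
    ch531 <- matrix(0, h, w)
    true_ratio <- spec$ratio_intercept +
      spec$ratio_slope * spec$potentials_mV
    if (any(true_ratio <= 0)) {
      stop("assigned potentials map to non-positive ratios")
    }
    for (k in seq_len(nrow(spec$centers))) {
      cx <- spec$centers[k, 1]; cy <- spec$centers[k, 2]
      r <- spec$radii[k]
      half <- spec$ring_px / 2
      rows <- max(1, floor(cy - r - half)):min(h, ceiling(cy + r + half))
      cols <- max(1, floor(cx - r - half)):min(w, ceiling(cx + r + half))
      dd <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
      ring <- abs(dd - r) <= half
      ch531[rows, cols][ring] <- ch531[rows, cols][ring] + spec$amp_531
      ch438[rows, cols][ring] <- ch438[rows, cols][ring] +
        true_ratio[k] * spec$amp_531
    }
    add_bg <- function(m) {
      m <- m + spec$background
      if (spec$noise_sd > 0) {
        m <- m + matrix(stats::rnorm(length(m), 0, spec$noise_sd), nrow(m))
      }
      matrix(as.integer(pmin(pmax(round(m), 0), 65535)), nrow(m))
    }
    structure(list(ch438 = add_bg(ch438), ch531 = add_bg(ch531),
                   truth = data.frame(id = seq_len(nrow(spec$centers)),
                                      x = spec$centers[, 1],
                                      y = spec$centers[, 2],
                                      radius = spec$radii,
                                      potential_mV = spec$potentials_mV,
                                      true_ratio = true_ratio,
                                      group = spec$group)),
              class = "ratio_image_pair")
  })
}

#' Write / read a ratio image pair as 16-bit TIFFs
#'
#' Writes `<prefix>_438.tif`, `<prefix>_531.tif` and a plain-text truth
#' table `<prefix>_truth.tsv` when ground truth is present.
#'
#' @param pair A `ratio_image_pair`.
#' @param dir Directory (created if needed).
#' @param prefix File-name prefix.
#' @return `read_ratio_images` returns a `ratio_image_pair` (truth included
#'   when the truth table file exists).
#' @export
write_ratio_images <- function(pair, dir, prefix = "field") {
  stopifnot(inherits(pair, "ratio_image_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in c("438", "531")) {
    tiff::writeTIFF(pair[[paste0("ch", ch)]] / 65535,
                    file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                    bits.per.sample = 16L)
  }
  if (!is.null(pair$truth)) {
    utils::write.table(pair$truth,
                       file.path(dir, paste0(prefix, "_truth.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ratio_images
#' @export
read_ratio_images <- function(dir, prefix = "field") {
  rd <- function(ch) {
    m <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", prefix, ch)))
    matrix(as.integer(round(m * 65535)), nrow(m))
  }
  tf <- file.path(dir, paste0(prefix, "_truth.tsv"))
  truth <- if (file.exists(tf)) {
    utils::read.table(tf, sep = "\t", header = TRUE)
  } else NULL
  structure(list(ch438 = rd("438"), ch531 = rd("531"), truth = truth),
            class = "ratio_image_pair")
}
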