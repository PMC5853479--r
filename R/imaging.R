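# Ratiometric membrane-potential image analysis: ring segmentation,
# background-subtracted excitation ratios, group comparison.

#' Segment protoplast membrane rings in a fluorescence image
#'
#' Global automatic (Otsu) threshold, connected-component labelling
#' (via \pkg{EBImage}), then a circle fit per component: the centre is the
#' component centroid and the rim radius the mean distance of component
#' pixels from it. Each ROI carries an annulus mask of configurable
#' thickness centred on the fitted rim. Components whose annulus would leave
#' the image are flagged edge-truncated; tiny specks are dropped. The
#' background region is the lowest-intensity quantile of the pixels outside
#' all components.
#'
#' @param img Numeric/integer matrix, one channel (conventionally the 531 nm
#'   excitation image), 16-bit scale.
#' @param ring_px Annulus thickness, px (default 3).
#' @param min_px Minimum component size in pixels (smaller components are
#'   ignored).
#' @param bg_quantile Fraction of the dimmest outside pixels used as the
#'   background region.
#' @return An object of class `protoplast_segmentation`: list with `rois`
#'   (list of `protoplast_roi`, each with `id`, `center` (x, y), `radius`,
#'   `annulus_idx` (linear indices), `n_px`, `edge_truncated`) and
#'   `background_idx` (linear indices of the background region). An empty
#'   ROI list (with a warning) is returned when nothing is found.
#' @export
segment_protoplasts <- function(img, ring_px = 3, min_px = 30,
                                bg_quantile = 0.2) {
  stopifnot(is.matrix(img))
  img <- matrix(as.numeric(img), nrow(img))
  empty <- function() {
    warning("no protoplasts found")
    structure(list(rois = list(), background_idx = seq_along(img)),
              class = "protoplast_segmentation")
  }
  rng <- range(img)
  if (diff(rng) < 1e-9) return(empty())
  norm <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  n_comp <- max(lab)
  if (n_comp == 0) return(empty())
  h <- nrow(img); w <- ncol(img)
  row_of <- row(img); col_of <- col(img)
  half <- ring_px / 2
  rois <- list()
  for (k in seq_len(n_comp)) {
    idx <- which(lab == k)
    if (length(idx) < min_px) next
    cy <- mean(row_of[idx]); cx <- mean(col_of[idx])
    r <- mean(sqrt((row_of[idx] - cy)^2 + (col_of[idx] - cx)^2))
    rows <- max(1, floor(cy - r - half)):min(h, ceiling(cy + r + half))
    cols <- max(1, floor(cx - r - half)):min(w, ceiling(cx + r + half))
    dd <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
    sub_idx <- outer(rows, (cols - 1) * h, "+")
    ann <- sub_idx[abs(dd - r) <= half]
    edge <- (cy - r - half) < 1 || (cy + r + half) > h ||
            (cx - r - half) < 1 || (cx + r + half) > w
    rois[[length(rois) + 1]] <- structure(
      list(id = length(rois) + 1L, center = c(x = cx, y = cy), radius = r,
           annulus_idx = as.integer(ann), n_px = length(idx),
           edge_truncated = edge),
      class = "protoplast_roi")
  }
  if (length(rois) == 0) return(empty())
  outside <- which(lab == 0)
  cut <- stats::quantile(img[outside], bg_quantile)
  structure(list(rois = rois,
                 background_idx = outside[img[outside] <= cut]),
            class = "protoplast_segmentation")
}

#' Background-subtracted excitation ratio for one ROI
#'
#' Ratio of ROI-mean background-subtracted intensities,
#' `mean(I438 - bg438) / mean(I531 - bg531)` over the membrane annulus
#' (means of background-subtracted intensities, not a mean of per-pixel
#' ratios, which is noisier). Saturated pixels (either channel at or above
#' `saturation`) are excluded; the result is marked invalid when the
#' denominator (or numerator) mean is non-positive or no usable pixels
#' remain.
#'
#' @param roi A `protoplast_roi`.
#' @param img438,img531 Registered channel matrices (16-bit scale).
#' @param background_idx Linear indices of the background region (from
#'   [segment_protoplasts()]).
#' @param saturation Saturation level (default 65535).
#' @return A one-row data.frame: `id`, `x`, `y`, `radius`, `i438`, `i531`
#'   (background-subtracted annulus means), `ratio`, `n_saturated`, `valid`.
#' @export
compute_ratio <- function(roi, img438, img531, background_idx,
                          saturation = 65535) {
  stopifnot(inherits(roi, "protoplast_roi"),
            all(dim(img438) == dim(img531)))
  bg438 <- mean(img438[background_idx])
  bg531 <- mean(img531[background_idx])
  ann <- roi$annulus_idx
  sat <- img438[ann] >= saturation | img531[ann] >= saturation
  use <- ann[!sat]
  i438 <- if (length(use)) mean(img438[use]) - bg438 else NA_real_
  i531 <- if (length(use)) mean(img531[use]) - bg531 else NA_real_
  valid <- length(use) > 0 && is.finite(i531) && i531 > 0 &&
    is.finite(i438) && i438 > 0
  data.frame(id = roi$id, x = roi$center[["x"]], y = roi$center[["y"]],
             radius = roi$radius, i438 = i438, i531 = i531,
             ratio = if (valid) i438 / i531 else NA_real_,
             n_saturated = sum(sat), valid = valid)
}

#' Per-protoplast ratios for a registered image pair
#'
#' Segments the 531 nm image, drops edge-truncated ROIs (by default) and
#' computes the background-subtracted excitation ratio for each remaining
#' protoplast.
#'
#' @param img438,img531 Registered channel matrices, or a
#'   `ratio_image_pair`.
#' @param drop_edge Exclude edge-truncated ROIs (default TRUE).
#' @param ... Passed to [segment_protoplasts()].
#' @inheritParams compute_ratio
#' @return A data.frame, one row per ROI (see [compute_ratio()]), with an
#'   added `edge_truncated` column when `drop_edge = FALSE`.
#' @export
analyze_ratio_images <- function(img438, img531 = NULL, drop_edge = TRUE,
                                 saturation = 65535, ...) {
  if (inherits(img438, "ratio_image_pair")) {
    img531 <- img438$ch531
    img438 <- img438$ch438
  }
  seg <- segment_protoplasts(img531, ...)
  rois <- seg$rois
  if (drop_edge) rois <- Filter(function(r) !r$edge_truncated, rois)
  if (length(rois) == 0) {
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      radius = numeric(), i438 = numeric(), i531 = numeric(),
                      ratio = numeric(), n_saturated = integer(),
                      valid = logical()))
  }
  out <- do.call(rbind, lapply(rois, compute_ratio, img438 = img438,
                               img531 = img531,
                               background_idx = seg$background_idx,
                               saturation = saturation))
  if (!drop_edge) {
    out$edge_truncated <- vapply(rois, `[[`, logical(1), "edge_truncated")
  }
  out
}

#' Compare excitation ratios between cell-type groups
#'
#' Group means with standard errors and a two-sided Welch t-test, plus an
#' explicit ordering statement (which group has the smaller mean ratio,
#' i.e. the more hyperpolarized population).
#'
#' @param ratios Numeric vector of per-protoplast ratios (NAs dropped).
#' @param group Group labels, one per ratio (exactly two groups, >= 2 valid
#'   ratios each).
#' @return An object of class `ratio_comparison`: list with `summary`
#'   (per-group mean, SE, n), `p_value`, `smaller_group`, and `ordering`
#'   (text statement).
#' @export
compare_ratio_groups <- function(ratios, group) {
  stopifnot(length(ratios) == length(group))
  ok <- is.finite(ratios)
  ratios <- ratios[ok]; group <- factor(as.character(group[ok]))
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) < 2)) stop("need >= 2 valid ratios per group")
  sm <- do.call(rbind, lapply(levels(group), function(g) {
    x <- ratios[group == g]
    data.frame(group = g, mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
               n = length(x))
  }))
  pv <- tryCatch(stats::t.test(ratios ~ group)$p.value,
                 error = function(e) NA_real_)
  smaller <- sm$group[which.min(sm$mean)]
  structure(list(summary = sm, p_value = pv, smaller_group = smaller,
                 ordering = sprintf("mean ratio smaller in %s (%.3f vs %.3f)",
                                    smaller, min(sm$mean), max(sm$mean))),
            class = "ratio_comparison")
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat("<ratio_comparison>", x$ordering,
      sprintf(" P = %.3g\n", x$p_value))
  invisible(x)
}
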