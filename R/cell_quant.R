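#' Detect labeled cells in one fluorescence channel
#'
#' Transparent, parameter-light blob detection: the channel is thresholded
#' at `background median + threshold_k x MAD`, connected components are
#' labeled (8-connectivity), and components smaller than `min_area` pixels
#' are discarded. On noise-free images the MAD is zero; the threshold then
#' falls back to `median + 0.01 x (max - median)`, which cleanly separates
#' rendered objects from a constant background. A blank image yields an
#' empty detection list with a warning. Classification downstream is
#' invariant to rescaling the channel by a positive constant because the
#' threshold is median/MAD-relative.
#'
#' @param channel 2-D numeric matrix (one channel, arbitrary units).
#' @param min_area Minimum component area in pixels.
#' @param threshold_k MAD multiplier (> 0), default 6.
#' @param pixel_size Micrometers per pixel (for centroids and areas in
#'   physical units).
#' @param origin `c(x0, y0)` of the frame in micrometers.
#' @return Data frame of detections: `label`, `x`, `y` (intensity-weighted
#'   centroid, micrometers), `area_px`, `area_um2`, `mean_intensity`; the
#'   label matrix is attached as attribute `"labels"` for mask-overlap
#'   classification.
#' @export
detect_blobs <- function(channel, min_area = 4, threshold_k = 6,
                         pixel_size = 1, origin = c(0, 0)) {
  stopifnot(threshold_k > 0, is.matrix(channel))
  med <- stats::median(channel)
  madv <- stats::mad(channel)
  rng <- max(channel) - med
  empty <- function(msg) {
    warning(msg)
    out <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0))
    attr(out, "labels") <- matrix(0L, nrow(channel), ncol(channel))
    out
  }
  if (rng <= 0) return(empty("blank or saturated channel: no detections"))
  thr <- if (madv > 0) med + threshold_k * madv else med + 0.01 * rng
  mask <- channel > thr
  if (!any(mask)) return(empty("no pixels above threshold: no detections"))
  lab <- EBImage::bwlabel(mask)
  labv <- as.integer(lab)
  keep <- which(tabulate(labv) >= min_area)
  if (!length(keep)) return(empty("all components below min_area: no detections"))
  sel <- labv %in% keep
  idx <- which(sel)
  lv <- labv[idx]
  inten <- channel[idx]
  rr <- ((idx - 1) %% nrow(channel)) + 1
  cc <- ((idx - 1) %/% nrow(channel)) + 1
  wsum <- tapply(inten, lv, sum)
  cx <- tapply(inten * cc, lv, sum) / wsum
  cy <- tapply(inten * rr, lv, sum) / wsum
  area <- tapply(inten, lv, length)
  out <- data.frame(label = as.integer(names(wsum)),
                    x = px_to_um(as.numeric(cx), origin[1], pixel_size),
                    y = px_to_um(as.numeric(cy), origin[2], pixel_size),
                    area_px = as.integer(area),
                    area_um2 = as.numeric(area) * pixel_size^2,
                    mean_intensity = as.numeric(wsum / area))
  # zero out dropped components in the label matrix
  lab_clean <- matrix(0L, nrow(channel), ncol(channel))
  lab_clean[idx] <- lv
  attr(out, "labels") <- lab_clean
  rownames(out) <- NULL
  out
}

#' Classify detections into starter / input / helper-only cells
#'
#' Operationalizes double-label identification: a DsRed detection whose
#' mask overlaps some GFP detection by at least `overlap_min` (as a
#' fraction of the smaller mask, default 0.5) is a starter (helper AAV +
#' rabies); remaining DsRed detections are presynaptic inputs (rabies
#' only); GFP detections not claimed by a starter are helper-only cells,
#' counted for QC but excluded from both the starter count S and the input
#' counts N.
#'
#' @param gfp_det,dsred_det Detection tables from [detect_blobs()] on the
#'   two registered channels of the same section.
#' @param overlap_min Minimum overlap fraction of the smaller mask.
#' @return Data frame with `class` (`"starter"`, `"input"`,
#'   `"helper_only"`), centroid `x`, `y` (micrometers; DsRed centroid for
#'   starters/inputs, GFP centroid for helper-only cells), and the
#'   per-channel mean intensities where defined.
#' @export
classify_cells <- function(gfp_det, dsred_det, overlap_min = 0.5) {
  gl <- attr(gfp_det, "labels"); rl <- attr(dsred_det, "labels")
  stopifnot(!is.null(gl), !is.null(rl), all(dim(gl) == dim(rl)))
  both <- gl > 0 & rl > 0
  starter_red <- integer(0); matched_gfp <- integer(0)
  if (any(both)) {
    ov <- table(red = rl[both], gfp = gl[both])
    red_ids <- as.integer(rownames(ov)); gfp_ids <- as.integer(colnames(ov))
    red_area <- stats::setNames(dsred_det$area_px, dsred_det$label)
    gfp_area <- stats::setNames(gfp_det$area_px, gfp_det$label)
    for (i in seq_along(red_ids)) {
      frac <- ov[i, ] / pmin(red_area[as.character(red_ids[i])],
                             gfp_area[as.character(gfp_ids)])
      j <- which.max(frac)
      if (frac[j] >= overlap_min) {
        starter_red <- c(starter_red, red_ids[i])
        matched_gfp <- c(matched_gfp, gfp_ids[j])
      }
    }
  }
  is_starter <- dsred_det$label %in% starter_red
  red_rows <- data.frame(class = ifelse(is_starter, "starter", "input"),
                         x = dsred_det$x, y = dsred_det$y,
                         gfp = rep(NA_real_, nrow(dsred_det)),
                         dsred = dsred_det$mean_intensity,
                         stringsAsFactors = FALSE)
  helper <- !(gfp_det$label %in% matched_gfp)
  helper_rows <- data.frame(class = rep("helper_only", sum(helper)),
                            x = gfp_det$x[helper], y = gfp_det$y[helper],
                            gfp = gfp_det$mean_intensity[helper],
                            dsred = rep(NA_real_, sum(helper)),
                            stringsAsFactors = FALSE)
  out <- rbind(red_rows, helper_rows)
  rownames(out) <- NULL
  out
}

#' Restrict starter cells to the ipsilateral CA1 pyramidal layer
#'
#' Starters found outside CA1_Py on the injection side are reclassified to
#' `"starter_flagged"` (kept for QC, excluded from the starter count S). If
#' no valid starter remains the connectivity indices are undefined and an
#' error is raised.
#'
#' @param cells Cell table with columns `class` and `key` (region-assigned,
#'   e.g. via [assign_region()]).
#' @return The table with flagged starters reclassified.
#' @export
restrict_starters <- function(cells) {
  stopifnot(all(c("class", "key") %in% names(cells)))
  bad <- cells$class == "starter" & cells$key != "CA1_Py_ipsi"
  cells$class[bad] <- "starter_flagged"
  if (!any(cells$class == "starter")) {
    stop("no starter neurons remain in ipsilateral CA1: CSI undefined")
  }
  cells
}
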