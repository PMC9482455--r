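#' Segment amyloid plaques in a single channel
#'
#' Threshold (background median + `threshold_k` x MAD, with the same
#' noise-free fallback as [detect_blobs()]), connected-component labeling
#' and a minimum-area filter; each component is summarized by its area,
#' circular equivalent diameter and mean gray value.
#'
#' @param channel 2-D numeric matrix (plaque channel, arbitrary units).
#' @param threshold_k MAD multiplier.
#' @param min_area_um2 Minimum plaque area in square micrometers.
#' @param pixel_size Micrometers per pixel.
#' @return Data frame of `PlaqueRecord`s: `label`, `area_um2`,
#'   `equiv_diameter` (`2 sqrt(area / pi)`, micrometers), `mean_gray`.
#' @export
segment_plaques <- function(channel, threshold_k = 6, min_area_um2 = 10,
                            pixel_size = 0.65) {
  min_px <- max(1, floor(min_area_um2 / pixel_size^2))
  det <- withCallingHandlers(
    detect_blobs(channel, min_area = min_px, threshold_k = threshold_k,
                 pixel_size = pixel_size),
    warning = function(w) invokeRestart("muffleWarning"))
  data.frame(label = det$label,
             area_um2 = det$area_um2,
             equiv_diameter = 2 * sqrt(det$area_um2 / pi),
             mean_gray = det$mean_intensity)
}

#' Per-section plaque metrics
#'
#' @param records Plaque records from [segment_plaques()].
#' @param fov_area_mm2 Field-of-view area in square millimeters (> 0).
#' @return One-row data frame: `density` (plaques per square millimeter),
#'   `mean_size` (mean equivalent diameter), `mean_intensity` (mean gray
#'   value), `n_plaques`, and `flag` (`"no_plaques"` when the section is
#'   empty, in which case size and intensity are `NA`).
#' @export
section_metrics <- function(records, fov_area_mm2) {
  stopifnot(fov_area_mm2 > 0)
  n <- nrow(records)
  data.frame(density = n / fov_area_mm2,
             mean_size = if (n) mean(records$equiv_diameter) else NA_real_,
             mean_intensity = if (n) mean(records$mean_gray) else NA_real_,
             n_plaques = n,
             flag = if (n) "" else "no_plaques",
             stringsAsFactors = FALSE)
}

#' Average section metrics per brain
#'
#' Arithmetic mean of the per-section plaque metrics for each brain
#' (two sections per brain in the study design). Brains with fewer than
#' the expected number of sections are kept but flagged.
#'
#' @param sections Data frame of per-section metrics with a `brain_id`
#'   column (and optionally `group`), e.g. rows from [section_metrics()].
#' @param expected_sections Number of sections each brain should have.
#' @return One row per brain with averaged `density`, `mean_size`,
#'   `mean_intensity` and a `flag` column.
#' @export
per_brain_average <- function(sections, expected_sections = 2) {
  stopifnot("brain_id" %in% names(sections))
  out <- lapply(split(sections, sections$brain_id), function(s) {
    flag <- if (nrow(s) != expected_sections) {
      sprintf("expected %d sections, got %d", expected_sections, nrow(s))
    } else ""
    data.frame(brain_id = s$brain_id[1],
               group = if ("group" %in% names(s)) s$group[1] else NA_character_,
               density = mean(s$density),
               mean_size = mean(s$mean_size, na.rm = TRUE),
               mean_intensity = mean(s$mean_intensity, na.rm = TRUE),
               n_sections = nrow(s), flag = flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default plaque-imaging configuration
#'
#' Study conditions for the plaque arm: four groups of five brains with
#' two sections each; wild-type brains carry no plaques while APP knock-in
#' brains carry the published young/old densities (654.3 and 1339 plaques
#' per square millimeter) and mean intensities (1057 and 1254 AU); plaque
#' diameters are lognormal with mean 12 um (no age difference); intensity
#' varies between brains (SD 40) and between plaques (SD 80); the CA1
#' field of view is 250 x 200 um at 0.65 um/px.
#'
#' @return Nested list of parameters.
#' @export
default_plaque_config <- function() {
  list(groups = list(
         WT_young = list(density = 0, intensity = NA_real_),
         APP_KI_young = list(density = 654.3, intensity = 1057),
         WT_old = list(density = 0, intensity = NA_real_),
         APP_KI_old = list(density = 1339, intensity = 1254)),
       n_brains = 5, sections_per_brain = 2,
       size_distribution = list(meanlog = log(12) - 0.246^2 / 2, sdlog = 0.246),
       intensity_brain_sd = 40, intensity_sd = 80,
       fov = c(width = 250, height = 200),
       pixel_size = 0.65, background = 150, noise_sd = 0)
}

#' Simulate and quantify a plaque imaging arm
#'
#' Renders `n_brains x sections_per_brain` synthetic sections per group
#' ([render_plaque_section()]), runs [segment_plaques()] and
#' [section_metrics()] on each, and returns the per-section table ready
#' for [per_brain_average()] and [compare_plaques()]. Brain-level
#' intensity heterogeneity enters as a Gaussian random intercept.
#'
#' @param cfg Configuration, see [default_plaque_config()].
#' @param groups Which groups to simulate (default: those with plaques).
#' @param seed Integer seed.
#' @return Data frame of per-section metrics with `group`, `brain_id`,
#'   `section`, the recovered metrics, and the planted truth count
#'   `n_planted`.
#' @export
simulate_plaque_study <- function(cfg = default_plaque_config(),
                                  groups = c("APP_KI_young", "APP_KI_old"),
                                  seed = 1) {
  set.seed(seed)
  area_mm2 <- cfg$fov[1] * cfg$fov[2] / 1e6
  rows <- list()
  for (g in groups) {
    gp <- cfg$groups[[g]]
    if (is.null(gp)) stop("unknown plaque group: ", g)
    for (b in seq_len(cfg$n_brains)) {
      brain_shift <- if (gp$density > 0) stats::rnorm(1, 0, cfg$intensity_brain_sd) else 0
      for (s in seq_len(cfg$sections_per_brain)) {
        sec <- render_plaque_section(
          density = gp$density,
          size_distribution = cfg$size_distribution,
          intensity = list(mean = gp$intensity + brain_shift, sd = cfg$intensity_sd),
          fov = cfg$fov, pixel_size = cfg$pixel_size,
          background = cfg$background, noise_sd = cfg$noise_sd)
        rec <- segment_plaques(sec$image, pixel_size = cfg$pixel_size)
        m <- section_metrics(rec, area_mm2)
        m$group <- g
        m$brain_id <- sprintf("%s_b%02d", g, b)
        m$section <- s
        m$n_planted <- nrow(sec$truth)
        rows[[length(rows) + 1]] <- m
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
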