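#' Default end-to-end run configuration
#'
#' Bundles the stage configurations: cohort generator, plaque arm, imaging
#' and detection parameters, the comparison plan, and bookkeeping (seed,
#' atlas path). `mode = "counts"` runs the count-level pipeline (the
#' generator's per-region counts feed the metrics directly); `mode =
#' "image"` renders every section of every animal, detects and classifies
#' cells, and rebuilds the counts from the images — the two modes agree
#' exactly on noise-free, non-overlapping renders.
#'
#' @param seed Integer seed for the whole run.
#' @param mode `"counts"` or `"image"`.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, mode = c("counts", "image")) {
  mode <- match.arg(mode)
  structure(list(
    seed = seed,
    mode = mode,
    atlas_path = system.file("extdata", "atlas.csv", package = "rabiestrace"),
    cohort = default_cohort_config(seed),
    plaques = default_plaque_config(),
    imaging = list(pixel_size = 5, psf_sigma = 10, noise_sd = 0),
    detection = list(min_area = 2, threshold_k = 6, overlap_min = 0.5),
    report_regions = c("MS_DB", "CA1_Or_ipsi", "CA2_Py_ipsi", "CA3_Py_ipsi",
                       "SUB_ipsi", "EC_ipsi"),
    bin_width = 0.09,
    injection_ap = -1.94
  ), class = "run_config")
}

#' Rescale a cohort configuration
#'
#' Utility for reduced problem sizes (e.g. image-mode runs): scales every
#' region mean, optionally overrides the starter-count mean, the minimum
#' cell spacing used at placement, and the helper-cell fraction.
#'
#' @param cfg Cohort configuration.
#' @param mu_scale Multiplier applied to all region mean CSIs.
#' @param starter_mean,min_spacing,helper_frac Optional overrides.
#' @param groups Optional subset of group names to keep.
#' @return Modified configuration.
#' @export
scale_cohort_config <- function(cfg, mu_scale = 1, starter_mean = NULL,
                                min_spacing = NULL, helper_frac = NULL,
                                groups = NULL) {
  if (!is.null(groups)) cfg$groups <- cfg$groups[groups]
  for (g in names(cfg$groups)) {
    cfg$groups[[g]]$regions$mu <- cfg$groups[[g]]$regions$mu * mu_scale
    cfg$groups[[g]]$overall <- cfg$groups[[g]]$overall * mu_scale
  }
  if (!is.null(starter_mean)) cfg$starter$mean <- starter_mean
  if (!is.null(min_spacing)) cfg$placement$min_spacing <- min_spacing
  if (!is.null(helper_frac)) cfg$helper_frac <- helper_frac
  cfg
}

validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop("not a run_config")
  if (!file.exists(config$atlas_path)) {
    stop("config validation failed: atlas file not found: ", config$atlas_path)
  }
  validate_cohort_config(config$cohort)
  stopifnot(config$bin_width > 0, config$imaging$pixel_size > 0)
  invisible(config)
}

log_line <- function(con, ...) {
  msg <- sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  writeLines(msg, con)
}

#' Rebuild per-animal counts from rendered section images
#'
#' The image-level quantification path: for each mounted section of one
#' animal, render the three-channel micrograph, detect blobs in the GFP
#' and DsRed channels, classify starter / input / helper-only cells by
#' mask overlap, assign region keys from the detected centroids, and
#' restrict starters to ipsilateral CA1. Returns the starter count and the
#' per-region input counts in the same shape the count-level generator
#' emits.
#'
#' @param cells Planted cell table of one animal.
#' @param atlas Atlas table.
#' @param imaging,detection Imaging and detection parameter lists (see
#'   [default_run_config()]).
#' @return List with `S`, `counts` (named vector over [region_keys()]),
#'   `n_helper`, `n_flagged`.
#' @export
image_mode_counts <- function(cells, atlas = load_atlas(),
                              imaging = list(pixel_size = 5, psf_sigma = 10,
                                             noise_sd = 0),
                              detection = list(min_area = 2, threshold_k = 6,
                                               overlap_min = 0.5)) {
  keys <- region_keys()
  counts <- stats::setNames(integer(length(keys)), keys)
  all_classified <- list()
  for (ap in sort(unique(cells$ap))) {
    sec_cells <- cells[cells$ap == ap, ]
    geom <- section_geometry(ap = ap, pixel_size = imaging$pixel_size)
    sec <- render_tracing_section(sec_cells, geom,
                                  noise_sd = imaging$noise_sd,
                                  psf_sigma = imaging$psf_sigma)
    org <- c(geom$frame[1], geom$frame[2])
    suppress_empty <- function(expr) {
      withCallingHandlers(expr, warning = function(w) invokeRestart("muffleWarning"))
    }
    gdet <- suppress_empty(detect_blobs(sec$image[, , 2], detection$min_area,
                                        detection$threshold_k,
                                        imaging$pixel_size, org))
    rdet <- suppress_empty(detect_blobs(sec$image[, , 3], detection$min_area,
                                        detection$threshold_k,
                                        imaging$pixel_size, org))
    cl <- classify_cells(gdet, rdet, detection$overlap_min)
    if (!nrow(cl)) next
    asn <- assign_region(rep(ap, nrow(cl)), cl$x, cl$y, atlas)
    cl$key <- asn$key
    all_classified[[length(all_classified) + 1]] <- cl
  }
  cl <- do.call(rbind, all_classified)
  cl <- restrict_starters(cl)
  inp <- cl[cl$class == "input", ]
  tab <- table(factor(inp$key, levels = keys))
  counts[names(tab)] <- as.integer(tab)
  list(S = sum(cl$class == "starter"), counts = counts,
       n_helper = sum(cl$class == "helper_only"),
       n_flagged = sum(cl$class == "starter_flagged"))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate, (render + detect + classify +
#' assign in image mode), connectivity metrics, plaque arm, statistics,
#' report — writing every table as CSV into `out_dir` together with the
#' serialized configuration, its MD5 hash, and a timestamped log of
#' per-stage counts. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config Run configuration from [default_run_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "log.txt"), "w")
  on.exit(close(logf))
  stage <- function(name, expr) {
    log_line(logf, "stage ", name, " start")
    tryCatch(expr, error = function(e) {
      log_line(logf, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_line(logf, "config hash ", cfg_hash)

  atlas <- stage("load_atlas", load_atlas(config$atlas_path))
  level <- if (config$mode == "image") "cells" else "counts"
  sim <- stage("simulate", simulate_study(config$cohort, config$seed, level, atlas))
  log_line(logf, "simulated ", nrow(sim$animals), " animals")

  if (config$mode == "image") {
    counts_rows <- stage("detect", {
      out <- list()
      for (id in sim$animals$animal_id) {
        q <- image_mode_counts(sim$cells[sim$cells$animal_id == id, ], atlas,
                               config$imaging, config$detection)
        sim$animals$S[sim$animals$animal_id == id] <- q$S
        out[[id]] <- data.frame(animal_id = id, key = names(q$counts),
                                count = as.integer(q$counts),
                                stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
    sim$counts <- counts_rows
    log_line(logf, "image-mode quantification of ", length(unique(counts_rows$animal_id)),
             " animals")
  }

  conn <- stage("metrics", connectivity_table(sim$animals, sim$counts))
  curves <- NULL
  if (level == "cells") {
    curves <- stage("ap_curves", {
      rows <- list()
      for (g in unique(sim$animals$group)) {
        an <- sim$animals[sim$animals$group == g, ]
        ce <- sim$cells[sim$cells$animal_id %in% an$animal_id, ]
        for (key in config$report_regions) {
          gc <- group_ap_curves(ce, an, key, config$bin_width)
          rows[[length(rows) + 1]] <- data.frame(
            group = g, key = key, ap = gc$ap, mean = gc$mean, se = gc$se)
        }
      }
      do.call(rbind, rows)
    })
  }

  plaque_sections <- stage("plaques", {
    set.seed(config$seed + 1L)
    simulate_plaque_study(config$plaques, seed = config$seed + 1L)
  })
  plaque_brains <- per_brain_average(plaque_sections,
                                     config$plaques$sections_per_brain)

  stats_res <- stage("stats", compare_groups(conn))
  plaque_stats <- stage("plaque_stats",
                        compare_plaques(plaque_sections, "APP_KI_young", "APP_KI_old"))
  log_line(logf, "ran ", attr(stats_res, "n_tests"), " group tests (unadjusted)")

  wr <- function(df, name) {
    if (is.null(df)) return(invisible())
    utils::write.csv(cbind(df, config_hash = cfg_hash), file.path(out_dir, name),
                     row.names = FALSE)
  }
  wr(sim$animals, "animals.csv")
  wr(sim$counts, "counts.csv")
  if (!is.null(sim$cells)) wr(sim$cells, "cells.csv")
  wr(conn, "connectivity.csv")
  wr(curves, "ap_curves.csv")
  wr(plaque_sections, "plaque_sections.csv")
  wr(plaque_brains, "plaque_brains.csv")
  wr(stats_res, "stats_results.csv")
  wr(plaque_stats, "plaque_stats.csv")
  log_line(logf, "run complete")
  invisible(out_dir)
}

serialize_config <- function(config) {
  ser <- rapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, classes = "ANY", how = "replace")
  ser
}

#' Build the tabular / graphical report for a completed run
#'
#' Emits `report.json` — group bar tables (mean, SE, n) for overall
#' connectivity, per-region CSI and PI with significance stars from the
#' stats stage, plaque summaries, and the AP curves with the injection
#' site marker at AP -1.94 mm — plus an `ap_curves.pdf` figure when curves
#' were computed. Every plotted number is present in the JSON.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Path to `report.json`, invisibly.
#' @export
make_report <- function(run_dir) {
  rd <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  conn <- rd("connectivity.csv")
  if (is.null(conn)) stop("no connectivity.csv in ", run_dir, "; run the pipeline first")
  stats_res <- rd("stats_results.csv")
  curves <- rd("ap_curves.csv")
  plaque_brains <- rd("plaque_brains.csv")
  plaque_stats <- rd("plaque_stats.csv")

  per_animal <- conn[!duplicated(conn$animal_id), ]
  overall <- lapply(split(per_animal, per_animal$group), function(s) {
    list(mean = mean(s$overall), se = stats::sd(s$overall) / sqrt(nrow(s)),
         n = nrow(s))
  })
  region_tab <- function(metric) {
    out <- list()
    for (g in unique(conn$group)) {
      s <- conn[conn$group == g, ]
      agg <- lapply(split(s[[metric]], s$key), function(v) {
        list(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
      })
      out[[g]] <- agg
    }
    out
  }
  report <- list(
    overall_connectivity = overall,
    csi = region_tab("csi"),
    pi = region_tab("pi"),
    stats = if (!is.null(stats_res)) stats_res else list(),
    plaques = list(brains = if (!is.null(plaque_brains)) plaque_brains else list(),
                   stats = if (!is.null(plaque_stats)) plaque_stats else list()),
    ap_curves = if (!is.null(curves)) curves else list(),
    injection_ap_mm = -1.94,
    multiplicity = "none (unadjusted p-values)"
  )
  out_path <- file.path(run_dir, "report.json")
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(curves)) {
    grDevices::pdf(file.path(run_dir, "ap_curves.pdf"), width = 7, height = 5)
    for (key in unique(curves$key)) {
      sub <- curves[curves$key == key, ]
      graphics::plot(NULL, xlim = range(sub$ap), ylim = range(c(0, sub$mean + sub$se)),
                     xlab = "AP (mm from bregma)", ylab = "CSI per bin", main = key)
      cols <- stats::setNames(seq_along(unique(sub$group)) + 1, unique(sub$group))
      for (g in unique(sub$group)) {
        s <- sub[sub$group == g, ]
        graphics::lines(s$ap, s$mean, col = cols[g])
      }
      graphics::abline(v = -1.94, col = "red", lty = 2)
      graphics::legend("topleft", legend = names(cols), col = cols, lty = 1, bty = "n")
    }
    grDevices::dev.off()
  }
  invisible(out_path)
}
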