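#' Default group-comparison plan
#'
#' The study's contrast structure: age-matched genotype comparisons and
#' within-genotype age comparisons, applied per region to CSI and PI and to
#' the brain-wide overall index, plus male-female comparisons within each
#' group. No multiple-testing adjustment is applied (the number of tests is
#' reported alongside the results).
#'
#' @param keys Region keys to test (default all canonical keys).
#' @return List with `contrasts` (list of group pairs), `metrics`, `keys`,
#'   `sex_split` (logical).
#' @export
default_comparison_plan <- function(keys = region_keys()) {
  list(contrasts = list(c("WT_young", "APP_KI_young"),
                        c("WT_old", "APP_KI_old"),
                        c("WT_young", "WT_old"),
                        c("APP_KI_young", "APP_KI_old")),
       metrics = c("csi", "pi"),
       keys = keys,
       sex_split = TRUE)
}

#' Run the group-comparison battery on a connectivity table
#'
#' For every planned contrast, applies the exact tie-aware Wilcoxon
#' rank-sum test ([rank_sum_exact()]) to each region's CSI and PI and to
#' the per-animal overall connectivity, and (optionally) compares males and
#' females within each group. Contrasts with fewer than 2 animals in a
#' group are skipped with a flag row.
#'
#' @param conn Connectivity table from [connectivity_table()].
#' @param plan Comparison plan, see [default_comparison_plan()].
#' @return Data frame of `StatResult` rows with columns `metric`, `key`
#'   added; attribute `n_tests` gives the number of tests run (no
#'   multiplicity adjustment is applied).
#' @export
compare_groups <- function(conn, plan = default_comparison_plan()) {
  res <- list()
  add <- function(row, metric, key, label) {
    row$metric <- metric; row$key <- key; row$comparison <- label
    res[[length(res) + 1]] <<- row
  }
  one_animal_metric <- function(sub, metric, key) {
    if (metric == "overall") {
      u <- sub[!duplicated(sub$animal_id), ]
      u$value <- u$overall
      return(u)
    }
    u <- sub[sub$key == key, ]
    u$value <- u[[metric]]
    u
  }
  run_contrast <- function(sub_a, sub_b, label_a, label_b, metric, key) {
    lab <- sprintf("%s vs %s: %s %s", label_a, label_b, key, metric)
    if (length(unique(sub_a$animal_id)) < 2 || length(unique(sub_b$animal_id)) < 2) {
      add(stat_result(lab, "skipped", NA_real_, NA_real_,
                      NA, NA, length(unique(sub_a$animal_id)),
                      NA, NA, length(unique(sub_b$animal_id)),
                      flag = "skipped: group with n < 2"), metric, key, lab)
      return(invisible())
    }
    va <- one_animal_metric(sub_a, metric, key)$value
    vb <- one_animal_metric(sub_b, metric, key)$value
    add(rank_sum_exact(va, vb), metric, key, lab)
  }
  for (ct in plan$contrasts) {
    a <- conn[conn$group == ct[1], ]; b <- conn[conn$group == ct[2], ]
    for (key in plan$keys) {
      for (metric in plan$metrics) run_contrast(a, b, ct[1], ct[2], metric, key)
    }
    run_contrast(a, b, ct[1], ct[2], "overall", "whole_brain")
  }
  if (isTRUE(plan$sex_split)) {
    for (g in unique(conn$group)) {
      sub <- conn[conn$group == g, ]
      am <- sub[sub$sex == "M", ]; af <- sub[sub$sex == "F", ]
      for (key in plan$keys) {
        for (metric in plan$metrics) {
          run_contrast(am, af, paste0(g, ":M"), paste0(g, ":F"), metric, key)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  p_done <- !is.na(out$p_value)
  attr(out, "n_tests") <- sum(p_done)
  attr(out, "multiplicity") <- "none (unadjusted p-values)"
  out
}

#' Cross-check the comparison battery against the reference library
#'
#' Re-runs every non-degenerate rank-sum contrast of [compare_groups()]
#' through [stats::wilcox.test()] and reports the largest absolute p-value
#' discrepancy. A tooling aid for verifying the from-scratch tests, not
#' part of the analysis path (the reference test warns and approximates
#' under ties; discrepancies on tied data reflect its different tie
#' handling, so tied contrasts are reported separately).
#'
#' @param conn Connectivity table.
#' @param plan Comparison plan.
#' @return List with `max_abs_dp_untied`, `n_untied`, `n_tied`, `n_total`.
#' @export
cross_check_contrasts <- function(conn, plan = default_comparison_plan()) {
  res <- compare_groups(conn, plan)
  max_dp <- 0; n_untied <- 0L; n_tied <- 0L
  get_vals <- function(sub, metric, key) {
    if (metric == "overall") return(sub$overall[!duplicated(sub$animal_id)])
    sub[[metric]][sub$key == key]
  }
  for (i in seq_len(nrow(res))) {
    if (res$test[i] == "skipped") next
    parts <- strsplit(res$comparison[i], " vs |: | ")[[1]]
    ga <- parts[1]; gb <- parts[2]
    sub_a <- if (grepl(":", ga)) {
      g <- sub(":.*", "", ga); conn[conn$group == g & conn$sex == sub(".*:", "", ga), ]
    } else conn[conn$group == ga, ]
    sub_b <- if (grepl(":", gb)) {
      g <- sub(":.*", "", gb); conn[conn$group == g & conn$sex == sub(".*:", "", gb), ]
    } else conn[conn$group == gb, ]
    va <- get_vals(sub_a, res$metric[i], res$key[i])
    vb <- get_vals(sub_b, res$metric[i], res$key[i])
    tied <- any(duplicated(c(va, vb)))
    if (tied) { n_tied <- n_tied + 1L; next }
    n_untied <- n_untied + 1L
    # match the implementation's regime: full enumeration only for n+m <= 14
    ref <- suppressWarnings(stats::wilcox.test(
      va, vb, exact = length(c(va, vb)) <= 14, correct = TRUE)$p.value)
    max_dp <- max(max_dp, abs(ref - res$p_value[i]))
  }
  list(max_abs_dp_untied = max_dp, n_untied = n_untied, n_tied = n_tied,
       n_total = n_untied + n_tied)
}

#' Paired AP-curve comparison between two groups
#'
#' Compares two groups' AP-registered CSI distribution curves for one
#' region with the exact Wilcoxon signed-rank test applied to the
#' AP-bin-matched group mean values; bins where both group means are zero
#' are dropped. This operationalizes a paired rank comparison of
#' AP-registered curves.
#'
#' @param curves_a,curves_b Results of [group_ap_curves()] on the same grid.
#' @return One-row `StatResult` data frame.
#' @export
compare_ap_curves <- function(curves_a, curves_b) {
  stopifnot(isTRUE(all.equal(curves_a$ap, curves_b$ap)))
  keep <- curves_a$mean != 0 | curves_b$mean != 0
  if (!any(keep)) {
    return(stat_result("curve A vs B", "Wilcoxon signed-rank (exact, tie-aware)",
                       0, 1, 0, 0, 0, 0, 0, 0, "degenerate: both curves all-zero"))
  }
  signed_rank_paired(curves_a$mean[keep], curves_b$mean[keep])
}

#' Plaque-metric group comparison
#'
#' Density and size are compared across brains with the exact rank-sum
#' test; intensity is compared at the section level with the
#' random-intercept LME (brain as the random effect), mirroring an
#' analysis where two sections per brain are measured.
#'
#' @param sections Per-section metrics with columns `brain_id`, `group`,
#'   `density`, `mean_size`, `mean_intensity`.
#' @param group_a,group_b Group labels to compare.
#' @return Data frame: rank-sum rows for density and size (per-brain
#'   averages) and an LME row for intensity.
#' @export
compare_plaques <- function(sections, group_a, group_b) {
  sub <- sections[sections$group %in% c(group_a, group_b), ]
  brains <- per_brain_average(sub)
  a <- brains[brains$group == group_a, ]; b <- brains[brains$group == group_b, ]
  rows <- list()
  for (metric in c("density", "mean_size")) {
    r <- rank_sum_exact(a[[metric]], b[[metric]])
    r$comparison <- sprintf("%s vs %s: %s", group_a, group_b, metric)
    r$metric <- metric; r$key <- "plaques"
    rows[[length(rows) + 1]] <- r
  }
  fit <- lme_random_intercept(sub$mean_intensity, sub$brain_id,
                              factor(sub$group, levels = c(group_a, group_b)))
  rows[[length(rows) + 1]] <- data.frame(
    comparison = sprintf("%s vs %s: mean_intensity", group_a, group_b),
    test = "LME random intercept (ML, Wald)", statistic = fit$z_group,
    p_value = fit$p_group, stars = p_stars(fit$p_group),
    mean_a = mean(a$mean_intensity), se_a = stats::sd(a$mean_intensity) / sqrt(nrow(a)),
    n_a = nrow(a),
    mean_b = mean(b$mean_intensity), se_b = stats::sd(b$mean_intensity) / sqrt(nrow(b)),
    n_b = nrow(b), flag = "", metric = "mean_intensity", key = "plaques",
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
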