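#' Connectivity strength index (CSI)
#'
#' Per-animal ratio of presynaptic input neurons in a region to the number
#' of starter neurons: `CSI_r = N_r / S`.
#'
#' @param counts Named non-negative vector of per-region input counts.
#' @param S Starter-neuron count (>= 1).
#' @return Named numeric vector of CSI values.
#' @export
compute_csi <- function(counts, S) {
  if (length(S) != 1 || is.na(S) || S < 1) {
    stop("CSI is undefined without starter neurons (S >= 1)")
  }
  if (any(counts < 0)) stop("negative input counts")
  counts / S
}

#' Proportion of input (PI)
#'
#' Per-animal fraction of all labeled inputs that lie in a region:
#' `PI_r = N_r / N_tot`. Sums to 1 over the canonical region partition
#' (which includes the catch-all OTHER).
#'
#' @param counts Named non-negative vector of per-region input counts.
#' @return Named numeric vector of PI values.
#' @export
compute_pi <- function(counts) {
  if (any(counts < 0)) stop("negative input counts")
  tot <- sum(counts)
  if (tot < 1) stop("PI is undefined without labeled inputs (N_tot >= 1)")
  counts / tot
}

#' Brain-wide overall connectivity index
#'
#' Total labeled inputs over starters: `O = N_tot / S = sum_r CSI_r`.
#'
#' @inheritParams compute_csi
#' @return Scalar overall index.
#' @export
overall_connectivity <- function(counts, S) {
  sum(compute_csi(counts, S))
}

#' Per-animal connectivity table
#'
#' Long-format table of CSI and PI for every animal and canonical region,
#' plus the per-animal overall index, with group metadata carried along.
#'
#' @param animals Animal table from [simulate_cohort()] (columns
#'   `animal_id`, `group`, `genotype`, `age_group`, `sex`, `S`).
#' @param counts Long count table (`animal_id`, `key`, `count`).
#' @return Data frame with one row per animal x region: `csi`, `pi`,
#'   `overall` (repeated within animal) and the metadata columns.
#' @export
connectivity_table <- function(animals, counts) {
  stopifnot(all(counts$animal_id %in% animals$animal_id))
  out <- lapply(seq_len(nrow(animals)), function(i) {
    a <- animals[i, ]
    ct <- counts[counts$animal_id == a$animal_id, ]
    v <- stats::setNames(ct$count, ct$key)
    csi <- compute_csi(v, a$S)
    data.frame(animal_id = a$animal_id, group = a$group,
               genotype = a$genotype, age_group = a$age_group, sex = a$sex,
               S = a$S, key = names(v), count = unname(v),
               csi = unname(csi), pi = unname(compute_pi(v)),
               overall = sum(csi), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' AP bin grid anchored at bregma
#'
#' @param ap_range Span (mm) to cover, default the packaged atlas span.
#' @param bin_width Bin width in mm; the default 0.09 mm equals the
#'   effective section spacing (30 um thickness, one of three mounted).
#' @return Numeric vector of bin centers (multiples of `bin_width`).
#' @export
ap_bin_grid <- function(ap_range = c(-4.95, 1.08), bin_width = 0.09) {
  stopifnot(bin_width > 0, ap_range[1] < ap_range[2])
  k <- seq(floor(ap_range[1] / bin_width), ceiling(ap_range[2] / bin_width))
  k * bin_width + 0
}

#' Per-animal AP-registered CSI distribution curve
#'
#' Bins a region's input cells along the anterior-posterior axis and divides
#' the per-bin counts by the animal's starter count, so that the curve sums
#' exactly to the region's CSI. Bins are anchored at bregma; each cell is
#' assigned to the nearest bin center.
#'
#' @param cells Cell table with columns `key` and `ap` (input cells; any
#'   non-input rows are ignored).
#' @param key Canonical region key, e.g. `"CA3_Py_ipsi"`.
#' @param S Starter count of the animal.
#' @param bin_width,ap_range Grid parameters, see [ap_bin_grid()].
#' @return Object of class `ap_curve`: data frame with `ap` (bin centers)
#'   and `csi` (per-bin CSI).
#' @export
build_ap_curve <- function(cells, key, S, bin_width = 0.09,
                           ap_range = c(-4.95, 1.08)) {
  if (length(S) != 1 || S < 1) stop("S >= 1 required")
  centers <- ap_bin_grid(ap_range, bin_width)
  sel <- cells$key == key & (!("class" %in% names(cells)) | cells$class == "input")
  ap <- cells$ap[sel]
  idx <- round(ap / bin_width) - round(ap_range[1] / bin_width) + 1
  if (length(idx) && (min(idx) < 1 || max(idx) > length(centers))) {
    stop("cell AP outside the curve's AP range")
  }
  cnt <- tabulate(idx, nbins = length(centers))
  out <- data.frame(ap = centers, csi = cnt / S)
  class(out) <- c("ap_curve", "data.frame")
  out
}

#' Group AP curves: per-animal curves on a common grid with mean and SE
#'
#' @param cells Cell table for several animals (column `animal_id`).
#' @param animals Animal table supplying `S` per animal.
#' @inheritParams build_ap_curve
#' @return List with `ap` (bin centers), `curves` (animals x bins matrix),
#'   `mean`, `se`.
#' @export
group_ap_curves <- function(cells, animals, key, bin_width = 0.09,
                            ap_range = c(-4.95, 1.08)) {
  centers <- ap_bin_grid(ap_range, bin_width)
  m <- t(vapply(seq_len(nrow(animals)), function(i) {
    a <- animals[i, ]
    build_ap_curve(cells[cells$animal_id == a$animal_id, ], key, a$S,
                   bin_width, ap_range)$csi
  }, numeric(length(centers))))
  list(ap = centers, curves = m,
       mean = colMeans(m),
       se = apply(m, 2, stats::sd) / sqrt(nrow(m)))
}

#' Area under an AP distribution curve
#'
#' Trapezoidal area of a per-animal binned CSI curve over its AP span
#' (dimensionless CSI x mm). An isolated single-bin spike of height `h`
#' between zero neighbors contributes `h x bin_width` (rectangle
#' convention); an all-zero curve has area 0.
#'
#' @param curve An `ap_curve` from [build_ap_curve()], or a data frame with
#'   columns `ap` and `csi`.
#' @return Scalar area.
#' @export
curve_auc <- function(curve) {
  x <- curve$ap; y <- curve$csi
  if (length(x) < 2) stop("need at least 2 bins")
  pracma::trapz(x, y)
}
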