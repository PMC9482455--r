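#' Canonical brain-region codes
#'
#' The region ontology used throughout the package: hippocampal CA1/CA2/CA3
#' layers (pyramidal Py, oriens Or, radiatum Rad, lacunosum-moleculare LMol),
#' the medial septum-diagonal band complex (MS_DB), subiculum (SUB),
#' entorhinal cortex (EC), median/paramedian raphe (MnR_PMnR), nucleus
#' reuniens (ReN), and a catch-all OTHER that pools all remaining labeled
#' cells so that proportion-of-input indices normalize over every input.
#'
#' @return Character vector of the 14 region codes.
#' @export
region_codes <- function() {
  c("CA1_Py", "CA1_Or", "CA1_Rad", "CA1_LMol", "CA2_Py", "CA2_Or",
    "CA3_Py", "CA3_Or", "MS_DB", "SUB", "EC", "MnR_PMnR", "ReN", "OTHER")
}

#' @rdname region_codes
#' @export
midline_codes <- function() c("MS_DB", "MnR_PMnR", "ReN")

#' Canonical (region, side) keys
#'
#' Region codes crossed with hemisphere side. Midline structures (MS-DB,
#' MnR/PMnR, ReN) carry a single key; all other codes are split into
#' ipsilateral and contralateral keys relative to the (left) injection
#' hemisphere.
#'
#' @return Character vector of 25 region-side keys, e.g. `"CA1_Py_ipsi"`,
#'   `"MS_DB"`.
#' @export
region_keys <- function() {
  sided <- setdiff(region_codes(), midline_codes())
  c(as.vector(t(outer(sided, c("ipsi", "contra"), paste, sep = "_"))),
    midline_codes())
}

#' Build a (region, side) key from its components
#'
#' @param code Region code(s), see [region_codes()].
#' @param side `"ipsi"`, `"contra"` or `"midline"`.
#' @return Character key; midline codes map to the bare code.
#' @export
region_key <- function(code, side) {
  ifelse(code %in% midline_codes(), code, paste(code, side, sep = "_"))
}

#' Load the packaged schematic atlas
#'
#' The atlas is a simplified stand-in for atlas-guided anatomical assignment:
#' one rectangular footprint per region code in the left hemisphere (mirrored
#' for the right), each valid over an anterior-posterior slab. Region
#' footprints within overlapping slabs never overlap spatially, so assignment
#' is unambiguous. It orders regions along the AP axis (MS-DB most anterior,
#' then the hippocampal formation with CA3 starting anterior to CA1, SUB, and
#' EC most posterior) but is not a volumetric reference atlas.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Data frame with columns `region`, `side_rule`, `ap_min`, `ap_max`
#'   and a list-column `polygon` of two-column vertex matrices (micrometers).
#' @export
load_atlas <- function(path = system.file("extdata", "atlas.csv",
                                          package = "rabiestrace")) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  at <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "side_rule", "ap_min", "ap_max", "polygon")
  if (!all(need %in% names(at))) {
    stop("atlas is missing columns: ", paste(setdiff(need, names(at)), collapse = ", "))
  }
  at$polygon <- lapply(at$polygon, parse_polygon)
  validate_atlas(at)
  at
}

parse_polygon <- function(s) {
  verts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[[:space:]]+")
  m <- do.call(rbind, lapply(verts, function(v) as.numeric(v[nzchar(v)])))
  colnames(m) <- c("x", "y")
  m
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

validate_atlas <- function(at) {
  stopifnot(all(at$ap_min < at$ap_max))
  areas <- vapply(at$polygon, polygon_area, numeric(1))
  if (any(areas <= 0)) stop("atlas polygons must have positive area")
  if (!all(at$region %in% region_codes())) {
    stop("unknown region codes in atlas: ",
         paste(setdiff(at$region, region_codes()), collapse = ", "))
  }
  # pairwise non-overlap within intersecting AP slabs (bounding boxes suffice
  # for the packaged rectangular footprints)
  n <- nrow(at)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ap_olap <- at$ap_min[i] < at$ap_max[j] && at$ap_min[j] < at$ap_max[i]
      if (!ap_olap) next
      bi <- apply(at$polygon[[i]], 2, range)
      bj <- apply(at$polygon[[j]], 2, range)
      if (bi[1, 1] < bj[2, 1] && bj[1, 1] < bi[2, 1] &&
          bi[1, 2] < bj[2, 2] && bj[1, 2] < bi[2, 2]) {
        stop("atlas footprints overlap within one AP slab: ",
             at$region[i], " / ", at$region[j])
      }
    }
  }
  invisible(at)
}

#' Hemisphere side of a mediolateral coordinate
#'
#' @param ml Signed mediolateral coordinate(s) in micrometers; the origin is
#'   the midline and positive values are the right hemisphere.
#' @param injection_side `"left"` (default, matching a left-hemisphere CA1
#'   injection) or `"right"`.
#' @param midline_band Half-width (micrometers) of the band around the
#'   midline classified as `"midline"`.
#' @return Character vector: `"ipsi"`, `"contra"` or `"midline"`.
#' @export
hemisphere_side <- function(ml, injection_side = c("left", "right"),
                            midline_band = 150) {
  injection_side <- match.arg(injection_side)
  out <- rep("midline", length(ml))
  left <- ml < -midline_band
  right <- ml > midline_band
  if (injection_side == "left") {
    out[left] <- "ipsi"; out[right] <- "contra"
  } else {
    out[left] <- "contra"; out[right] <- "ipsi"
  }
  out
}

# even-odd point-in-polygon with inclusive boundary (closed polygons)
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # on-edge test: collinear and within segment bounds
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    cr <- dx * (py - y[i]) - dy * (px - x[i])
    if (abs(cr) < 1e-9 &&
        px >= min(x[i], x[j]) - 1e-9 && px <= max(x[i], x[j]) + 1e-9 &&
        py >= min(y[i], y[j]) - 1e-9 && py <= max(y[i], y[j]) + 1e-9) {
      return(TRUE)
    }
    if ((y[i] > py) != (y[j] > py)) {
      xint <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Assign labeled cells to atlas regions
#'
#' Deterministic and total: every cell receives exactly one (code, side)
#' pair. A cell matches an atlas entry when its AP position lies inside the
#' entry's slab (inclusive) and its section coordinates fall inside the
#' footprint polygon (boundary inclusive); `"mirror"` entries are tested in
#' the cell's own hemisphere by reflecting the coordinate across the midline.
#' Cells matching no footprint, and cells whose AP lies outside every slab
#' (warned), map to `OTHER` with the side given by [hemisphere_side()].
#'
#' @param ap Numeric vector, AP position of each cell (mm from bregma).
#' @param x,y Numeric vectors, section coordinates (micrometers; x signed,
#'   midline origin).
#' @param atlas Atlas table from [load_atlas()].
#' @param injection_side,midline_band Passed to [hemisphere_side()].
#' @return Data frame with columns `code`, `side`, `key`.
#' @export
assign_region <- function(ap, x, y, atlas = load_atlas(),
                          injection_side = "left", midline_band = 150) {
  stopifnot(length(ap) == length(x), length(x) == length(y))
  if (nrow(atlas) == 0) stop("atlas is empty")
  side <- hemisphere_side(x, injection_side, midline_band)
  code <- rep("OTHER", length(ap))
  in_any_slab <- rep(FALSE, length(ap))
  for (i in seq_len(nrow(atlas))) {
    slab <- ap >= atlas$ap_min[i] & ap <= atlas$ap_max[i]
    in_any_slab <- in_any_slab | slab
    cand <- which(slab & code == "OTHER")
    if (atlas$region[i] == "OTHER") next  # catch-all resolved last
    poly <- atlas$polygon[[i]]
    for (k in cand) {
      px <- x[k]
      if (atlas$side_rule[i] == "mirror" && px > 0) px <- -px
      if (point_in_polygon(px, y[k], poly)) code[k] <- atlas$region[i]
    }
  }
  if (any(!in_any_slab)) {
    warning(sum(!in_any_slab),
            " cell(s) with AP outside every atlas slab assigned to OTHER")
  }
  side[code %in% midline_codes()] <- "midline"
  # sided codes need ipsi/contra: cells inside the midline band that match a
  # sided (or no) footprint resolve to the injection side by convention
  side[!(code %in% midline_codes()) & side == "midline"] <- "ipsi"
  data.frame(code = code, side = side, key = region_key(code, side),
             stringsAsFactors = FALSE)
}

#' Anterior-posterior occupancy profiles of the atlas regions
#'
#' Mean and spread (mm) of a truncated-Gaussian AP occupancy per region,
#' used by the synthetic cohort generator. Means are ordered along AP as in
#' the atlas (MS-DB anterior, EC posterior) and the CA3 mean sits anterior
#' to the CA1 injection site at AP -1.94 mm, reproducing the anterior CA3
#' input peak seen in tracing data.
#'
#' @return Data frame with columns `region`, `ap_mu`, `ap_sd`.
#' @export
region_ap_profiles <- function() {
  data.frame(
    region = c("CA1_Py", "CA1_Or", "CA1_Rad", "CA1_LMol", "CA2_Py", "CA2_Or",
               "CA3_Py", "CA3_Or", "MS_DB", "SUB", "EC", "MnR_PMnR", "ReN",
               "OTHER"),
    ap_mu = c(-1.94, -1.94, -1.94, -1.94, -1.90, -1.90,
              -1.60, -1.60, 0.70, -3.20, -3.80, -4.40, -0.80, -1.50),
    ap_sd = c(0.45, 0.45, 0.45, 0.45, 0.30, 0.30,
              0.35, 0.35, 0.25, 0.30, 0.50, 0.20, 0.30, 1.50),
    stringsAsFactors = FALSE
  )
}
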