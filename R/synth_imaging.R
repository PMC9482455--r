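#' Section geometry descriptor
#'
#' @param ap AP position of the section (mm from bregma).
#' @param thickness Section thickness, micrometers (30 um sectioning).
#' @param mounted_every One of every `mounted_every` consecutive sections is
#'   mounted (default 3), giving an effective AP spacing of
#'   `thickness * mounted_every` (90 um).
#' @param pixel_size Micrometers per pixel (default 0.65, a 10x
#'   slide-scanner scale).
#' @param frame Section frame in micrometers: `c(x0, y0, width, height)`;
#'   the default covers the packaged atlas.
#' @return List of class `section_geometry`.
#' @export
section_geometry <- function(ap = 0, thickness = 30, mounted_every = 3,
                             pixel_size = 0.65,
                             frame = c(x0 = -1750, y0 = -50,
                                       width = 3500, height = 3200)) {
  stopifnot(thickness > 0, mounted_every >= 1, pixel_size > 0,
            frame[3] > 0, frame[4] > 0)
  structure(list(ap = ap, thickness = thickness, mounted_every = mounted_every,
                 pixel_size = pixel_size, frame = frame),
            class = "section_geometry")
}

um_to_px <- function(u, origin, pixel_size) (u - origin) / pixel_size + 0.5
px_to_um <- function(p, origin, pixel_size) origin + (p - 0.5) * pixel_size

# add truncated Gaussian spots (cut at 3 sigma) to a matrix, in place
add_spots <- function(img, cx, cy, amp, sigma_px, truncate = 3) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(truncate * sigma_px)
  for (i in seq_along(cx)) {
    c0 <- max(1, floor(cx[i] - r)); c1 <- min(w, ceiling(cx[i] + r))
    r0 <- max(1, floor(cy[i] - r)); r1 <- min(h, ceiling(cy[i] + r))
    if (c0 > c1 || r0 > r1) next
    cc <- c0:c1; rr <- r0:r1
    d2 <- outer((rr - cy[i])^2, (cc - cx[i])^2, "+")
    patch <- amp[i] * exp(-d2 / (2 * sigma_px^2))
    patch[d2 > (truncate * sigma_px)^2] <- 0
    img[rr, cc] <- img[rr, cc] + patch
  }
  img
}

#' Render a synthetic tracing section (DAPI / GFP / DsRed)
#'
#' Each cell on the section is drawn as a Gaussian spot (truncated at 3
#' sigma) in the channels dictated by its class: starters in GFP and DsRed,
#' inputs in DsRed only, helper-only cells in GFP only; amplitudes come
#' from the cell table's `gfp`/`dsred` columns. Optional additive Gaussian
#' background noise. The planted truth is retained alongside the image.
#'
#' @param cells Cell table (columns `class`, `x`, `y`, `gfp`, `dsred`), all
#'   on this section's AP.
#' @param geometry [section_geometry()].
#' @param noise_sd Additive Gaussian noise SD (arbitrary units).
#' @param psf_sigma Spot Gaussian sigma in micrometers.
#' @param background Per-channel background level `c(dapi, gfp, dsred)`.
#' @param seed Optional seed (noise only).
#' @return List of class `synthetic_section`: `image` (h x w x 3 array,
#'   channel order DAPI, GFP, DsRed), `truth`, `geometry`.
#' @export
render_tracing_section <- function(cells, geometry = section_geometry(),
                                   noise_sd = 0, psf_sigma = 10,
                                   background = c(dapi = 500, gfp = 100, dsred = 100),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ps <- geometry$pixel_size
  w <- unname(ceiling(geometry$frame[3] / ps))
  h <- unname(ceiling(geometry$frame[4] / ps))
  img <- array(rep(background, each = h * w), dim = c(h, w, 3))
  if (nrow(cells)) {
    cx <- um_to_px(cells$x, geometry$frame[1], ps)
    cy <- um_to_px(cells$y, geometry$frame[2], ps)
    bad <- cx < 1 | cx > w | cy < 1 | cy > h
    if (any(bad)) stop("planted cells outside the section frame")
    s_px <- psf_sigma / ps
    gfp_on <- cells$gfp > 0
    if (any(gfp_on)) {
      img[, , 2] <- add_spots(img[, , 2], cx[gfp_on], cy[gfp_on],
                              cells$gfp[gfp_on], s_px)
    }
    red_on <- cells$dsred > 0
    if (any(red_on)) {
      img[, , 3] <- add_spots(img[, , 3], cx[red_on], cy[red_on],
                              cells$dsred[red_on], s_px)
    }
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
    img[img < 0] <- 0
  }
  structure(list(image = img, truth = cells, geometry = geometry),
            class = "synthetic_section")
}

#' Render a synthetic amyloid-plaque section
#'
#' Plants `Poisson(density x fov_area)` uniform-intensity disks in a single
#' channel over background. Each plaque's diameter is lognormal and its
#' intensity Gaussian around the section's mean level. Centers are sampled
#' inside the field of view inset by the plaque's own radius, with a
#' minimum separation so that plaques remain spatially distinct objects.
#'
#' @param density Plaques per square millimeter (>= 0).
#' @param size_distribution List `(meanlog, sdlog)` of the lognormal plaque
#'   diameter in micrometers.
#' @param intensity List `(mean, sd)` of the per-plaque mean gray value
#'   (arbitrary units).
#' @param fov Field-of-view width and height, micrometers.
#' @param pixel_size Micrometers per pixel.
#' @param background Background gray level.
#' @param noise_sd Additive Gaussian noise SD.
#' @param min_gap Minimum edge-to-edge gap between plaques, micrometers.
#' @param seed Optional seed.
#' @return List of class `synthetic_section`: `image` (h x w matrix),
#'   `truth` (data frame `x`, `y`, `radius`, `intensity`), `fov_area_mm2`.
#' @export
render_plaque_section <- function(density,
                                  size_distribution = list(meanlog = log(12) - 0.246^2 / 2,
                                                           sdlog = 0.246),
                                  intensity = list(mean = 1200, sd = 80),
                                  fov = c(width = 250, height = 200),
                                  pixel_size = 0.65, background = 150,
                                  noise_sd = 0, min_gap = 2, seed = NULL) {
  stopifnot(density >= 0, fov[1] > 0, fov[2] > 0)
  if (!is.null(seed)) set.seed(seed)
  area_mm2 <- fov[1] * fov[2] / 1e6
  n <- stats::rpois(1, density * area_mm2)
  radius <- sort(stats::rlnorm(n, size_distribution$meanlog,
                               size_distribution$sdlog) / 2, decreasing = TRUE)
  inten <- stats::rnorm(n, intensity$mean, intensity$sd)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      x <- stats::runif(1, radius[i], fov[1] - radius[i])
      y <- stats::runif(1, radius[i], fov[2] - radius[i])
      if (!length(xs) ||
          all(sqrt((xs - x)^2 + (ys - y)^2) >= radius[seq_along(xs)] + radius[i] + min_gap)) {
        placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place plaque ", i, " without overlap; lower the density")
    xs <- c(xs, x); ys <- c(ys, y)
  }
  w <- unname(ceiling(fov[1] / pixel_size))
  h <- unname(ceiling(fov[2] / pixel_size))
  img <- matrix(background, h, w)
  if (n > 0) {
    px <- um_to_px(xs, 0, pixel_size); py <- um_to_px(ys, 0, pixel_size)
    rp <- radius / pixel_size
    for (i in seq_len(n)) {
      c0 <- max(1, floor(px[i] - rp[i])); c1 <- min(w, ceiling(px[i] + rp[i]))
      r0 <- max(1, floor(py[i] - rp[i])); r1 <- min(h, ceiling(py[i] + rp[i]))
      cc <- c0:c1; rr <- r0:r1
      d2 <- outer((rr - py[i])^2, (cc - px[i])^2, "+")
      blk <- img[rr, cc]
      blk[d2 <= rp[i]^2] <- inten[i]
      img[rr, cc] <- blk
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), h, w)
    img[img < 0] <- 0
  }
  truth <- data.frame(x = xs, y = ys, radius = radius[seq_len(n)],
                      intensity = inten[seq_len(n)])
  structure(list(image = img, truth = truth, pixel_size = pixel_size,
                 fov_area_mm2 = unname(area_mm2)),
            class = "synthetic_section")
}

#' Write / read a multi-channel section as 16-bit multi-page TIFF
#'
#' Channels are stored as pages in fixed order (DAPI, GFP, DsRed), scaled
#' by 1/65535; a truth sidecar CSV is written next to the image when the
#' section carries planted ground truth.
#'
#' @param section A `synthetic_section` (or plain matrix/array in AU).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(section, path) {
  img <- if (inherits(section, "synthetic_section")) section$image else section
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1))
  pages <- lapply(seq_len(dim(img)[3]), function(k) {
    m <- img[, , k] / 65535
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (inherits(section, "synthetic_section") && is.data.frame(section$truth) &&
      nrow(section$truth)) {
    utils::write.csv(section$truth, sub("\\.tiff?$", "_truth.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_section_tiff
#' @export
read_section_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 65535
  arr
}
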