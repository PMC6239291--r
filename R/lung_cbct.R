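#' Density volumes
#'
#' A `density_volume` is a 3-D grid of mass densities in g/cm^3 with voxel
#' spacing in mm. Axis order is `(slice, row, col)` with 0-based voxel
#' indices; world position = index * spacing.
#'
#' @param values 3-D numeric array of densities (g/cm^3, all `>= 0`).
#' @param spacing_mm Length-3 positive numeric, voxel spacing in mm per
#'   axis.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(values, spacing_mm) {
  if (length(dim(values)) != 3L) stop_bad_input("values must be a 3-D array")
  if (any(values < 0)) stop_bad_input("densities must be non-negative")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop_bad_input("spacing must be strictly positive")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_volume> %dx%dx%d voxels @ %.3gx%.3gx%.3g mm, range %.3f-%.3f g/cm3\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Hounsfield-unit calibration
#'
#' Two-point linear calibration mapping HU to mass density through the
#' air and water anchors.
#'
#' @param hu_air,hu_water HU anchor values (defaults -1000 and 0).
#' @param density_air,density_water Densities at the anchors in g/cm^3
#'   (defaults 0 and 1).
#' @return A `hu_calibration` list.
#' @export
hu_calibration <- function(hu_air = -1000, hu_water = 0,
                           density_air = 0, density_water = 1) {
  if (hu_air >= hu_water) stop_bad_input("hu_air must be below hu_water")
  if (density_air >= density_water)
    stop_bad_input("density_air must be below density_water")
  structure(list(hu_air = hu_air, hu_water = hu_water,
                 density_air = density_air, density_water = density_water),
            class = "hu_calibration")
}

#' Convert a HU volume to mass density
#'
#' Linear map through the `(hu_air, density_air)` and
#' `(hu_water, density_water)` anchor points, clipped at zero.
#'
#' @param values 3-D array of HU values.
#' @param spacing_mm Voxel spacing in mm.
#' @param cal A [hu_calibration()].
#' @return A [density_volume()].
#' @export
hu_to_density <- function(values, spacing_mm, cal = hu_calibration()) {
  slope <- (cal$density_water - cal$density_air) / (cal$hu_water - cal$hu_air)
  dens <- cal$density_air + (values - cal$hu_air) * slope
  density_volume(pmax(dens, 0), spacing_mm)
}

# Fill in-plane holes of a boolean volume slice by slice: background
# components (4-connected) not touching the slice border are holes.
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (s in seq_len(d[1])) {
    sl <- mask[s, , ]
    bg <- !sl
    if (!any(bg) || !any(sl)) next
    lab <- .cpp_label_components(as.logical(bg), dim(sl), 4L)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0]
    hole <- bg & !(lab %in% border)
    if (any(hole)) mask[s, , ][hole] <- TRUE
  }
  mask
}

# Keep the `n` largest connected components (26-connectivity).
keep_largest_components <- function(mask, n = 2L) {
  lab <- .cpp_label_components(as.logical(mask), dim(mask), 26L)
  if (max(lab) <= n) return(mask)
  sizes <- tabulate(lab)
  keep <- order(sizes, decreasing = TRUE)[seq_len(n)]
  out <- array(lab %in% keep, dim(mask))
  out
}

#' Body mask from a density volume
#'
#' The animal's body is taken as the largest 26-connected component of
#' voxels at soft-tissue density or above, with in-plane holes (the lungs
#' and airways) filled slice-wise. This separates the animal from the
#' surrounding air without manual input.
#'
#' @param vol A [density_volume()].
#' @param threshold Soft-tissue density threshold in g/cm^3 (default 0.9).
#' @return A logical array congruent with `vol$values`.
#' @export
body_mask <- function(vol, threshold = 0.9) {
  m <- vol$values >= threshold
  if (!any(m)) return(array(FALSE, dim(vol$values)))
  m <- keep_largest_components(m, 1L)
  fill_holes_slicewise(m)
}

#' Segment healthy lung by density thresholding
#'
#' Healthy lung tissue is the set of voxels with density in `[lo, hi)`
#' g/cm^3 inside the body mask (excluding outside air), cleaned
#' morphologically: in-plane holes are filled slice-wise and at most the
#' two largest 26-connected components (the two lungs) are kept.
#'
#' @param vol A [density_volume()].
#' @param body Logical body mask congruent with `vol`; computed with
#'   [body_mask()] when `NULL`.
#' @param lo,hi Density window in g/cm^3; the interval is half-open
#'   `[lo, hi)` (default 0 to 0.7).
#' @return A logical lung mask; empty (with a warning) when no voxel
#'   qualifies.
#' @export
segment_healthy_lung <- function(vol, body = NULL, lo = 0, hi = 0.7) {
  if (!inherits(vol, "density_volume")) stop_bad_input("vol must be a density_volume")
  if (is.null(body)) body <- body_mask(vol)
  if (!identical(dim(body), dim(vol$values)))
    stop_bad_input("body mask is not congruent with the volume")
  m <- vol$values >= lo & vol$values < hi & body
  if (!any(m)) {
    warning("healthy-lung segmentation is empty")
    return(array(FALSE, dim(vol$values)))
  }
  m <- fill_holes_slicewise(m)
  keep_largest_components(m, 2L)
}

#' Volume of a mask in cubic centimetres
#'
#' @param mask Logical array.
#' @param spacing_mm Voxel spacing in mm (length 3).
#' @return Voxel count times voxel volume, in cm^3.
#' @export
compute_volume <- function(mask, spacing_mm) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  sum(mask) * prod(spacing_mm) / 1000
}

#' Region-of-interest boxes for lung densitometry
#'
#' `roi_box()` describes one in-plane square ROI by fractional coordinates
#' `(slice, row, col)` of the lung-mask bounding box. `default_roi_spec()`
#' returns the seven-ROI protocol: four 1.5 mm boxes in the lung apex and
#' three 2.4 mm boxes in the base, anchored to the bounding box so that
#' the same positions are measured at every timepoint.
#'
#' @param label ROI label.
#' @param center Length-3 fractional coordinates in `[0, 1]`.
#' @param size_mm In-plane square edge in mm.
#' @param region `"apex"` or `"base"`.
#' @return A `roi_box` list / list of seven `roi_box`es.
#' @export
roi_box <- function(label, center, size_mm, region = c("apex", "base")) {
  region <- match.arg(region)
  if (any(center < 0 | center > 1))
    stop_bad_input("fractional coordinates must be in [0, 1]")
  assert_scalar_pos(size_mm, "size_mm")
  structure(list(label = label, center = center, size_mm = size_mm,
                 region = region), class = "roi_box")
}

#' @rdname roi_box
#' @export
default_roi_spec <- function() {
  list(
    roi_box("apex_1", c(0.20, 0.35, 0.23), 1.5, "apex"),
    roi_box("apex_2", c(0.20, 0.35, 0.77), 1.5, "apex"),
    roi_box("apex_3", c(0.20, 0.65, 0.23), 1.5, "apex"),
    roi_box("apex_4", c(0.20, 0.65, 0.77), 1.5, "apex"),
    roi_box("base_1", c(0.75, 0.50, 0.23), 2.4, "base"),
    roi_box("base_2", c(0.75, 0.50, 0.77), 2.4, "base"),
    roi_box("base_3", c(0.65, 0.50, 0.23), 2.4, "base"))
}

#' Place ROI boxes on a lung mask
#'
#' Each ROI is centred at its fractional coordinates of the lung-mask
#' bounding box, as an in-plane square of `size_mm` on the nearest axial
#' slice. Placement is deterministic for a given mask and equivariant
#' under whole-voxel translations of the mask.
#'
#' @param mask Logical lung mask.
#' @param spacing_mm Voxel spacing in mm.
#' @param spec List of [roi_box()]es (default [default_roi_spec()]).
#' @return A data frame with one row per ROI: `label`, `region`, `slice`,
#'   `row0`, `row1`, `col0`, `col1` (1-based voxel bounds) and `clipped`.
#' @export
place_rois <- function(mask, spacing_mm, spec = default_roi_spec()) {
  if (!any(mask)) stop_bad_input("cannot place ROIs on an empty mask")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  d <- dim(mask)
  out <- lapply(spec, function(b) {
    ctr <- lo + b$center * (hi - lo)
    sl <- round(ctr[1])
    edge_r <- max(1L, round(b$size_mm / spacing_mm[2]))
    edge_c <- max(1L, round(b$size_mm / spacing_mm[3]))
    r0 <- round(ctr[2]) - (edge_r - 1L) %/% 2L; r1 <- r0 + edge_r - 1L
    c0 <- round(ctr[3]) - (edge_c - 1L) %/% 2L; c1 <- c0 + edge_c - 1L
    clipped <- r0 < 1 || c0 < 1 || r1 > d[2] || c1 > d[3] || sl < 1 || sl > d[1]
    if (clipped)
      warning(sprintf("ROI %s extends outside the volume; clipping", b$label))
    data.frame(label = b$label, region = b$region,
               slice = min(max(sl, 1L), d[1]),
               row0 = max(r0, 1L), row1 = min(r1, d[2]),
               col0 = max(c0, 1L), col1 = min(c1, d[3]),
               clipped = clipped, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Measure lung density in placed ROIs
#'
#' @param vol A [density_volume()].
#' @param rois ROI table from [place_rois()].
#' @return A `lung_metrics` list: `roi_densities` (named per-ROI mean
#'   densities, g/cm^3) and `mean_density` (their unweighted mean).
#' @export
measure_density <- function(vol, rois) {
  dens <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    if (r$row1 < r$row0 || r$col1 < r$col0)
      stop_bad_input("ROI ", r$label, " is empty after clipping")
    mean(vol$values[r$slice, r$row0:r$row1, r$col0:r$col1])
  }, 0)
  names(dens) <- rois$label
  structure(list(roi_densities = dens, mean_density = mean(dens)),
            class = "lung_metrics")
}

#' Full lung metrics from a density volume
#'
#' Runs segmentation, volume computation, ROI placement and densitometry.
#'
#' @param vol A [density_volume()].
#' @param lo,hi Healthy-density window (g/cm^3).
#' @param spec ROI specification (default the seven-ROI protocol).
#' @return A list: `healthy_volume_cm3`, `roi_densities`, `mean_density`,
#'   `mask`, `rois`.
#' @export
lung_metrics <- function(vol, lo = 0, hi = 0.7, spec = default_roi_spec()) {
  mask <- segment_healthy_lung(vol, lo = lo, hi = hi)
  vol_cm3 <- compute_volume(mask, vol$spacing_mm)
  if (!any(mask))
    return(list(healthy_volume_cm3 = 0, roi_densities = NULL,
                mean_density = NA_real_, mask = mask, rois = NULL))
  rois <- place_rois(mask, vol$spacing_mm, spec)
  md <- measure_density(vol, rois)
  list(healthy_volume_cm3 = vol_cm3, roi_densities = md$roi_densities,
       mean_density = md$mean_density, mask = mask, rois = rois)
}

# Volume fraction of an ellipsoid below the axial plane u in [-1, 1]
# (u = z/c): used to cut injury caps of an exact volume fraction.
ellipsoid_cap_fraction <- function(u) ((u + 1)^2 * (2 - u)) / 4

#' Generate a two-lung digital phantom
#'
#' Builds a body ellipsoid at soft-tissue density containing two lung
#' ellipsoids, optionally with Gaussian density texture and an "injury":
#' a cap of a given volume fraction of a lung raised to an injured
#' density (emulating consolidation). Returns the analytic ground truth
#' alongside the voxelized volume.
#'
#' @param spacing_mm Isotropic voxel spacing in mm (default 0.2).
#' @param lung_semiaxes_mm Length-3 semi-axes (slice, row, col) of each
#'   lung ellipsoid in mm; the default `c(8, 3, 3)` gives 0.302 cm^3 per
#'   lung.
#' @param body_semiaxes_mm Semi-axes of the body ellipsoid in mm.
#' @param lung_offset_mm Lateral (col-axis) offset of each lung centre
#'   from the body centre, mm.
#' @param lung_density,body_density,air_density Densities in g/cm^3.
#' @param injury `NULL`, or a list with `fraction` (volume fraction of the
#'   affected lung, from its caudal end), `lung` (1 or 2) and `density`
#'   (injured density, g/cm^3).
#' @param noise_sd Gaussian density texture SD in g/cm^3.
#' @param margin_mm Air margin around the body.
#' @param seed Integer seed (texture only).
#' @return A list: `volume` (a [density_volume()]), and `truth` with the
#'   analytic `healthy_volume_cm3`, `total_lung_volume_cm3`, per-lung
#'   membership predicates and the injury cut plane.
#' @export
make_phantom <- function(spacing_mm = 0.2,
                         lung_semiaxes_mm = c(8, 3, 3),
                         body_semiaxes_mm = c(10.5, 7, 8.5),
                         lung_offset_mm = 3.6,
                         lung_density = 0.474, body_density = 1.06,
                         air_density = 0, injury = NULL, noise_sd = 0,
                         margin_mm = 1.2, seed = 1L) {
  if (lung_offset_mm - lung_semiaxes_mm[3] < 0)
    stop_bad_input("lung ellipsoids overlap")
  if (any(lung_semiaxes_mm >= body_semiaxes_mm - c(0, 0, 0)) &&
      (lung_semiaxes_mm[1] >= body_semiaxes_mm[1] ||
       lung_semiaxes_mm[2] >= body_semiaxes_mm[2] ||
       lung_offset_mm + lung_semiaxes_mm[3] >= body_semiaxes_mm[3]))
    stop_bad_input("lungs do not fit inside the body ellipsoid")
  set.seed(seed)
  ext <- body_semiaxes_mm + margin_mm
  d <- as.integer(ceiling(2 * ext / spacing_mm)) + 1L
  ctr <- (d + 1) / 2
  # voxel-centre world coordinates relative to the body centre
  zs <- (seq_len(d[1]) - ctr[1]) * spacing_mm
  ys <- (seq_len(d[2]) - ctr[2]) * spacing_mm
  xs <- (seq_len(d[3]) - ctr[3]) * spacing_mm
  z2 <- (zs / body_semiaxes_mm[1])^2
  y2 <- (ys / body_semiaxes_mm[2])^2
  x2 <- (xs / body_semiaxes_mm[3])^2
  body <- outer(outer(z2, y2, `+`), x2, `+`) <= 1

  lung_member <- function(xc) {
    lz <- (zs / lung_semiaxes_mm[1])^2
    ly <- (ys / lung_semiaxes_mm[2])^2
    lx <- ((xs - xc) / lung_semiaxes_mm[3])^2
    outer(outer(lz, ly, `+`), lx, `+`) <= 1
  }
  lungs <- list(lung_member(-lung_offset_mm), lung_member(lung_offset_mm))
  lung_density <- rep_len(lung_density, 2L)

  vol <- array(air_density, d)
  vol[body] <- body_density
  vol[lungs[[1]]] <- lung_density[1]
  vol[lungs[[2]]] <- lung_density[2]

  lung_vol_analytic <- 4 / 3 * pi * prod(lung_semiaxes_mm) / 1000
  healthy_analytic <- 2 * lung_vol_analytic
  cut_mm <- NULL
  if (!is.null(injury) && injury$fraction > 0) {
    if (injury$fraction > 1) stop_bad_input("injury fraction must be <= 1")
    u <- stats::uniroot(function(u) ellipsoid_cap_fraction(u) - injury$fraction,
                        c(-1, 1), tol = 1e-12)$root
    cut_mm <- u * lung_semiaxes_mm[1]
    inj <- lungs[[injury$lung]] &
      outer(outer(zs <= cut_mm, rep(TRUE, d[2]), `&`), rep(TRUE, d[3]), `&`)
    vol[inj] <- injury$density
    healthy_analytic <- healthy_analytic - injury$fraction * lung_vol_analytic
  }
  if (noise_sd > 0) vol <- pmax(vol + rnorm(length(vol), sd = noise_sd), 0)

  list(volume = density_volume(vol, spacing_mm),
       truth = list(healthy_volume_cm3 = healthy_analytic,
                    total_lung_volume_cm3 = 2 * lung_vol_analytic,
                    lung_masks = lungs, body_mask = body,
                    injury_cut_mm = cut_mm))
}
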