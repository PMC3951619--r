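# DXA densitometry: elliptical-cylinder volumetric BMD from dual-projection scans.
#
# The scanner reports, per projection (AP and lateral), a bone width, a
# projected bone area, BMC and areal BMD over an operator-placed ROI whose
# height spans the regenerate. The regenerate is modelled as an elliptical
# cylinder with semi-axes AP width / 2 and lateral width / 2 and height equal
# to the ROI height; volumetric BMD is BMC over that volume. All lengths are
# in cm, areas cm^2, volumes cm^3, masses g.

#' Cross-sectional area of an elliptical bone section
#'
#' Models the regenerate cross-section as an ellipse whose full diameters are
#' the bone widths measured on the anterior-posterior (AP) and lateral (LAT)
#' DXA scans: area = pi * (AP/2) * (LAT/2).
#'
#' @param ap_width Bone width from the AP scan (cm, full diameter).
#' @param lat_width Bone width from the lateral scan (cm, full diameter).
#' @return Cross-sectional area in cm^2. Vectorised over both arguments.
#' @examples
#' elliptical_cross_section(1, 1)  # circle: pi/4
#' @export
elliptical_cross_section <- function(ap_width, lat_width) {
  assert_positive(ap_width, "ap_width")
  assert_positive(lat_width, "lat_width")
  pi * (ap_width / 2) * (lat_width / 2)
}

#' Regenerate volume as an elliptical cylinder
#'
#' @param cross_section_area Elliptical cross-section area (cm^2).
#' @param roi_height Height of the scan region of interest (cm); the ROI is
#'   placed so the whole regenerate column is included.
#' @return Volume in cm^3.
#' @export
regenerate_volume <- function(cross_section_area, roi_height) {
  assert_positive(cross_section_area, "cross_section_area")
  assert_positive(roi_height, "roi_height")
  cross_section_area * roi_height
}

#' Volumetric bone mineral density
#'
#' @param bmc Bone mineral content (g); may be zero.
#' @param volume Regenerate volume (cm^3); must be positive.
#' @return vBMD in g/cm^3.
#' @export
volumetric_bmd <- function(bmc, volume) {
  if (any(!is.finite(bmc)) || any(bmc < 0)) {
    stop("`bmc` must be finite and non-negative", call. = FALSE)
  }
  assert_positive(volume, "volume")
  bmc / volume
}

#' Average a quantity over the AP and lateral projections
#'
#' The two scans image one physical regenerate, so per-projection BMC, BMD and
#' vBMD are summarised by their arithmetic mean.
#'
#' @param ap_value,lat_value Per-projection values.
#' @return The arithmetic mean.
#' @export
average_projections <- function(ap_value, lat_value) {
  (ap_value + lat_value) / 2
}

#' Build a single DXA projection record
#'
#' @param specimen_id Specimen identifier.
#' @param projection `"AP"` or `"LAT"`.
#' @param bone_width Bone width (cm).
#' @param bone_area Projected bone area reported by the scanner (cm^2); carried
#'   through but not used by the elliptical model.
#' @param bmc Bone mineral content (g).
#' @param bmd Areal bone mineral density (g/cm^2).
#' @param roi_height ROI height (cm).
#' @return A one-row tibble.
#' @export
dxa_projection <- function(specimen_id, projection, bone_width, bone_area,
                           bmc, bmd, roi_height) {
  projection <- match.arg(toupper(projection), c("AP", "LAT"))
  for (f in c("bone_width", "bone_area", "bmc", "bmd", "roi_height")) {
    assert_positive(get(f), f)
  }
  fast_tbl(
    specimen_id = as.character(specimen_id), projection = projection,
    bone_width = bone_width, bone_area = bone_area,
    bmc = bmc, bmd = bmd, roi_height = roi_height
  )
}

#' Derive geometry, volume and volumetric BMD for one specimen
#'
#' Combines the AP and lateral projection records of one specimen: the
#' elliptical cross-section uses both widths; the volume uses the AP scan's
#' ROI height (the two heights must agree within `roi_tolerance`, since a
#' single physical regenerate was scanned twice); per-projection vBMD divides
#' each projection's own BMC by the one shared volume; BMC, BMD and vBMD are
#' then averaged across projections.
#'
#' @param ap,lat One-row data frames as returned by [dxa_projection()], with
#'   projections `"AP"` and `"LAT"` in either argument order.
#' @param roi_tolerance Maximum allowed relative discrepancy between the two
#'   ROI heights (default 0.05); a larger discrepancy signals inconsistent ROI
#'   box placement and is an error.
#' @return A one-row tibble with `specimen_id`, `cross_section_area`,
#'   `volume`, `vbmd_ap`, `vbmd_lat`, `bmc_mean`, `bmd_mean`, `vbmd_mean`.
#' @export
derive_specimen <- function(ap, lat, roi_tolerance = 0.05) {
  ap <- as.data.frame(ap)
  lat <- as.data.frame(lat)
  if (identical(ap$projection, "LAT") && identical(lat$projection, "AP")) {
    tmp <- ap; ap <- lat; lat <- tmp
  }
  if (!identical(ap$projection, "AP") || !identical(lat$projection, "LAT")) {
    stop("need exactly one AP and one LAT projection record", call. = FALSE)
  }
  if (!identical(ap$specimen_id, lat$specimen_id)) {
    stop(sprintf("specimen_id mismatch: '%s' (AP) vs '%s' (LAT)",
                 ap$specimen_id, lat$specimen_id), call. = FALSE)
  }
  rel <- abs(ap$roi_height - lat$roi_height) /
    max(ap$roi_height, lat$roi_height)
  if (rel > roi_tolerance) {
    stop(sprintf(
      "ROI heights differ by %.1f%% (> %.1f%% tolerance) for specimen '%s': inconsistent ROI placement",
      100 * rel, 100 * roi_tolerance, ap$specimen_id), call. = FALSE)
  }
  area <- elliptical_cross_section(ap$bone_width, lat$bone_width)
  vol <- regenerate_volume(area, ap$roi_height)
  vbmd_ap <- volumetric_bmd(ap$bmc, vol)
  vbmd_lat <- volumetric_bmd(lat$bmc, vol)
  fast_tbl(
    specimen_id = ap$specimen_id,
    cross_section_area = area,
    volume = vol,
    vbmd_ap = vbmd_ap,
    vbmd_lat = vbmd_lat,
    bmc_mean = average_projections(ap$bmc, lat$bmc),
    bmd_mean = average_projections(ap$bmd, lat$bmd),
    vbmd_mean = average_projections(vbmd_ap, vbmd_lat)
  )
}

#' Derive per-specimen DXA summaries for a whole measurement table
#'
#' @param measurements Data frame with one row per specimen per projection and
#'   columns `specimen_id`, `projection`, `bone_width`, `bone_area`, `bmc`,
#'   `bmd`, `roi_height` (see [read_dxa_measurements()] for the CSV schema).
#' @param roi_tolerance Passed to [derive_specimen()].
#' @return A tibble with one row per specimen.
#' @export
derive_dxa <- function(measurements, roi_tolerance = 0.05) {
  measurements <- as.data.frame(measurements)
  out <- lapply(split(measurements, measurements$specimen_id), function(m) {
    if (nrow(m) != 2L) {
      stop(sprintf("specimen '%s' has %d projection rows; expected 2 (AP, LAT)",
                   m$specimen_id[1], nrow(m)), call. = FALSE)
    }
    derive_specimen(m[m$projection == "AP", , drop = FALSE],
                    m[m$projection == "LAT", , drop = FALSE],
                    roi_tolerance = roi_tolerance)
  })
  res <- do.call(rbind, out)
  res[order(match(res$specimen_id, unique(measurements$specimen_id))), ]
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

# cheap tibble construction for hot paths (skips tibble()'s quoting machinery)
fast_tbl <- function(...) {
  l <- list(...)
  n <- max(lengths(l))
  short <- lengths(l) != n
  l[short] <- lapply(l[short], rep_len, n)
  tibble::new_tibble(l, nrow = n)
}
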