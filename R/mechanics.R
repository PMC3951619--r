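# Compression mechanics: stress-strain transformation and parameter extraction.
#
# Load-displacement records from compression-to-failure tests are converted to
# engineering stress-strain using the DXA-derived mean cross-sectional area
# (stress, MPa) and the exposed bone length lo (strain, mm/mm). From each
# curve the modulus of elasticity, 0.2 % offset yield point, ultimate failure
# point and strain-energy densities are extracted. Curves are treated as
# piecewise linear between the recorded samples; abscissae need not be
# uniformly spaced.

#' Transform a load-displacement record to engineering stress-strain
#'
#' @param displacement_mm Crosshead displacements (mm), non-negative and
#'   non-decreasing.
#' @param load_n Loads (N), same length as `displacement_mm`.
#' @param exposed_length_lo_mm Exposed bone length lo between the mounting
#'   blocks (mm); divisor converting displacement to strain.
#' @param cross_section_area_cm2 DXA-derived mean cross-sectional area (cm^2);
#'   converted internally to mm^2 so stress is N/mm^2 = MPa.
#' @return A tibble with columns `strain` (mm/mm) and `stress` (MPa) in the
#'   input order.
#' @export
to_stress_strain <- function(displacement_mm, load_n, exposed_length_lo_mm,
                             cross_section_area_cm2) {
  assert_positive(exposed_length_lo_mm, "exposed_length_lo_mm")
  assert_positive(cross_section_area_cm2, "cross_section_area_cm2")
  if (any(!is.finite(displacement_mm)) || any(displacement_mm < 0)) {
    stop("`displacement_mm` must be finite and non-negative", call. = FALSE)
  }
  if (is.unsorted(displacement_mm)) {
    stop("`displacement_mm` must be non-decreasing", call. = FALSE)
  }
  if (length(load_n) != length(displacement_mm)) {
    stop("`load_n` and `displacement_mm` lengths differ", call. = FALSE)
  }
  area_mm2 <- cross_section_area_cm2 * 100
  fast_tbl(
    strain = displacement_mm / exposed_length_lo_mm,
    stress = load_n / area_mm2
  )
}

#' Modulus of elasticity by maximum moving-window regression slope
#'
#' Slides a strain window covering `window_fraction` of the pre-ultimate
#' strain range along the curve, fits a least-squares line in every window
#' with at least three samples, and reports the maximum slope. The maximum-
#' slope rule makes the estimate robust to a compliant toe region without a
#' manually chosen fit interval.
#'
#' @param ss Stress-strain data frame with columns `strain` and `stress`
#'   (MPa), as from [to_stress_strain()].
#' @param window_fraction Window width as a fraction of the pre-ultimate
#'   strain range, in (0, 0.5]; default 0.2.
#' @return A list with `modulus` (GPa), `window` (the winning window's strain
#'   interval) and `n_window` (samples in it).
#' @export
fit_modulus <- function(ss, window_fraction = 0.2) {
  strain <- ss$strain
  stress <- ss$stress
  if (length(strain) < 10L) {
    stop("need at least 10 stress-strain samples to fit a modulus",
         call. = FALSE)
  }
  if (window_fraction <= 0 || window_fraction > 0.5) {
    stop("`window_fraction` must be in (0, 0.5]", call. = FALSE)
  }
  peak <- which.max(stress)
  strain <- strain[seq_len(peak)]
  stress <- stress[seq_len(peak)]
  rng <- strain[length(strain)] - strain[1]
  if (rng <= 0) stop("degenerate curve: zero strain range", call. = FALSE)
  w <- window_fraction * rng

  # O(n) sliding windows via cumulative sums
  n <- length(strain)
  cx <- cumsum(strain); cy <- cumsum(stress)
  cxx <- cumsum(strain^2); cxy <- cumsum(strain * stress)
  # full-width windows only: windows clipped at the peak hold few, closely
  # spaced samples whose regression slope is numerically unstable
  lo <- which(strain <= strain[n] - w + 1e-12 * rng)
  hi <- findInterval(strain[lo] + w * (1 + 1e-12), strain)
  keep <- hi - lo + 1L >= 3L
  if (!any(keep)) {
    stop("window too narrow: no window holds 3 samples", call. = FALSE)
  }
  lo <- lo[keep]; hi <- hi[keep]
  m <- hi - lo + 1
  sx <- cx[hi] - cx[lo] + strain[lo]
  sy <- cy[hi] - cy[lo] + stress[lo]
  sxx <- cxx[hi] - cxx[lo] + strain[lo]^2
  sxy <- cxy[hi] - cxy[lo] + strain[lo] * stress[lo]
  denom <- m * sxx - sx^2
  ok <- denom > .Machine$double.eps * m * sxx
  if (!any(ok)) {
    stop("degenerate window: zero strain variance", call. = FALSE)
  }
  slope <- rep(-Inf, length(lo))
  slope[ok] <- (m[ok] * sxy[ok] - sx[ok] * sy[ok]) / denom[ok]
  best <- which.max(slope)
  list(
    modulus = slope[best] / 1000, # MPa -> GPa
    window = c(strain[lo[best]], strain[hi[best]]),
    n_window = m[best]
  )
}

#' Offset-rule yield point
#'
#' Intersects the piecewise-linear stress-strain curve with the offset line
#' sigma = E * (eps - offset); the conventional 0.2 % offset construction.
#' The search runs up to the ultimate (maximum-stress) sample and the first
#' crossing is interpolated linearly within its bracketing segment. A purely
#' elastic curve has no crossing: the specimen is then flagged as having no
#' detectable yield rather than raising an error, so it can be excluded from
#' yield-based statistics downstream.
#'
#' @param ss Stress-strain data frame (`strain`, `stress` in MPa).
#' @param modulus_gpa Modulus of elasticity (GPa), normally from
#'   [fit_modulus()].
#' @param offset Strain offset of the construction line; default 0.002.
#' @return A list with `yield_strain`, `yield_stress` (MPa) and logical
#'   `found`; the numeric fields are `NA` when no yield is detected.
#' @export
detect_yield <- function(ss, modulus_gpa, offset = 0.002) {
  strain <- ss$strain
  stress <- ss$stress
  assert_positive(modulus_gpa, "modulus_gpa")
  if (offset < 0) stop("`offset` must be non-negative", call. = FALSE)
  e_mpa <- modulus_gpa * 1000
  peak <- which.max(stress)
  strain <- strain[seq_len(peak)]
  stress <- stress[seq_len(peak)]
  diff_line <- stress - e_mpa * (strain - offset)
  tol <- 1e-9 * max(abs(stress), 1)
  n <- length(diff_line)
  # downward crossings of the offset line; the last one is the point after
  # which the curve stays below the line. On a noiseless curve with a
  # hardening slope below E there is a single crossing, so this coincides
  # with the first intersection; on noisy records it ignores transient early
  # crossings caused by modulus estimation error.
  cross <- which(diff_line[-1] < -tol & diff_line[-n] >= -tol) + 1L
  if (length(cross) == 0L) {
    return(list(yield_strain = NA_real_, yield_stress = NA_real_,
                found = FALSE))
  }
  i <- cross[length(cross)]
  j <- i - 1L
  da <- diff_line[j]; db <- diff_line[i]
  t <- if (da <= 0) 0 else da / (da - db)
  ys <- strain[j] + t * (strain[i] - strain[j])
  list(
    yield_strain = ys,
    yield_stress = stress[j] + t * (stress[i] - stress[j]),
    found = TRUE
  )
}

#' Ultimate failure point
#'
#' In compression the regenerate fails by collapse at peak load, so the
#' failure point is the sample of maximum stress; ties are broken toward the
#' smaller strain. An alternative rule, the first sample after which stress
#' drops by at least 10 % of the running maximum, is available for curves
#' with extended plateaus.
#'
#' @param ss Stress-strain data frame (`strain`, `stress` in MPa).
#' @param rule `"ultimate"` (default) or `"drop10"`.
#' @return A list with `failure_strain`, `failure_stress` and the sample
#'   `index`.
#' @export
detect_failure <- function(ss, rule = c("ultimate", "drop10")) {
  rule <- match.arg(rule)
  strain <- ss$strain
  stress <- ss$stress
  if (length(stress) == 0L) stop("empty stress-strain curve", call. = FALSE)
  idx <- which.max(stress) # first maximum; strains non-decreasing
  if (rule == "drop10") {
    runmax <- cummax(stress)
    dropped <- which(stress <= 0.9 * runmax & runmax > 0)
    if (length(dropped) > 0L) {
      # the failure point is the running maximum preceding the first drop
      idx <- which.max(stress[seq_len(dropped[1])])
    }
  }
  list(failure_strain = strain[idx], failure_stress = stress[idx],
       index = idx)
}

#' Strain-energy density up to a given strain
#'
#' Trapezoidal integral of stress over strain from 0 to `up_to_strain`; the
#' final partial interval is handled by linear interpolation, so the integral
#' is exact for piecewise-linear curves. MPa times strain is MJ/m^3.
#'
#' @param ss Stress-strain data frame (`strain`, `stress` in MPa).
#' @param up_to_strain Upper integration limit; must lie within the curve's
#'   strain range.
#' @return Energy density in MJ/m^3.
#' @export
strain_energy <- function(ss, up_to_strain) {
  strain <- ss$strain
  stress <- ss$stress
  if (up_to_strain < strain[1] || up_to_strain > strain[length(strain)]) {
    stop(sprintf("`up_to_strain` = %g outside the curve's strain range [%g, %g]",
                 up_to_strain, strain[1], strain[length(strain)]),
         call. = FALSE)
  }
  full <- which(strain <= up_to_strain)
  k <- full[length(full)]
  e <- 0
  if (k >= 2L) {
    e <- sum(diff(strain[1:k]) * (stress[1:(k - 1)] + stress[2:k]) / 2)
  }
  if (up_to_strain > strain[k] && k < length(strain)) {
    t <- (up_to_strain - strain[k]) / (strain[k + 1] - strain[k])
    s_end <- stress[k] + t * (stress[k + 1] - stress[k])
    e <- e + (up_to_strain - strain[k]) * (stress[k] + s_end) / 2
  }
  e
}

#' Extract all mechanical parameters for one specimen
#'
#' Runs the full chain: stress-strain transformation, modulus fit, offset
#' yield, failure point, and strain-energy densities at yield and failure.
#' Post-yield energy is the difference of the two energies. Specimens without
#' a detectable yield keep their failure-side fields and carry `NA` in the
#' yield-derived columns with `yield_found = FALSE`.
#'
#' @param curve Data frame with columns `displacement_mm` and `load_n`.
#' @param exposed_length_lo_mm Exposed bone length lo (mm).
#' @param cross_section_area_cm2 DXA-derived cross-sectional area (cm^2).
#' @param specimen_id Identifier copied into the output.
#' @param offset Yield offset strain (default 0.002).
#' @param window_fraction Modulus window fraction (default 0.2).
#' @param failure_rule Passed to [detect_failure()].
#' @return One-row tibble with `specimen_id`, `modulus` (GPa), `yield_strain`,
#'   `yield_stress` (MPa), `failure_strain`, `failure_stress` (MPa),
#'   `energy_yield`, `energy_failure`, `post_yield_energy` (MJ/m^3),
#'   `yield_found`, and the modulus window bounds.
#' @export
summarize_mechanics <- function(curve, exposed_length_lo_mm,
                                cross_section_area_cm2,
                                specimen_id = "specimen",
                                offset = 0.002, window_fraction = 0.2,
                                failure_rule = c("ultimate", "drop10")) {
  failure_rule <- match.arg(failure_rule)
  if (nrow(curve) < 10L) {
    stop(sprintf("specimen '%s': need at least 10 samples, got %d",
                 specimen_id, nrow(curve)), call. = FALSE)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("specimen '%s', stage %s: %s", specimen_id, what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  ss <- stage("stress-strain", to_stress_strain(
    curve$displacement_mm, curve$load_n,
    exposed_length_lo_mm, cross_section_area_cm2))
  modf <- stage("modulus", fit_modulus(ss, window_fraction))
  fail <- stage("failure", detect_failure(ss, failure_rule))
  yld <- stage("yield", detect_yield(ss, modf$modulus, offset))
  e_f <- stage("energy", strain_energy(ss, fail$failure_strain))
  e_y <- if (yld$found) {
    stage("energy", strain_energy(ss, yld$yield_strain))
  } else NA_real_
  fast_tbl(
    specimen_id = as.character(specimen_id),
    modulus = modf$modulus,
    yield_strain = yld$yield_strain,
    yield_stress = yld$yield_stress,
    failure_strain = fail$failure_strain,
    failure_stress = fail$failure_stress,
    energy_yield = e_y,
    energy_failure = e_f,
    post_yield_energy = e_f - e_y,
    yield_found = yld$found,
    modulus_window_lo = modf$window[1],
    modulus_window_hi = modf$window[2]
  )
}

#' Cohort summary table of mechanical (and optionally DXA) parameters
#'
#' Mean and sample standard deviation (n - 1 denominator) per parameter,
#' excluding missing values field-wise (specimens without a detected yield
#' contribute to failure-side rows only) and reporting the per-field n.
#' Fields with fewer than two available values are reported as unavailable
#' (`NA` mean and SD).
#'
#' @param mech Tibble of per-specimen rows from [summarize_mechanics()].
#' @param dxa Optional tibble from [derive_dxa()]; adds BMC, BMD and vBMD rows.
#' @return Tibble with columns `parameter`, `n`, `mean`, `sd`.
#' @export
cohort_table <- function(mech, dxa = NULL) {
  cols <- list(
    modulus = "E", yield_strain = "epsilon_y", yield_stress = "sigma_y",
    failure_strain = "epsilon_f", failure_stress = "sigma_f",
    energy_yield = "e_Y", energy_failure = "e_F",
    post_yield_energy = "post_yield_e"
  )
  rows <- list()
  if (!is.null(dxa)) {
    rows <- list(summary_row("BMC", dxa$bmc_mean),
                 summary_row("BMD", dxa$bmd_mean),
                 summary_row("vBMD", dxa$vbmd_mean))
  }
  order_mech <- c("modulus", "energy_yield", "yield_stress", "yield_strain",
                  "energy_failure", "failure_stress", "failure_strain",
                  "post_yield_energy")
  for (col in order_mech) {
    rows[[length(rows) + 1L]] <- summary_row(cols[[col]], mech[[col]])
  }
  do.call(rbind, rows)
}

summary_row <- function(label, x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) {
    return(fast_tbl(parameter = label, n = length(x),
                          mean = NA_real_, sd = NA_real_))
  }
  fast_tbl(parameter = label, n = length(x),
                 mean = mean(x), sd = stats::sd(x))
}
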