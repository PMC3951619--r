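# Synthetic cohort generator.
#
# Emulates a cohort of lengthened rabbit tibiae: per specimen a latent
# Gaussian copula ties volumetric BMD to the material parameters (modulus,
# yield stress, failure stress) at a configurable Spearman rank correlation,
# marginals are truncated normals at the published cohort moments, and the
# generator emits (a) dual-projection DXA measurement rows and (b) bilinear
# load-displacement compression curves, so the whole analysis pipeline can be
# exercised and its parameter recovery quantified against the known truth.

#' Configuration of the synthetic cohort
#'
#' Defaults are the cohort moments of the emulated study: DXA summary
#' statistics (vBMD 0.63 g/cm^3, SD 0.09; regenerate area 0.61 cm^2, SD 0.21;
#' lengthening 0.71 cm, SD 0.12) and mechanical parameters (E 0.55 GPa, SD
#' 0.235; yield stress 17.1 MPa, SD 4.55; failure stress 19.2 MPa; failure
#' strain 0.05), with a target Spearman rank correlation of 0.5 between vBMD
#' and each of modulus, yield stress and failure stress, and rank correlation
#' 0 between vBMD and the strains.
#'
#' Failure parameters are generated as yield plus a strictly positive
#' increment, so failure >= yield holds by construction and the target rank
#' correlations are not distorted by rejection. Yield strain is implied by the
#' elastic model (epsilon_y = sigma_y / E); `yield_strain_mean` is used only
#' to check configuration feasibility (`failure_strain_mean` must exceed it).
#'
#' @param n_specimens Number of specimens (default 41).
#' @param seed Integer RNG seed used by [generate_cohort()].
#' @param vbmd_mean,vbmd_sd Volumetric BMD moments (g/cm^3).
#' @param modulus_mean,modulus_sd Modulus moments (GPa).
#' @param yield_stress_mean,yield_stress_sd Yield stress moments (MPa).
#' @param yield_strain_mean Nominal yield strain (feasibility check only).
#' @param failure_stress_mean Failure stress mean (MPa); the mean stress
#'   increment beyond yield is `failure_stress_mean - yield_stress_mean`.
#' @param failure_strain_mean Failure strain mean; the mean strain increment
#'   beyond the implied yield strain is `failure_strain_mean -
#'   yield_stress_mean / (1000 * modulus_mean)`.
#' @param rho_vbmd_mech Target Spearman correlation between vBMD and each of
#'   modulus, yield stress and failure stress; |rho| < 1 (default 0.5).
#' @param roi_height_mean,roi_height_sd Regenerate (ROI) height moments (cm).
#' @param area_mean,area_sd Elliptical cross-section area moments (cm^2).
#' @param measurement_noise_cv Coefficient of variation of the multiplicative
#'   measurement noise applied to BMC and to curve loads (default 0.02,
#'   typical DXA precision).
#' @param samples_per_curve Samples per load-displacement record (default 100,
#'   about 10 Hz logging over a test lasting tens of seconds).
#' @param yield_missing_rate Fraction of specimens emitted with a purely
#'   elastic (no-yield) curve, mimicking records on which a yield point cannot
#'   be identified (default 0).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_specimens = 41, seed = 1,
                          vbmd_mean = 0.63, vbmd_sd = 0.09,
                          modulus_mean = 0.55, modulus_sd = 0.235,
                          yield_stress_mean = 17.1, yield_stress_sd = 4.55,
                          yield_strain_mean = 0.04,
                          failure_stress_mean = 19.2,
                          failure_strain_mean = 0.05,
                          rho_vbmd_mech = 0.5,
                          roi_height_mean = 0.71, roi_height_sd = 0.12,
                          area_mean = 0.61, area_sd = 0.21,
                          measurement_noise_cv = 0.02,
                          samples_per_curve = 100,
                          yield_missing_rate = 0) {
  cfg <- as.list(environment())
  sds <- c(vbmd_sd, modulus_sd, yield_stress_sd, roi_height_sd, area_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (abs(rho_vbmd_mech) >= 1) stop("|rho_vbmd_mech| must be < 1",
                                    call. = FALSE)
  if (n_specimens < 2) stop("need at least 2 specimens", call. = FALSE)
  if (failure_stress_mean < yield_stress_mean) {
    stop("infeasible config: failure_stress_mean < yield_stress_mean",
         call. = FALSE)
  }
  implied_ey <- yield_stress_mean / (1000 * modulus_mean)
  if (failure_strain_mean <= implied_ey) {
    stop(sprintf(
      "infeasible config: failure_strain_mean (%g) must exceed the implied mean yield strain sigma_y/E = %g",
      failure_strain_mean, implied_ey), call. = FALSE)
  }
  if (samples_per_curve < 10) stop("samples_per_curve must be >= 10",
                                   call. = FALSE)
  if (yield_missing_rate < 0 || yield_missing_rate >= 1) {
    stop("yield_missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Spearman rank correlation -> Pearson parameter of the Gaussian copula
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Quantile map from a standard normal score to a normal marginal truncated at
# +/- 3 SD (lower bound clipped away from zero for positive quantities).
truncnorm_from_z <- function(z, mean, sd, positive = TRUE) {
  if (sd == 0) return(rep(mean, length(z)))
  lower <- mean - 3 * sd
  if (positive) lower <- max(lower, 0.05 * mean)
  upper <- mean + 3 * sd
  a <- stats::pnorm((lower - mean) / sd)
  b <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(a + stats::pnorm(z) * (b - a))
}

#' Generate a synthetic cohort
#'
#' Draws per-specimen latent Gaussian scores with a copula correlation
#' targeting `rho_vbmd_mech` (on the Spearman scale, converted via
#' 2 sin(pi rho / 6)) between vBMD and each of modulus, yield stress and the
#' yield-side component of failure stress; maps them to truncated-normal
#' marginals; derives geometry (elliptical section with fixed AP/LAT aspect
#' ratio 1.2, ROI height) and builds, per specimen, two DXA projection rows
#' (BMC with multiplicative measurement noise, areal BMD against a projected
#' width x height area proxy) and a bilinear stress-strain law sampled as a
#' noisy load-displacement record whose strain grid includes the yield strain,
#' so the sampled polyline represents the underlying law exactly.
#'
#' Output is deterministic for a fixed config (same seed, same tables).
#'
#' @param config A [cohort_config()].
#' @return A list with tibbles `truth` (per-specimen ground truth, consumed
#'   only by tests), `dxa_measurements` (2 rows per specimen),
#'   `mechanical_curves` (long format: `specimen_id`, `displacement_mm`,
#'   `load_n`) and `specimens` (`specimen_id`, `exposed_length_lo_mm`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_specimens
  ids <- sprintf("S%03d", seq_len(n))

  r_vm <- spearman_to_pearson(cfg$rho_vbmd_mech)
  r_em <- spearman_to_pearson(0.6)  # modulus vs stresses
  sigma <- matrix(c(1, r_vm, r_vm,
                    r_vm, 1, r_em,
                    r_vm, r_em, 1), 3, 3)
  z <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = sigma)
  if (n == 1) z <- matrix(z, nrow = 1)

  vbmd <- truncnorm_from_z(z[, 1], cfg$vbmd_mean, cfg$vbmd_sd)
  modulus <- truncnorm_from_z(z[, 2], cfg$modulus_mean, cfg$modulus_sd)
  sy <- truncnorm_from_z(z[, 3], cfg$yield_stress_mean, cfg$yield_stress_sd)

  # failure = yield + strictly positive increment (no rejection, so the
  # copula's target dependence is preserved exactly)
  d_stress_mean <- cfg$failure_stress_mean - cfg$yield_stress_mean
  d_stress <- truncnorm_from_z(stats::rnorm(n), d_stress_mean,
                               d_stress_mean / 2)
  sf <- sy + d_stress
  ey <- sy / (1000 * modulus)
  d_strain_mean <- cfg$failure_strain_mean -
    cfg$yield_stress_mean / (1000 * cfg$modulus_mean)
  d_strain <- truncnorm_from_z(stats::rnorm(n), d_strain_mean,
                               d_strain_mean / 2)
  # keep the hardening limb clearly shallower than the elastic limb, and the
  # elastic limb at least a quarter of the strain range, so the maximum-slope
  # modulus window always lies pre-yield
  d_strain <- pmin(pmax(d_strain, d_stress / (0.6 * 1000 * modulus)), 3 * ey)
  ef <- ey + d_strain

  area <- truncnorm_from_z(stats::rnorm(n), cfg$area_mean, cfg$area_sd)
  roi <- truncnorm_from_z(stats::rnorm(n), cfg$roi_height_mean,
                          cfg$roi_height_sd)
  lat_w <- sqrt(4 * area / (pi * 1.2))
  ap_w <- 1.2 * lat_w
  volume <- area * roi

  no_yield <- stats::runif(n) < cfg$yield_missing_rate

  truth <- fast_tbl(
    specimen_id = ids,
    true_vbmd = vbmd,
    true_modulus = modulus,
    true_yield_stress = ifelse(no_yield, NA_real_, sy),
    true_yield_strain = ifelse(no_yield, NA_real_, ey),
    true_failure_stress = sf,
    true_failure_strain = ef,
    ap_width = ap_w, lat_width = lat_w, roi_height = roi,
    cross_section_area = area, volume = volume
  )

  cv <- cfg$measurement_noise_cv
  mk_proj <- function(projection, width) {
    bmc <- vbmd * volume * (1 + stats::rnorm(n, 0, cv))
    fast_tbl(
      specimen_id = ids, projection = projection,
      bone_width = width, bone_area = width * roi,
      bmc = bmc, bmd = bmc / (width * roi), roi_height = roi
    )
  }
  dxa <- rbind(mk_proj("AP", ap_w), mk_proj("LAT", lat_w))
  dxa <- dxa[order(match(dxa$specimen_id, ids), dxa$projection), ]

  lo_mm <- roi * 10
  area_mm2 <- area * 100
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    e_mpa <- 1000 * modulus[i]
    if (no_yield[i]) {
      # purely linear ramp to the failure stress: no offset-yield crossing
      strain <- seq(0, ef[i], length.out = cfg$samples_per_curve)
      stress <- sf[i] * strain / ef[i]
    } else {
      strain <- sort(unique(c(
        seq(0, ef[i], length.out = cfg$samples_per_curve - 1L), ey[i])))
      hard <- (sf[i] - sy[i]) / (ef[i] - ey[i])
      stress <- ifelse(strain <= ey[i], e_mpa * strain,
                       sy[i] + hard * (strain - ey[i]))
    }
    load <- stress * area_mm2[i] * (1 + stats::rnorm(length(stress), 0, cv))
    load[1] <- 0
    curves[[i]] <- fast_tbl(
      specimen_id = ids[i],
      displacement_mm = strain * lo_mm[i],
      load_n = load
    )
  }

  list(
    truth = truth,
    dxa_measurements = tibble::as_tibble(dxa),
    mechanical_curves = do.call(rbind, curves),
    specimens = fast_tbl(specimen_id = ids,
                               exposed_length_lo_mm = lo_mm)
  )
}

#' Total programmed lengthening of a distraction protocol
#'
#' @param rate_mm Distraction per step (mm), e.g. 0.375.
#' @param steps_per_day Steps per day, e.g. 2 (every 12 h).
#' @param days Days of distraction; may be zero.
#' @return Total programmed lengthening in mm.
#' @examples
#' programmed_lengthening(0.375, 2, 10)  # 7.5 mm
#' @export
programmed_lengthening <- function(rate_mm, steps_per_day, days) {
  assert_positive(rate_mm, "rate_mm")
  assert_positive(steps_per_day, "steps_per_day")
  if (!is.finite(days) || days < 0) {
    stop("`days` must be finite and non-negative", call. = FALSE)
  }
  rate_mm * steps_per_day * days
}

#' Write a synthetic cohort to CSV fixtures
#'
#' Emits `dxa_measurements.csv`, `mechanical_curves.csv`, `specimens.csv` and
#' `truth.csv` (the last is consumed only by tests, never by the analysis
#' pipeline) in the schemas the analysis modules read.
#'
#' @param cohort A list from [generate_cohort()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, a tibble manifest of files and row counts.
#' @export
write_fixture_set <- function(cohort, directory) {
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE)
  }
  files <- c(dxa_measurements = "dxa_measurements.csv",
             mechanical_curves = "mechanical_curves.csv",
             specimens = "specimens.csv",
             truth = "truth.csv")
  paths <- file.path(directory, files)
  names(paths) <- names(files)
  write_one <- function(df, path) {
    tryCatch(
      utils::write.csv(as.data.frame(df), path, row.names = FALSE),
      error = function(e) stop(sprintf("failed writing '%s': %s", path,
                                       conditionMessage(e)), call. = FALSE))
  }
  write_one(rename_dxa_out(cohort$dxa_measurements), paths["dxa_measurements"])
  write_one(stats::setNames(cohort$mechanical_curves,
                            c("specimen_id", "displacement_mm", "load_N")),
            paths["mechanical_curves"])
  write_one(cohort$specimens, paths["specimens"])
  write_one(cohort$truth, paths["truth"])
  invisible(fast_tbl(
    file = unname(paths),
    rows = c(nrow(cohort$dxa_measurements), nrow(cohort$mechanical_curves),
             nrow(cohort$specimens), nrow(cohort$truth))
  ))
}

rename_dxa_out <- function(dxa) {
  stats::setNames(as.data.frame(dxa),
                  c("specimen_id", "projection", "bone_width_cm",
                    "bone_area_cm2", "bmc_g", "bmd_g_cm2", "roi_height_cm"))
}
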