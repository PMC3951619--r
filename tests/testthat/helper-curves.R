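# Closed-form constructions for bilinear stress-strain laws, used as
# independent oracles for the curve-extraction operations.

# Sampled bilinear curve: elastic limb of slope e_mpa through the origin up
# to the kink (eps_y, e_mpa * eps_y), then a hardening limb to
# (eps_f, sigma_f). The kink strain is inserted into the grid so the sampled
# polyline represents the law exactly.
bilinear_ss <- function(e_mpa, eps_y, eps_f, sigma_f, n = 60) {
  sigma_y <- e_mpa * eps_y
  strain <- sort(unique(c(seq(0, eps_f, length.out = n), eps_y)))
  hard <- (sigma_f - sigma_y) / (eps_f - eps_y)
  stress <- ifelse(strain <= eps_y, e_mpa * strain,
                   sigma_y + hard * (strain - eps_y))
  data.frame(strain = strain, stress = stress)
}

# Analytic intersection of the offset line sigma = E (eps - offset) with the
# hardening limb of the bilinear law.
bilinear_offset_yield <- function(e_mpa, eps_y, eps_f, sigma_f, offset) {
  sigma_y <- e_mpa * eps_y
  hard <- (sigma_f - sigma_y) / (eps_f - eps_y)
  eps <- (sigma_y - hard * eps_y + e_mpa * offset) / (e_mpa - hard)
  c(strain = eps, stress = e_mpa * (eps - offset))
}

# Analytic area under the bilinear law from 0 to up_to.
bilinear_energy <- function(e_mpa, eps_y, eps_f, sigma_f, up_to) {
  sigma_y <- e_mpa * eps_y
  hard <- (sigma_f - sigma_y) / (eps_f - eps_y)
  if (up_to <= eps_y) {
    return(0.5 * e_mpa * up_to^2)
  }
  s_end <- sigma_y + hard * (up_to - eps_y)
  0.5 * sigma_y * eps_y + (sigma_y + s_end) / 2 * (up_to - eps_y)
}

# Load-displacement record realising a bilinear law for a given geometry.
bilinear_curve <- function(e_mpa, eps_y, eps_f, sigma_f, lo_mm, area_cm2,
                           n = 60) {
  ss <- bilinear_ss(e_mpa, eps_y, eps_f, sigma_f, n)
  data.frame(displacement_mm = ss$strain * lo_mm,
             load_n = ss$stress * area_cm2 * 100)
}
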