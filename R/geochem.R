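# Dissolved greenhouse-gas geochemistry: Henry's law with van't Hoff
# temperature adjustment, headspace-equilibration mass balance, saturation,
# methanotroph estimated abundance, Box-Cox regression and DOM optical
# indices.

GAS_CONSTANT_L_ATM <- 0.082057  # L atm K^-1 mol^-1
T0_K <- 298.15

#' Gas specification
#'
#' Henry solubility at 25 degC, its van't Hoff temperature coefficient and
#' the atmospheric mixing ratio. Defaults follow the standard solubility
#' compilation values for freshwater (no salinity correction; the systems
#' are tundra ponds): CO2 0.0334 mol L^-1 atm^-1 / 2400 K / 407 ppm, CH4
#' 1.4e-3 mol L^-1 atm^-1 / 1700 K / 1.85 ppm.
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @param k_h25 Henry solubility at 25 degC (mol L^-1 atm^-1).
#' @param vant_hoff Temperature coefficient (K).
#' @param atm_ppm Atmospheric mixing ratio (ppm).
#' @return An object of class `gas_spec`.
#' @export
gas_spec <- function(gas = c("CO2", "CH4"), k_h25 = NULL, vant_hoff = NULL,
                     atm_ppm = NULL) {
  gas <- match.arg(gas)
  defaults <- list(CO2 = list(k = 0.0334, c = 2400, ppm = 407),
                   CH4 = list(k = 1.4e-3, c = 1700, ppm = 1.85))[[gas]]
  k_h25 <- k_h25 %||% defaults$k
  vant_hoff <- vant_hoff %||% defaults$c
  atm_ppm <- atm_ppm %||% defaults$ppm
  if (k_h25 <= 0 || vant_hoff <= 0) stop("K_H and coefficient must be > 0")
  if (atm_ppm <= 0 || atm_ppm >= 1e6) stop("mixing ratio out of (0, 1)")
  structure(list(gas = gas, k_h25 = k_h25, vant_hoff = vant_hoff,
                 atm_mixing_ratio = atm_ppm * 1e-6),
            class = "gas_spec")
}

check_temp <- function(temp_c) {
  if (any(temp_c < -5) || any(temp_c > 40)) {
    stop("temperature outside the physically plausible range -5..40 degC")
  }
  invisible(temp_c)
}

#' Henry constant at temperature
#'
#' `K_H(T) = K_H25 * exp(coeff * (1/T - 1/298.15))`, T in kelvin.
#'
#' @param spec A [gas_spec()].
#' @param temp_c Water temperature (degC), vectorized.
#' @return K_H in mol L^-1 atm^-1.
#' @export
henry_constant <- function(spec, temp_c) {
  check_temp(temp_c)
  TK <- temp_c + 273.15
  spec$k_h25 * exp(spec$vant_hoff * (1 / TK - 1 / T0_K))
}

#' Dissolved gas concentration from partial pressure
#'
#' Henry's law, `Gas_aq = K_H(T) * pGas`, returned in micromolar.
#'
#' @param spec A [gas_spec()].
#' @param p_gas_atm Partial pressure (atm), vectorized.
#' @param temp_c Water temperature (degC).
#' @return Concentration in uM.
#' @export
dissolved_gas <- function(spec, p_gas_atm, temp_c) {
  if (any(p_gas_atm < 0)) stop("negative partial pressure")
  henry_constant(spec, temp_c) * p_gas_atm * 1e6
}

#' Air-equilibrium dissolved concentration
#'
#' Dissolved concentration in equilibrium with the atmospheric mixing
#' ratio of the gas at the given temperature.
#'
#' @param spec A [gas_spec()].
#' @param temp_c Water temperature (degC).
#' @return Concentration in uM.
#' @export
equilibrium_concentration <- function(spec, temp_c) {
  dissolved_gas(spec, spec$atm_mixing_ratio, temp_c)
}

#' Forward headspace equilibration (simulator / round-trip oracle)
#'
#' Given an in-situ dissolved concentration, computes the headspace partial
#' pressure after equilibrating `v_water_ml` of water with `v_head_ml` of
#' ambient air at `temp_c`, by mass balance with an ideal-gas headspace.
#'
#' @param spec A [gas_spec()].
#' @param c0_uM In-situ dissolved concentration (uM).
#' @param temp_c Equilibration temperature (degC).
#' @param v_water_ml,v_head_ml Water and headspace volumes (ml).
#' @param p_amb_atm Ambient-air partial pressure (atm); defaults to the
#'   spec's atmospheric mixing ratio.
#' @return Equilibrated headspace partial pressure (atm).
#' @export
equilibrate_headspace <- function(spec, c0_uM, temp_c, v_water_ml = 40,
                                  v_head_ml = 20, p_amb_atm = NULL) {
  stopifnot(v_water_ml > 0, v_head_ml > 0, c0_uM >= 0)
  p_amb_atm <- p_amb_atm %||% spec$atm_mixing_ratio
  kh <- henry_constant(spec, temp_c)
  TK <- temp_c + 273.15
  Vw <- v_water_ml / 1000
  Vh <- v_head_ml / 1000
  n_total <- (c0_uM * 1e-6) * Vw + p_amb_atm * Vh / (GAS_CONSTANT_L_ATM * TK)
  n_total / (kh * Vw + Vh / (GAS_CONSTANT_L_ATM * TK))
}

#' Invert a headspace measurement to the in-situ concentration
#'
#' Mass balance of the headspace technique: total moles before shaking
#' (unknown dissolved amount plus injected ambient air) equal total moles
#' after (dissolved at Henry equilibrium with the measured headspace, plus
#' headspace). The ambient-air term implements the correction for the
#' minor atmospheric contribution of the injected air.
#'
#' @param spec A [gas_spec()].
#' @param headspace_ppm Measured post-equilibration headspace mixing ratio
#'   (ppm), vectorized.
#' @param ambient_ppm Ambient-air mixing ratio (ppm).
#' @param temp_c Equilibration temperature (degC).
#' @param v_water_ml,v_head_ml Water and headspace volumes (ml).
#' @return In-situ dissolved concentration (uM); negative mass balances
#'   (measurement below the ambient injection) are clamped to 0 with a
#'   warning.
#' @export
headspace_to_insitu <- function(spec, headspace_ppm, ambient_ppm, temp_c,
                                v_water_ml = 40, v_head_ml = 20) {
  stopifnot(all(headspace_ppm >= 0), all(ambient_ppm >= 0),
            v_water_ml > 0, v_head_ml > 0)
  kh <- henry_constant(spec, temp_c)
  TK <- temp_c + 273.15
  Vw <- v_water_ml / 1000
  Vh <- v_head_ml / 1000
  p_eq <- headspace_ppm * 1e-6
  p_amb <- ambient_ppm * 1e-6
  c_aq_eq <- kh * p_eq                       # mol / L at equilibrium
  n_total <- c_aq_eq * Vw + p_eq * Vh / (GAS_CONSTANT_L_ATM * TK)
  c0 <- (n_total - p_amb * Vh / (GAS_CONSTANT_L_ATM * TK)) / Vw
  if (any(c0 < 0)) {
    warning("negative mass balance clamped to 0 (headspace below ambient)")
    c0 <- pmax(c0, 0)
  }
  c0 * 1e6
}

#' Saturation relative to air equilibrium
#'
#' @param observed_uM Observed dissolved concentration (uM).
#' @param equilibrium_uM Air-equilibrium concentration (uM, > 0).
#' @return Saturation in percent.
#' @export
saturation_percent <- function(observed_uM, equilibrium_uM) {
  if (any(equilibrium_uM <= 0)) stop("equilibrium concentration must be > 0")
  100 * observed_uM / equilibrium_uM
}

#' Estimated methanotroph abundance
#'
#' Proportion of methanotroph reads multiplied by the total bacterial cell
#' count from microscopy.
#'
#' @param read_fraction Methanotroph read fraction in \[0, 1\].
#' @param total_cells_per_ml Total bacterial cells per ml (>= 0).
#' @return Estimated methanotroph cells per ml.
#' @export
methanotroph_abundance <- function(read_fraction, total_cells_per_ml) {
  stopifnot(all(read_fraction >= 0), all(read_fraction <= 1),
            all(total_cells_per_ml >= 0))
  read_fraction * total_cells_per_ml
}

#' Process a headspace gas-measurement table
#'
#' Applies [headspace_to_insitu()] row-wise and adds the air-equilibrium
#' concentration and saturation.
#'
#' @param gas_table data.frame with columns sample_id, gas, temperature_C,
#'   headspace_ppm, ambient_ppm, V_water_ml, V_head_ml.
#' @return The table with `concentration_uM`, `equilibrium_uM` and
#'   `saturation_pct` columns appended.
#' @export
process_gas_table <- function(gas_table) {
  need <- c("sample_id", "gas", "temperature_C", "headspace_ppm",
            "ambient_ppm", "V_water_ml", "V_head_ml")
  stopifnot(all(need %in% names(gas_table)))
  out <- gas_table
  out$concentration_uM <- NA_real_
  out$equilibrium_uM <- NA_real_
  for (g in unique(out$gas)) {
    spec <- gas_spec(g)
    rows <- out$gas == g
    out$concentration_uM[rows] <- headspace_to_insitu(
      spec, out$headspace_ppm[rows], out$ambient_ppm[rows],
      out$temperature_C[rows], out$V_water_ml[rows], out$V_head_ml[rows])
    out$equilibrium_uM[rows] <-
      equilibrium_concentration(spec, out$temperature_C[rows])
  }
  out$saturation_pct <- saturation_percent(out$concentration_uM,
                                           out$equilibrium_uM)
  out
}

# ---- Box-Cox ---------------------------------------------------------------

#' Box-Cox power transform
#'
#' `y = (x^lambda - 1) / lambda` for lambda != 0 and `log x` at lambda = 0
#' (the continuous limit).
#'
#' @param x Positive values.
#' @param lambda Power parameter.
#' @return Transformed values.
#' @export
box_cox <- function(x, lambda) {
  if (any(x <= 0)) {
    stop("Box-Cox requires positive values; offending: ",
         paste(utils::head(x[x <= 0], 5), collapse = ", "))
  }
  if (abs(lambda) < 1e-10) log(x) else (x^lambda - 1) / lambda
}

#' Inverse Box-Cox transform
#'
#' @param y Transformed values.
#' @param lambda Power parameter used in the forward transform.
#' @return Original-scale values.
#' @export
box_cox_inverse <- function(y, lambda) {
  if (abs(lambda) < 1e-10) exp(y) else (lambda * y + 1)^(1 / lambda)
}

#' Fit the Box-Cox power parameter by profile likelihood
#'
#' Maximizes the profile log-likelihood of the normal model on a lambda
#' grid (default \[-5, 5\] in steps of 0.01):
#' `ll(lambda) = -n/2 log(sigma^2_hat(lambda)) + (lambda - 1) sum log x`.
#'
#' @param x Positive values.
#' @param lambda_grid Candidate lambda values.
#' @return List of class `boxcox_fit`: `lambda`, `transformed`, `profile`
#'   (data.frame lambda/loglik).
#' @export
fit_box_cox <- function(x, lambda_grid = seq(-5, 5, by = 0.01)) {
  if (any(x <= 0)) stop("Box-Cox requires positive values")
  n <- length(x)
  # profile on geometric-mean-scaled data: lambda-hat is scale-invariant and
  # extreme lambdas then cannot collapse the transform to a numerical
  # constant (which would send the profile likelihood to +Inf)
  z <- x / exp(mean(log(x)))
  slog <- sum(log(z))
  ll <- vapply(lambda_grid, function(l) {
    y <- box_cox(z, l)
    s2 <- mean((y - mean(y))^2)
    if (!is.finite(s2) || s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (l - 1) * slog
  }, 0)
  lambda <- lambda_grid[which.max(ll)]
  structure(list(lambda = lambda, transformed = box_cox(x, lambda),
                 profile = data.frame(lambda = lambda_grid, loglik = ll)),
            class = "boxcox_fit")
}

#' Regression on Box-Cox-normalized scales
#'
#' Transforms response and predictor with fitted (or supplied) Box-Cox
#' lambdas and fits an ordinary least-squares regression.
#'
#' @param y,x Positive response and predictor.
#' @param lambda_y,lambda_x Optional fixed lambdas; fitted by profile
#'   likelihood when NULL.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `lambda_y`, `lambda_x` and the underlying `lm` fit.
#' @export
boxcox_regress <- function(y, x, lambda_y = NULL, lambda_x = NULL) {
  stopifnot(length(y) == length(x))
  lambda_y <- lambda_y %||% fit_box_cox(y)$lambda
  lambda_x <- lambda_x %||% fit_box_cox(x)$lambda
  ty <- box_cox(y, lambda_y)
  tx <- box_cox(x, lambda_x)
  fit <- stats::lm(ty ~ tx)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       lambda_y = lambda_y, lambda_x = lambda_x, model = fit)
}

# ---- DOM optics ------------------------------------------------------------

band_slope <- function(wl, a, band) {
  sel <- wl >= band[1] & wl <= band[2]
  if (sum(sel) < 3) stop("spectrum does not cover band ",
                         band[1], "-", band[2], " nm")
  if (any(a[sel] <= 0)) {
    warning("non-positive absorption in band ", band[1], "-", band[2],
            " nm: slope undefined")
    return(NA_real_)
  }
  -unname(stats::coef(stats::lm(log(a[sel]) ~ wl[sel]))[2])
}

#' DOM optical indices from an absorbance spectrum
#'
#' Computes the chromophoric DOM absorption coefficient
#' `a(lambda) = 2.303 A(lambda) / path`, SUVA254 (absorbance per cm at
#' 254 nm times 100, per mg C), the spectral slopes over 275-295 and
#' 350-400 nm (log-linear fits of a on wavelength) and their ratio, a
#' molecular-weight proxy.
#'
#' @param wavelength_nm Wavelengths (should cover 250-450 nm at <= 1 nm
#'   steps).
#' @param absorbance Dimensionless absorbance measured over `path_m`.
#' @param path_m Cuvette path length (m).
#' @param doc_mg_l DOC concentration (mg C per L) for SUVA254; NA skips it.
#' @return List of class `dom_optics`: `a320` (m^-1), `suva254`
#'   (L mg^-1 m^-1), `s275_295`, `s350_400` (nm^-1), `slope_ratio`.
#' @export
dom_optics <- function(wavelength_nm, absorbance, path_m,
                       doc_mg_l = NA_real_) {
  stopifnot(length(wavelength_nm) == length(absorbance), path_m > 0)
  if (min(wavelength_nm) > 254 || max(wavelength_nm) < 400) {
    stop("spectrum must cover at least 254-400 nm")
  }
  ord <- order(wavelength_nm)
  wl <- wavelength_nm[ord]
  A <- absorbance[ord]
  a <- 2.303 * A / path_m
  a320 <- stats::approx(wl, a, xout = 320)$y
  suva <- NA_real_
  if (!is.na(doc_mg_l)) {
    if (doc_mg_l <= 0) stop("DOC must be > 0 for SUVA254")
    A254_cm <- stats::approx(wl, A, xout = 254)$y / (path_m * 100)
    suva <- 100 * A254_cm / doc_mg_l
  }
  s1 <- band_slope(wl, a, c(275, 295))
  s2 <- band_slope(wl, a, c(350, 400))
  structure(list(a320 = a320, suva254 = suva, s275_295 = s1,
                 s350_400 = s2,
                 slope_ratio = if (is.na(s1) || is.na(s2)) NA_real_
                               else s1 / s2),
            class = "dom_optics")
}
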