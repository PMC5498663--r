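#' Simulator configuration
#'
#' Bundles every kinetic, noise and delivery parameter of the forward model.
#' Defaults are calibrated against the summary statistics of single-cell AID
#' depletion/recovery experiments in budding yeast: maximal depletion rate
#' saturating at 0.25 mM auxin, complete depletion in about 25 min at 0.5 mM,
#' an autofluorescence floor at 0.288 of the pre-depletion reporter signal, a
#' per-division dilution factor of 1.2, a median inter-budding interval of
#' 100 min, about 20% protein recovery within 60 min of auxin removal, full
#' recovery after several generations, a ~20 min extra depletion onset delay
#' in newborn daughters, and a 35% growth-rate reduction at 0.5 uM IAA under
#' blue-light excitation.
#'
#' The protein component C (concentration, normalized units) obeys
#' \deqn{dC/dt = k_{syn}^{max}(1 - C/c_{cap}) - k_{deg}(A_{eff}) C}
#' between divisions, and drops instantaneously by `dil_factor` at each
#' division. Synthesis saturation `c_cap` and `k_syn_max` are jointly
#' calibrated so that the periodic steady state of the unperturbed division
#' cycle has cycle-averaged C = 1 (see [cycle_fixed_point()]).
#'
#' @param k_deg_max maximal auxin-induced degradation rate (1/min).
#' @param ec50_deg auxin concentration of half-maximal degradation (mM).
#' @param hill_h Hill coefficient of the degradation dose response.
#' @param k_syn_max maximal synthesis rate (normalized conc/min).
#' @param c_cap synthesis-repression capacity (normalized conc); synthesis
#'   stops as C approaches this value.
#' @param dil_factor per-division concentration drop (fold, >= 1).
#' @param t_div_median median inter-budding interval of unperturbed cells (min).
#' @param t_div_cv coefficient of variation of the division interval.
#' @param af_floor autofluorescence level in units of the mean pre-depletion
#'   reporter signal (0 <= af_floor < 1).
#' @param noise_cv multiplicative (lognormal) measurement noise CV.
#' @param pka_iaa acid dissociation constant of indole-3-acetic acid.
#' @param ph_ref reference medium pH at which concentrations are quoted.
#' @param onset_m_max,onset_ec50 dose dependence of the per-cell depletion
#'   onset delay: mean delay = onset_m_max * onset_ec50 / (A + onset_ec50)
#'   (min, mM); delays are Gamma(shape 2) distributed.
#' @param daughter_delay extra onset delay of newborn daughter cells (min).
#' @param photo_r_max,photo_a50 saturating (Michaelis) growth-rate reduction
#'   by IAA combined with blue-light excitation (max fraction; mM).
#' @param dark_r_max,dark_a50 weaker growth-rate reduction by IAA without
#'   excitation light (max fraction; mM).
#' @param growth_recovery_k rate constant of the exponential relaxation of the
#'   growth-rate defect after auxin removal (1/min).
#' @param sample_period imaging period (min).
#' @param seed default RNG seed used by [simulate_experiment()].
#'
#' @return An object of class `aid_sim_config` (a validated named list).
#' @seealso [auxin_schedule()], [simulate_experiment()]
#' @export
#' @examples
#' cfg <- sim_config()
#' degradation_rate(0.25, cfg) / cfg$k_deg_max  # saturated at 0.25 mM
sim_config <- function(k_deg_max = 0.25,
                       ec50_deg = 0.05,
                       hill_h = 2,
                       k_syn_max = 0.00422,
                       c_cap = 1.7522,
                       dil_factor = 1.2,
                       t_div_median = 100,
                       t_div_cv = 0.15,
                       af_floor = 0.288,
                       noise_cv = 0.05,
                       pka_iaa = 4.75,
                       ph_ref = 5.1,
                       onset_m_max = 60,
                       onset_ec50 = 0.10,
                       daughter_delay = 20,
                       photo_r_max = 0.5,
                       photo_a50 = 2.143e-4,
                       dark_r_max = 0.1,
                       dark_a50 = 0.5,
                       growth_recovery_k = 0.004,
                       sample_period = 5,
                       seed = 1L) {
  cfg <- list(k_deg_max = k_deg_max, ec50_deg = ec50_deg, hill_h = hill_h,
              k_syn_max = k_syn_max, c_cap = c_cap, dil_factor = dil_factor,
              t_div_median = t_div_median, t_div_cv = t_div_cv,
              af_floor = af_floor, noise_cv = noise_cv,
              pka_iaa = pka_iaa, ph_ref = ph_ref,
              onset_m_max = onset_m_max, onset_ec50 = onset_ec50,
              daughter_delay = daughter_delay,
              photo_r_max = photo_r_max, photo_a50 = photo_a50,
              dark_r_max = dark_r_max, dark_a50 = dark_a50,
              growth_recovery_k = growth_recovery_k,
              sample_period = sample_period, seed = as.integer(seed))
  class(cfg) <- "aid_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "aid_sim_config"))
  rates <- c("k_deg_max", "ec50_deg", "hill_h", "k_syn_max", "c_cap",
             "t_div_median", "t_div_cv", "noise_cv", "onset_m_max",
             "onset_ec50", "daughter_delay", "growth_recovery_k")
  for (nm in rates) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0)
      stop("sim_config: `", nm, "` must be a single nonnegative number",
           call. = FALSE)
  }
  if (cfg$dil_factor < 1)
    stop("sim_config: `dil_factor` must be >= 1", call. = FALSE)
  if (cfg$af_floor < 0 || cfg$af_floor >= 1)
    stop("sim_config: `af_floor` must be in [0, 1)", call. = FALSE)
  if (cfg$sample_period <= 0)
    stop("sim_config: `sample_period` must be positive", call. = FALSE)
  if (cfg$photo_r_max < 0 || cfg$photo_r_max >= 1 ||
      cfg$dark_r_max < 0 || cfg$dark_r_max >= 1)
    stop("sim_config: growth-defect maxima must be in [0, 1)", call. = FALSE)
  cfg
}

#' @export
print.aid_sim_config <- function(x, ...) {
  cat("AID simulator configuration\n")
  cat(sprintf("  degradation: k_deg_max %.3g/min, EC50 %.3g mM, Hill h %.3g\n",
              x$k_deg_max, x$ec50_deg, x$hill_h))
  cat(sprintf("  synthesis:   k_syn_max %.3g/min, c_cap %.3g\n",
              x$k_syn_max, x$c_cap))
  cat(sprintf("  division:    dil %.3g-fold, T_div %.3g min (CV %.3g)\n",
              x$dil_factor, x$t_div_median, x$t_div_cv))
  cat(sprintf("  signal:      floor %.3g, noise CV %.3g, sampled every %g min\n",
              x$af_floor, x$noise_cv, x$sample_period))
  invisible(x)
}

#' Periodic steady state of the unperturbed division cycle
#'
#' Between divisions C relaxes towards `c_cap` at rate k = k_syn_max/c_cap;
#' each division divides C by `dil`. The periodic fixed point of this cycle
#' map satisfies MIN = (c_cap + (MIN - c_cap) e^(-kT)) / dil. This closed form
#' anchors the simulator's initial condition and the calibration of the
#' synthesis parameters (cycle-averaged C = 1 at the defaults).
#'
#' @param k_syn_max,c_cap,dil,T_div synthesis rate, capacity, per-division
#'   fold drop and cycle length; default from `config`.
#' @param config an [sim_config()] object supplying defaults.
#' @return list with `min`, `max` (trough/peak of C) and `mean`
#'   (cycle-averaged C).
#' @export
#' @examples
#' cycle_fixed_point(config = sim_config())$mean  # ~1
cycle_fixed_point <- function(config = sim_config(),
                              k_syn_max = config$k_syn_max,
                              c_cap = config$c_cap,
                              dil = config$dil_factor,
                              T_div = config$t_div_median) {
  k <- k_syn_max / c_cap
  E <- exp(-k * T_div)
  cmin <- c_cap * (1 - E) / (dil - E)
  cmax <- dil * cmin
  cmean <- c_cap + (cmin - c_cap) * (1 - E) / (k * T_div)
  list(min = cmin, max = cmax, mean = cmean)
}

#' pH-corrected effective auxin concentration
#'
#' Auxin enters cells in its protonated form; deprotonation at higher medium
#' pH reduces uptake. The effective concentration rescales the nominal one by
#' the Henderson-Hasselbalch protonated fraction f(pH) = 1/(1 + 10^(pH - pKa))
#' relative to the reference pH, so concentrations quoted at `ph_ref` are
#' unchanged.
#'
#' @param conc_mM nominal auxin concentration (mM), >= 0.
#' @param ph medium pH (0 < pH < 14).
#' @param config an [sim_config()] object (uses `pka_iaa`, `ph_ref`).
#' @return effective concentration (mM), strictly decreasing in `ph`.
#' @export
#' @examples
#' effective_auxin(0.1, 6.8) / 0.1  # uptake penalty at pH 6.8, ~0.029
effective_auxin <- function(conc_mM, ph, config = sim_config()) {
  if (any(conc_mM < 0)) stop("negative auxin concentration", call. = FALSE)
  if (any(ph <= 0 | ph >= 14)) stop("pH must be in (0, 14)", call. = FALSE)
  f <- function(p) 1 / (1 + 10^(p - config$pka_iaa))
  conc_mM * f(ph) / f(config$ph_ref)
}

#' Auxin-dependent degradation rate
#'
#' Hill-type dose response of the degron-mediated degradation rate,
#' k_deg(A) = k_deg_max A^h / (EC50^h + A^h). With the default EC50 (0.05 mM)
#' and h = 2, the rate is >= 96% of maximal at 0.25 mM, reproducing the
#' saturation of depletion rates at and above that concentration.
#'
#' @param eff_conc_mM effective auxin concentration (mM), see
#'   [effective_auxin()].
#' @param config an [sim_config()] object.
#' @return degradation rate (1/min), monotone nondecreasing in the dose.
#' @export
degradation_rate <- function(eff_conc_mM, config = sim_config()) {
  if (any(eff_conc_mM < 0)) stop("negative auxin concentration", call. = FALSE)
  a <- eff_conc_mM^config$hill_h
  ifelse(eff_conc_mM == 0, 0,
         config$k_deg_max * a / (config$ec50_deg^config$hill_h + a))
}

#' Fractional growth-rate reduction by auxin
#'
#' IAA photo-degrades under the blue light used for GFP excitation into toxic
#' derivatives; the combination reduces growth with a saturating (Michaelis)
#' dose response that is strong even at sub-micromolar IAA. Without
#' excitation light the defect is much weaker, and the indole-free substitute
#' NAA causes no growth defect at all.
#'
#' @param conc_mM auxin concentration (mM).
#' @param light_on logical; is GFP excitation light applied?
#' @param compound `"IAA"` or `"NAA"`.
#' @param config an [sim_config()] object.
#' @return fractional reduction of the growth rate, in \[0, 1).
#' @export
#' @examples
#' growth_reduction(5e-4, TRUE, "IAA")   # ~0.35 at 0.5 uM IAA + light
#' growth_reduction(0.1, TRUE, "NAA")    # 0
growth_reduction <- function(conc_mM, light_on, compound = "IAA",
                             config = sim_config()) {
  if (any(conc_mM < 0)) stop("negative auxin concentration", call. = FALSE)
  if (!all(compound %in% c("IAA", "NAA")))
    stop("unknown compound: ", paste(setdiff(compound, c("IAA", "NAA")),
                                     collapse = ", "), call. = FALSE)
  mich <- function(a, rmax, a50) rmax * a / (a50 + a)
  n <- max(length(conc_mM), length(light_on), length(compound))
  conc <- rep_len(conc_mM, n)
  li <- rep_len(light_on, n)
  comp <- rep_len(compound, n)
  out <- numeric(n)
  sel <- comp == "IAA" & li
  out[sel] <- mich(conc[sel], config$photo_r_max, config$photo_a50)
  sel <- comp == "IAA" & !li
  out[sel] <- mich(conc[sel], config$dark_r_max, config$dark_a50)
  out
}
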