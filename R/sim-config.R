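#' Configuration for the synthetic nitrogen-gradient generator
#'
#' Bundles every knob of the OTU-gradient simulator: the experimental
#' design (N levels, replicates), the environmental responses (DIN rises
#' and pH and plant richness fall with dose), the guild structure
#' (copiotrophs vs oligotrophs with distinct rrn/GC traits), and the
#' correlation-generating latent factors (module-level cooperation
#' factors with positive loadings, plus an antagonistic coupling
#' between paired oligotroph modules that is released as the dose
#' rises; between-guild negative correlation additionally arises from
#' the guilds' opposite abundance responses to the gradient).
#'
#' All gradient responses are linear in the dose `log2(N + 1)` (the
#' levels are doublings). Guild abundance responses act on the
#' standardized realized DIN and pH, so nitrogen reaches the community
#' only through the measured soil variables; likewise the oligotroph
#' extinction probability and the competition decay are driven by the
#' DIN-implied dose `(DIN - din_intercept)/din_slope`, clamped to the
#' design range (defined as 0 when `din_slope = 0`).
#'
#' @param n_levels ordered N application rates, g N m^-2 y^-1.
#' @param reps_per_level replicate plots per level (integer, >= 2).
#' @param n_taxa number of OTUs (>= 10).
#' @param frac_copiotroph expected copiotroph fraction, strictly in (0,1).
#' @param seq_depth expected reads per sample.
#' @param dispersion negative-binomial size parameter (> 0); smaller
#'   values mean more count overdispersion.
#' @param din_intercept,din_slope,din_sd DIN (mg kg^-1) baseline, change
#'   per unit dose, and plot-level noise sd.
#' @param ph_intercept,ph_slope,ph_sd soil pH baseline, decline per unit
#'   dose, and noise sd. pH is clipped to [3.5, 9].
#' @param plant_intercept,plant_slope,plant_sd plant species richness
#'   baseline, decline per unit dose, and noise sd (rounded, floored at 0).
#' @param copio_din_response copiotroph log-abundance response per SD of
#'   realized DIN.
#' @param copio_acid_tolerance copiotroph log-abundance benefit per SD
#'   of pH decline (acid-tolerant opportunists gain as the soil
#'   acidifies).
#' @param oligo_ph_sensitivity oligotroph log-abundance response per SD of
#'   realized pH (positive: oligotrophs suffer as pH drops).
#' @param copio_coop,oligo_coop within-guild cooperation-factor
#'   loadings (positive co-occurrence). Factors act on modules of
#'   `module_size` taxa inside each guild, not guild-wide, so the
#'   compositional closure cannot cancel them; oligotrophs default to
#'   the tighter interdependence.
#' @param module_size target number of oligotroph taxa sharing one
#'   cooperation factor (>= 2); copiotroph associations are a quarter
#'   of this size (copiotrophs form smaller, looser associations).
#' @param competition_base amplitude in [0, 1] of the antagonistic
#'   coupling between paired oligotroph modules at dose 0 (the second
#'   module of a pair loads on the first module's factor with opposite
#'   sign — zero-sum competition whose strength is this amplitude).
#' @param competition_decay rate of the linear release of the
#'   antagonistic coupling with the DIN-implied dose (1 = fully
#'   released at the top of the design range).
#' @param oligo_extinction expected oligotroph dropout probability in
#'   the most copiotroph-dominated samples, in [0, 1]. The dropout gate
#'   follows the realized abundance-weighted copiotroph dominance
#'   (competitive exclusion) and falls preferentially on rare taxa, so
#'   richness declines while the abundant, correlation-carrying taxa
#'   are largely spared.
#' @param baseline_sd per-taxon baseline log-abundance sd.
#' @param noise_sd residual per-taxon, per-sample log-abundance noise sd.
#' @param copio_rrn_mean,oligo_rrn_mean mean rrn operon copy number by
#'   guild (support >= 1).
#' @param copio_gc_mean,oligo_gc_mean,gc_sd genomic GC fraction by guild.
#' @param rng_seed master seed; every generator stage derives its own
#'   stream from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_taxa = 20, reps_per_level = 3)
#' cfg$n_levels
sim_config <- function(n_levels = c(0, 1, 2, 4, 8, 16, 32, 64),
                       reps_per_level = 10,
                       n_taxa = 60,
                       frac_copiotroph = 0.38,
                       seq_depth = 20000,
                       dispersion = 15,
                       din_intercept = 4, din_slope = 3, din_sd = 2.5,
                       ph_intercept = 7.2, ph_slope = 0.25, ph_sd = 0.3,
                       plant_intercept = 12, plant_slope = 1, plant_sd = 1.5,
                       copio_din_response = 0.5,
                       copio_acid_tolerance = 0.53,
                       oligo_ph_sensitivity = 0.15,
                       copio_coop = 0.93,
                       oligo_coop = 1.8,
                       module_size = 18,
                       competition_base = 0.92,
                       competition_decay = 0.67,
                       oligo_extinction = 0.42,
                       baseline_sd = 0.8,
                       noise_sd = 0.24,
                       copio_rrn_mean = 5, oligo_rrn_mean = 2,
                       copio_gc_mean = 0.62, oligo_gc_mean = 0.55,
                       gc_sd = 0.03,
                       rng_seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) {
    ngn_abort("config must be built with sim_config()", "ngn_config_error")
  }
  with(cfg, {
    if (length(n_levels) == 0 || any(!is.finite(n_levels)) ||
        any(n_levels < 0)) {
      ngn_abort("n_levels must be a non-empty set of non-negative rates",
                "ngn_config_error")
    }
    if (anyDuplicated(n_levels)) {
      ngn_abort("n_levels must be distinct", "ngn_config_error")
    }
    if (!is_wholenumber(reps_per_level) || reps_per_level < 2) {
      ngn_abort("reps_per_level must be an integer >= 2", "ngn_config_error")
    }
    if (!is_wholenumber(n_taxa) || n_taxa < 10) {
      ngn_abort("n_taxa must be an integer >= 10", "ngn_config_error")
    }
    if (frac_copiotroph <= 0 || frac_copiotroph >= 1) {
      ngn_abort("frac_copiotroph must lie strictly inside (0, 1)",
                "ngn_config_error")
    }
    if (seq_depth <= 0) ngn_abort("seq_depth must be > 0", "ngn_config_error")
    if (dispersion <= 0) ngn_abort("dispersion must be > 0", "ngn_config_error")
    if (oligo_extinction < 0 || oligo_extinction > 1) {
      ngn_abort("oligo_extinction must lie in [0, 1]", "ngn_config_error")
    }
    for (nm in c("din_sd", "ph_sd", "plant_sd", "baseline_sd", "noise_sd",
                 "gc_sd")) {
      if (cfg[[nm]] < 0) {
        ngn_abort(sprintf("%s must be non-negative", nm), "ngn_config_error")
      }
    }
    if (copio_rrn_mean < 1 || oligo_rrn_mean < 1) {
      ngn_abort("rrn means must be >= 1", "ngn_config_error")
    }
    if (!is_wholenumber(module_size) || module_size < 2) {
      ngn_abort("module_size must be an integer >= 2", "ngn_config_error")
    }
    if (competition_base < 0 || competition_base > 1) {
      ngn_abort("competition_base must lie in [0, 1]", "ngn_config_error")
    }
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d N levels (%s) x %d replicates, %d taxa\n",
              length(x$n_levels), paste(x$n_levels, collapse = ", "),
              x$reps_per_level, x$n_taxa))
  cat(sprintf("  expected depth %g, NB size %g, seed %d\n",
              x$seq_depth, x$dispersion, x$rng_seed))
  invisible(x)
}

#' A fully-null generator configuration
#'
#' All gradient effect sizes, latent-factor loadings, and the extinction
#' probability set to zero: taxa are exchangeable and independent of the
#' N gradient. Used for calibration checks of the downstream tests.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_null <- function(...) {
  defaults <- list(
    din_slope = 0, ph_slope = 0, plant_slope = 0,
    copio_din_response = 0, copio_acid_tolerance = 0,
    oligo_ph_sensitivity = 0,
    copio_coop = 0, oligo_coop = 0,
    competition_base = 0, competition_decay = 0,
    oligo_extinction = 0
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# implied dose position from realized DIN; 0 when the DIN slope is off
implied_dose <- function(din, cfg) {
  lmax <- max(n_dose(cfg$n_levels))
  if (cfg$din_slope == 0) return(rep(0, length(din)))
  pmin(pmax((din - cfg$din_intercept) / cfg$din_slope, 0), lmax)
}
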