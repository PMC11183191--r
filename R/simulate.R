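#' Simulate plot-level metadata along the nitrogen gradient
#'
#' One row per plot. DIN increases, while pH and plant richness decrease,
#' linearly in the dose `log2(N + 1)`, with Gaussian plot noise. DIN is
#' kept positive and pH clipped to [3.5, 9].
#'
#' @param config a [sim_config()].
#' @return a tibble with columns `sample_id`, `n_rate`, `din`, `ph`,
#'   `plant_richness`.
#' @export
#' @examples
#' head(simulate_environment(sim_config(reps_per_level = 2)))
simulate_environment <- function(config) {
  config <- validate_sim_config(config)
  lev <- config$n_levels
  reps <- config$reps_per_level
  n <- length(lev) * reps
  withr::with_seed(derive_seed(config$rng_seed, "environment"), {
    n_rate <- rep(lev, each = reps)
    dose <- n_dose(n_rate)
    din <- config$din_intercept + config$din_slope * dose +
      rnorm(n, sd = config$din_sd)
    ph <- config$ph_intercept - config$ph_slope * dose +
      rnorm(n, sd = config$ph_sd)
    plant <- config$plant_intercept - config$plant_slope * dose +
      rnorm(n, sd = config$plant_sd)
  })
  tibble(
    sample_id = sprintf("N%s_r%02d", formatC(n_rate, width = 2, flag = "0"),
                        rep(seq_len(reps), times = length(lev))),
    n_rate = n_rate,
    din = pmax(din, 0.01),
    ph = pmin(pmax(ph, 3.5), 9),
    plant_richness = pmax(round(plant), 0)
  )
}

#' Simulate a per-taxon life-history trait table
#'
#' Guilds are drawn Bernoulli(`frac_copiotroph`); copiotrophs carry a
#' higher mean rrn operon copy number (shifted Poisson, support >= 1) and
#' higher genomic GC than oligotrophs, so the community-weighted trait
#' shifts the pipeline estimates are reproducible from the counts.
#'
#' @param config a [sim_config()].
#' @return a tibble with columns `taxon_id`, `guild`, `rrn_copies`,
#'   `gc_content`.
#' @export
simulate_traits <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_taxa
  withr::with_seed(derive_seed(config$rng_seed, "traits"), {
    guild <- ifelse(runif(n) < config$frac_copiotroph,
                    "copiotroph", "oligotroph")
    rrn_mean <- ifelse(guild == "copiotroph",
                       config$copio_rrn_mean, config$oligo_rrn_mean)
    rrn <- 1L + rpois(n, lambda = rrn_mean - 1)
    gc_mean <- ifelse(guild == "copiotroph",
                      config$copio_gc_mean, config$oligo_gc_mean)
    gc <- rnorm(n, mean = gc_mean, sd = config$gc_sd)
  })
  tibble(
    taxon_id = sprintf("OTU%04d", seq_len(n)),
    guild = guild,
    rrn_copies = rrn,
    gc_content = pmin(pmax(gc, 0.201), 0.799)
  )
}

#' Simulate an OTU count table from metadata and traits
#'
#' Latent log-abundance per taxon and sample is
#' baseline + guild response to standardized realized (DIN, pH)
#' + a module-level cooperation factor (taxa are grouped into modules
#' of ~`module_size` within each guild; members share one positive
#' factor, giving the networks their module structure)
#' + an antagonistic coupling between paired oligotroph modules (the
#' paired module loads on its partner's factor with opposite sign; the
#' coupling rotates away as the DIN-implied dose rises, so competition
#' is strong at low N and released by fertilization while module
#' variance stays constant)
#' + Gaussian noise. Copiotrophs and oligotrophs also acquire
#' between-guild negative correlations from the gradient itself
#' (opposite abundance responses). Oligotrophs additionally suffer a per-sample
#' extinction probability driven by the sample's realized
#' copiotroph-over-oligotroph latent dominance (competitive
#' exclusion), so richness declines through oligotroph loss as the
#' community shifts copiotrophic. Latent abundances are closed to
#' proportions and counts drawn negative-binomially at the configured
#' expected depth.
#'
#' @param config a [sim_config()].
#' @param metadata output of [simulate_environment()] for the same config.
#' @param traits output of [simulate_traits()] for the same config.
#' @return a wide count tibble (`taxon_id` + one integer column per
#'   sample) with the generative ground truth attached as attribute
#'   `"truth"`.
#' @export
simulate_abundances <- function(config, metadata, traits) {
  config <- validate_sim_config(config)
  n_samp <- length(config$n_levels) * config$reps_per_level
  if (nrow(metadata) != n_samp) {
    ngn_abort("metadata rows do not match config design", "ngn_config_error")
  }
  if (nrow(traits) != config$n_taxa) {
    ngn_abort("trait rows do not match config n_taxa", "ngn_config_error")
  }
  nt <- config$n_taxa
  copio <- traits$guild == "copiotroph"
  z_din <- zscore0(metadata$din)
  z_ph <- zscore0(metadata$ph)
  dose_hat <- implied_dose(metadata$din, config)
  dmax <- max(n_dose(config$n_levels))
  decay <- if (dmax > 0) {
    pmax(1 - config$competition_decay * dose_hat / dmax, 0)
  } else {
    rep(1, n_samp)
  }
  comp_scale <- config$competition_base * decay

  withr::with_seed(derive_seed(config$rng_seed, "abundances"), {
    baseline <- rnorm(nt, sd = config$baseline_sd)
    resp_jit <- runif(nt, 0.6, 1.4)
    coop_load <- ifelse(copio, config$copio_coop, config$oligo_coop) *
      runif(nt, 0.7, 1.3)

    # module memberships: consecutive blocks per guild; copiotroph
    # associations are a quarter of the oligotroph module size
    cms <- max(2L, config$module_size %/% 4L)
    module <- integer(nt)
    module[copio] <- (seq_len(sum(copio)) - 1L) %/% cms + 1L
    module[!copio] <- max(module, 0L) +
      (seq_len(sum(!copio)) - 1L) %/% config$module_size + 1L
    n_mod <- max(module)
    f_mod <- matrix(rnorm(n_mod * n_samp), n_mod, n_samp)

    # antagonistic coupling between consecutive pairs of oligotroph
    # modules: the second module of a pair loads on the first module's
    # factor with opposite sign, rotated away as the dose rises, so the
    # negative block decays while every taxon's variance is unchanged
    omods <- sort(unique(module[!copio]))
    pairs <- NULL
    f_eff <- f_mod
    if (length(omods) >= 2 && any(comp_scale > 0)) {
      np <- length(omods) %/% 2
      pairs <- cbind(omods[2 * seq_len(np) - 1], omods[2 * seq_len(np)])
      for (p in seq_len(np)) {
        a <- pairs[p, 1]
        b <- pairs[p, 2]
        s <- pmin(comp_scale, 1)
        f_eff[b, ] <- -s * f_mod[a, ] + sqrt(1 - s^2) * f_mod[b, ]
      }
    }

    # copiotrophs follow DIN and benefit from acidification;
    # oligotrophs decline with pH
    env <- matrix(0, nt, n_samp)
    env[copio, ] <- resp_jit[copio] %o%
      (config$copio_din_response * z_din -
         config$copio_acid_tolerance * z_ph)
    env[!copio, ] <- (resp_jit[!copio] *
                        config$oligo_ph_sensitivity) %o% z_ph
    resp <- resp_jit * ifelse(copio,
                              config$copio_din_response +
                                config$copio_acid_tolerance,
                              config$oligo_ph_sensitivity)
    coop <- (coop_load %o% rep(1, n_samp)) * f_eff[module, , drop = FALSE]
    eta <- baseline %o% rep(1, n_samp) + env + coop +
      matrix(rnorm(nt * n_samp, sd = config$noise_sd), nt, n_samp)

    rel <- exp(eta)
    rel <- sweep(rel, 2, colSums(rel), "/")

    # competitive-exclusion dropout: the gate is the realized
    # abundance-weighted copiotroph dominance (the same quantity the
    # community copiotroph/oligotroph ratio measures), normalized over
    # the realized gradient, so oligotroph local extinction follows
    # the community state itself
    p_ext <- rep(0, n_samp)
    if (any(copio) && any(!copio) && config$oligo_extinction > 0) {
      lr <- log(colSums(rel[copio, , drop = FALSE])) -
        log(colSums(rel[!copio, , drop = FALSE]))
      rng <- max(lr) - min(lr)
      gate <- if (rng > 0) (lr - min(lr)) / rng else rep(0, n_samp)
      p_ext <- config$oligo_extinction * gate
    }
    # dropout targets rare oligotrophs: small populations go locally
    # extinct first, so richness (and network nodes) decline while the
    # abundance mass carrying the correlation structure is spared
    extinct <- matrix(0, nt, n_samp)
    if (any(!copio) && any(p_ext > 0)) {
      bl <- baseline[!copio]
      pct <- (rank(bl) - 1) / max(length(bl) - 1, 1)
      w <- 0.02 + 6.86 * (1 - pct)^6
      pmat <- matrix(1 - (1 - rep(p_ext, each = length(w)))^w,
                     length(w), n_samp)
      extinct[!copio, ] <- matrix(
        rbinom(length(w) * n_samp, 1, as.vector(pmat)),
        length(w), n_samp)
    }
    rel[extinct == 1] <- 0
    rel <- sweep(rel, 2, colSums(rel), "/")
    counts <- matrix(
      rnbinom(nt * n_samp, mu = config$seq_depth * as.vector(rel),
              size = config$dispersion), nt, n_samp)
  })
  dimnames(counts) <- list(traits$taxon_id, metadata$sample_id)
  out <- matrix_to_tbl(counts)
  attr(out, "truth") <- list(
    taxa = tibble(
      taxon_id = traits$taxon_id, guild = traits$guild,
      baseline = baseline, response = resp,
      module = module,
      coop_loading = coop_load
    ),
    antagonist_pairs = pairs,
    sample = tibble(
      sample_id = metadata$sample_id, implied_dose = dose_hat,
      competition_scale = comp_scale, extinction_prob = p_ext
    ),
    effect_signs = list(din = sign(config$din_slope),
                        ph = -sign(config$ph_slope),
                        plant = -sign(config$plant_slope),
                        copiotroph_share = sign(config$copio_din_response),
                        oligotroph_richness = -sign(config$oligo_extinction),
                        competition = -sign(config$competition_base)),
    config = unclass(config)
  )
  out
}

# environmental driver per taxon: copiotrophs follow DIN, oligotrophs pH
rbind_env <- function(copio, z_din, z_ph) {
  m <- matrix(0, length(copio), length(z_din))
  m[copio, ] <- matrix(z_din, sum(copio), length(z_din), byrow = TRUE)
  m[!copio, ] <- matrix(z_ph, sum(!copio), length(z_ph), byrow = TRUE)
  m
}

#' Simulate a complete, mutually consistent dataset bundle
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_bundle` with elements `counts`,
#'   `metadata`, `traits`, `truth`, and `config`.
#' @export
#' @examples
#' b <- simulate_dataset(sim_config(n_taxa = 15, reps_per_level = 3,
#'                                  seq_depth = 500))
#' dim(b$counts)
simulate_dataset <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  metadata <- simulate_environment(config)
  traits <- simulate_traits(config)
  counts <- simulate_abundances(config, metadata, traits)
  truth <- attr(counts, "truth")
  attr(counts, "truth") <- NULL
  structure(list(counts = counts, metadata = metadata, traits = traits,
                 truth = truth, config = config),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d taxa x %d samples, %d N levels\n",
              nrow(x$counts), ncol(x$counts) - 1L, length(x$config$n_levels)))
  invisible(x)
}
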