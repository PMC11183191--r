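test_that("environment table follows the experimental design", {
  cfg <- sim_config(reps_per_level = 5)
  md <- simulate_environment(cfg)
  expect_equal(nrow(md), 8 * 5)
  expect_setequal(unique(md$n_rate), c(0, 1, 2, 4, 8, 16, 32, 64))
  expect_true(all(md$din > 0))
  expect_true(all(md$ph > 3.4 & md$ph < 9.1))
  expect_false(anyDuplicated(md$sample_id) > 0)
})

test_that("null environmental effects give constant DIN and pH", {
  cfg <- sim_config(din_slope = 0, ph_slope = 0, din_sd = 0, ph_sd = 0)
  md <- simulate_environment(cfg)
  expect_equal(length(unique(md$din)), 1L)
  expect_equal(length(unique(md$ph)), 1L)
})

test_that("DIN increases along the gradient in almost every realization", {
  hits <- 0
  for (sd in 1:200) {
    md <- simulate_environment(sim_config(reps_per_level = 2, rng_seed = sd))
    hits <- hits + (mean(md$din[md$n_rate == 64]) >
                      mean(md$din[md$n_rate == 0]))
  }
  expect_gte(hits / 200, 0.99)
})

test_that("guild assignment is binomial and traits respect their support", {
  tr <- simulate_traits(sim_config(n_taxa = 200, frac_copiotroph = 0.5))
  n_cop <- sum(tr$guild == "copiotroph")
  band <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(n_cop, band[1])
  expect_lte(n_cop, band[2])
  expect_true(all(tr$rrn_copies >= 1))
  expect_true(all(tr$gc_content > 0.2 & tr$gc_content < 0.8))
  # copiotrophs carry the faster-growth trait syndrome on average
  expect_gt(mean(tr$rrn_copies[tr$guild == "copiotroph"]),
            mean(tr$rrn_copies[tr$guild == "oligotroph"]))
  expect_gt(mean(tr$gc_content[tr$guild == "copiotroph"]),
            mean(tr$gc_content[tr$guild == "oligotroph"]))
})

test_that("generation is deterministic given a seed and seed-sensitive", {
  cfg <- small_config(rng_seed = 11)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$metadata, b2$metadata)
  expect_identical(b1$traits, b2$traits)
  b3 <- simulate_dataset(small_config(rng_seed = 12))
  expect_false(identical(b1$counts, b3$counts))
})

test_that("certain extinction removes all oligotrophs at the top dose", {
  cfg <- small_config(oligo_extinction = 1,
                      din_sd = 0, ph_sd = 0, noise_sd = 0,
                      copio_coop = 0, oligo_coop = 0, competition_base = 0)
  b <- simulate_dataset(cfg)
  m <- as.matrix(b$counts[-1])
  rownames(m) <- b$counts$taxon_id
  olig <- b$traits$taxon_id[b$traits$guild == "oligotroph"]
  top <- b$metadata$sample_id[b$metadata$n_rate == 64]
  expect_true(all(m[olig, top] == 0))
})

test_that("dataset bundle is self-consistent and round-trips through io", {
  b <- simulate_dataset(small_config(rng_seed = 3))
  expect_s3_class(validate_bundle(b$counts, b$metadata, b$traits),
                  "ngn_bundle")
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  expect_equal(back$counts, b$counts)
  expect_equal(back$traits[names(b$traits)], b$traits)
  expect_equal(back$metadata$din, b$metadata$din, tolerance = 1e-12)
})

test_that("a fully null generator yields no spurious richness trend", {
  # with every effect size zero, the dose regression of richness must
  # reject at no more than its nominal level
  rejected <- 0
  usable <- 0
  for (sd in 1:100) {
    cfg <- sim_config_null(n_taxa = 20, reps_per_level = 3,
                           seq_depth = 120, module_size = 6, rng_seed = sd)
    b <- simulate_dataset(cfg)
    rich <- observed_richness(b$counts)
    d <- dplyr::left_join(rich, b$metadata[c("sample_id", "n_rate")],
                          by = "sample_id")
    if (length(unique(d$richness)) < 2) next
    usable <- usable + 1
    p <- tidy(gradient_trend(d, "richness"))$p_value[2]
    if (is.finite(p) && p < 0.01) rejected <- rejected + 1
  }
  expect_gte(usable, 50)
  expect_gte(1 - rejected / usable, 0.95)
})

test_that("default gradient shifts composition in the generative directions", {
  b <- simulate_dataset(sim_config(rng_seed = 5))
  rel <- to_relative_abundance(b$counts)
  m <- as.matrix(rel[-1])
  rownames(m) <- rel$taxon_id
  cop <- b$traits$taxon_id[b$traits$guild == "copiotroph"]
  share <- colSums(m[cop, , drop = FALSE])
  lo <- b$metadata$n_rate %in% c(0, 1)
  hi <- b$metadata$n_rate %in% c(32, 64)
  expect_gt(mean(share[hi]), mean(share[lo]))
  expect_gt(mean(b$metadata$din[hi]), mean(b$metadata$din[lo]))
  expect_lt(mean(b$metadata$ph[hi]), mean(b$metadata$ph[lo]))
})
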