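# Small, fast generator configurations used across tests. The default
# sim_config() is the full study design; these shrink it for speed
# without touching the default effect sizes unless a test needs to.

small_config <- function(...) {
  sim_config(n_taxa = 16, reps_per_level = 4, seq_depth = 800,
             module_size = 6, ...)
}

tiny_counts <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    s1 = c(0L, 3L, 1L),
    s2 = c(2L, 3L, 0L)
  )
}

tiny_metadata <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2"),
    n_rate = c(0, 64),
    din = c(4, 20),
    ph = c(7, 5.8),
    plant_richness = c(12, 6)
  )
}

tiny_traits <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    guild = c("copiotroph", "oligotroph", "unclassified"),
    rrn_copies = c(6, 2, NA),
    gc_content = c(0.63, 0.55, NA)
  )
}

random_relabund <- function(nt, ns, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rexp(nt * ns), nt, ns)
  })
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(sprintf("t%02d", seq_len(nt)),
                      sprintf("s%02d", seq_len(ns)))
  dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)),
                   tibble::as_tibble(m))
}
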