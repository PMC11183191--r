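#' Heuristic phylum-to-guild lookup table
#'
#' A coarse default mapping of common soil bacterial phyla to
#' copiotroph/oligotroph guilds, shipped for convenience when no
#' curated per-taxon annotation is available. It is a heuristic:
#' trophic strategy varies within phyla, and a user-supplied trait
#' table (e.g. from rrn-database lookups) should be preferred whenever
#' possible. Phyla not listed map to `unclassified`.
#'
#' @return a tibble with columns `phylum`, `guild`.
#' @export
#' @examples
#' default_guild_map()
default_guild_map <- function() {
  readr::read_tsv(system.file("extdata", "guild_phylum_map.tsv",
                              package = "ngradnet"),
                  show_col_types = FALSE, progress = FALSE)
}
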