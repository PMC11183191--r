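# Readers and writers for the three tabular inputs. TSV dialect: header
# row, tab separated, UTF-8, no quoting; fixed column order on write.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) {
    ngn_abort(sprintf("file not found: %s", path), "ngn_io_error")
  }
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    ngn_abort(sprintf("malformed TSV %s: row %d, %s", path,
                      probs$row[1L], probs$expected[1L]), "ngn_parse_error")
  }
  out
}

require_columns <- function(tbl, cols, path) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0) {
    ngn_abort(sprintf("missing column: %s", miss[1L]), "ngn_parse_error")
  }
  invisible(tbl)
}

#' Read and validate an OTU count table
#'
#' Expects a TSV whose first column (`taxon_id`) holds unique taxon
#' identifiers and whose remaining columns are non-negative integer
#' counts, one column per sample.
#'
#' @param path path to a tab-separated count file.
#' @return a wide count tibble (`taxon_id` + one column per sample).
#' @export
read_count_table <- function(path) {
  tbl <- read_tsv_strict(path)
  if (ncol(tbl) < 2) ngn_abort("count table needs taxon ids plus >= 1 sample",
                               "ngn_parse_error")
  names(tbl)[1L] <- "taxon_id"
  tbl$taxon_id <- as.character(tbl$taxon_id)
  dup <- tbl$taxon_id[duplicated(tbl$taxon_id)]
  if (length(dup) > 0) {
    ngn_abort(sprintf("duplicate taxon id: %s", dup[1L]), "ngn_parse_error")
  }
  sid <- setdiff(names(tbl), "taxon_id")
  if (anyDuplicated(sid)) {
    ngn_abort("duplicate sample id in header", "ngn_parse_error")
  }
  for (s in sid) {
    v <- tbl[[s]]
    if (!is.numeric(v) || any(!is_wholenumber(v)) || any(v < 0)) {
      bad <- which(!is.numeric(v) | !is_wholenumber(v) | v < 0)[1L]
      ngn_abort(sprintf(
        "negative or non-integer count for taxon %s in sample %s",
        tbl$taxon_id[bad], s), "ngn_parse_error")
    }
    tbl[[s]] <- as.integer(round(v))
  }
  tbl
}

#' Write an OTU count table
#' @param counts wide count tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read and validate per-sample metadata
#'
#' Required columns: `sample_id`, `n_rate` (g N m^-2 y^-1), `din`, `ph`,
#' `plant_richness`. pH must lie in (0, 14) and N rates be non-negative.
#'
#' @param path path to a tab-separated metadata file.
#' @return a validated tibble.
#' @export
read_metadata <- function(path) {
  tbl <- read_tsv_strict(path)
  require_columns(tbl, c("sample_id", "n_rate", "din", "ph",
                         "plant_richness"), path)
  tbl$sample_id <- as.character(tbl$sample_id)
  if (anyDuplicated(tbl$sample_id)) {
    ngn_abort("duplicate sample id in metadata", "ngn_parse_error")
  }
  if (any(tbl$n_rate < 0)) ngn_abort("negative n_rate", "ngn_parse_error")
  if (any(tbl$ph <= 0 | tbl$ph >= 14)) {
    ngn_abort("pH out of range (0, 14)", "ngn_parse_error")
  }
  tbl
}

#' Write per-sample metadata
#' @param metadata metadata tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  cols <- c("sample_id", "n_rate", "din", "ph", "plant_richness")
  readr::write_tsv(metadata[c(cols, setdiff(names(metadata), cols))], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and validate a per-taxon trait table
#'
#' Required columns: `taxon_id`, `guild` (copiotroph / oligotroph /
#' unclassified), `rrn_copies` (>= 1 or missing), `gc_content` (in (0, 1)
#' or missing).
#'
#' @param path path to a tab-separated trait file.
#' @return a validated tibble.
#' @export
read_trait_table <- function(path) {
  tbl <- read_tsv_strict(path)
  require_columns(tbl, c("taxon_id", "guild", "rrn_copies", "gc_content"),
                  path)
  tbl$taxon_id <- as.character(tbl$taxon_id)
  if (anyDuplicated(tbl$taxon_id)) {
    ngn_abort("duplicate taxon id in trait table", "ngn_parse_error")
  }
  ok <- tbl$guild %in% c("copiotroph", "oligotroph", "unclassified")
  if (any(!ok)) {
    ngn_abort(sprintf("unknown guild label: %s", tbl$guild[!ok][1L]),
              "ngn_parse_error")
  }
  if (any(tbl$rrn_copies < 1, na.rm = TRUE)) {
    ngn_abort("rrn_copies must be >= 1", "ngn_parse_error")
  }
  if (any(tbl$gc_content <= 0 | tbl$gc_content >= 1, na.rm = TRUE)) {
    ngn_abort("gc_content must lie in (0, 1)", "ngn_parse_error")
  }
  tbl
}

#' Write a per-taxon trait table
#' @param traits trait tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  cols <- c("taxon_id", "guild", "rrn_copies", "gc_content")
  readr::write_tsv(traits[c(cols, setdiff(names(traits), cols))], path,
                   progress = FALSE)
  invisible(path)
}

#' Cross-validate counts, metadata, and traits into one bundle
#'
#' Checks that every count sample is described in the metadata (extra
#' metadata rows are dropped, metadata reordered to the count order),
#' that no sample column sums to zero, and pads the trait table so every
#' taxon is present (missing taxa become guild `unclassified` with
#' missing numeric traits).
#'
#' @param counts wide count tibble.
#' @param metadata per-sample metadata tibble.
#' @param traits per-taxon trait tibble (may cover only some taxa).
#' @return a list of class `ngn_bundle` with elements `counts`,
#'   `metadata`, `traits`.
#' @export
validate_bundle <- function(counts, metadata, traits) {
  sid <- sample_ids(counts)
  if (length(intersect(sid, metadata$sample_id)) == 0) {
    ngn_abort("no sample ids shared between counts and metadata",
              "ngn_validate_error")
  }
  miss <- setdiff(sid, metadata$sample_id)
  if (length(miss) > 0) {
    ngn_abort(sprintf("sample missing from metadata: %s", miss[1L]),
              "ngn_validate_error")
  }
  metadata <- metadata[match(sid, metadata$sample_id), , drop = FALSE]
  m <- abund_matrix(counts)
  zero <- colSums(m) == 0
  if (any(zero)) {
    ngn_abort(sprintf("sample with zero total count: %s",
                      sid[zero][1L]), "ngn_validate_error")
  }
  extra <- setdiff(counts$taxon_id, traits$taxon_id)
  if (length(extra) > 0) {
    traits <- dplyr::bind_rows(
      traits,
      tibble(taxon_id = extra, guild = "unclassified",
             rrn_copies = NA_real_, gc_content = NA_real_))
  }
  traits <- traits[match(counts$taxon_id, traits$taxon_id), , drop = FALSE]
  structure(list(counts = counts, metadata = metadata, traits = traits),
            class = "ngn_bundle")
}

#' Write a simulated bundle to a directory
#'
#' Writes `counts.tsv`, `metadata.tsv`, `traits.tsv`, plus the ground
#' truth and the config echo as JSON.
#'
#' @param bundle a `sim_bundle` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(bundle$counts, file.path(dir, "counts.tsv"))
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  write_trait_table(bundle$traits, file.path(dir, "traits.tsv"))
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(bundle$config)) {
    jsonlite::write_json(unclass(bundle$config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a dataset bundle from a directory
#'
#' @param dir directory holding `counts.tsv`, `metadata.tsv`, `traits.tsv`.
#' @return a validated `ngn_bundle`.
#' @export
read_bundle <- function(dir) {
  validate_bundle(read_count_table(file.path(dir, "counts.tsv")),
                  read_metadata(file.path(dir, "metadata.tsv")),
                  read_trait_table(file.path(dir, "traits.tsv")))
}
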