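default_schema <- function() {
  c(sample_group = "sample_group", replicate = "replicate",
    region_id = "region_id", modifications = "modifications",
    peak_area = "peak_area")
}

#' Read a YAML column-schema mapping
#'
#' Maps arbitrary exported column names onto the canonical schema
#' (`sample_group`, `replicate`, `region_id`, `modifications`, `peak_area`).
#'
#' @param path Path to a YAML file whose keys are canonical names and values
#'   the column names found in the table.
#' @return Named character vector usable as the `schema` argument of
#'   [read_peak_area_table()].
#' @export
read_schema_config <- function(path) {
  raw <- yaml::read_yaml(path)
  schema <- default_schema()
  for (key in names(raw)) {
    if (!key %in% names(schema)) {
      rlang::abort(sprintf("unknown schema key '%s'", key),
                   class = "histoneptm_schema_error")
    }
    schema[[key]] <- as.character(raw[[key]])
  }
  schema
}

#' Read and canonicalize a peptidoform peak-area table
#'
#' Accepts TSV or CSV (sniffed from the header line unless `delim` is given)
#' with one row per sample x replicate x peptide region x modified form.
#' Modification strings are canonicalized (see [canonicalize_modstring()]);
#' rows with missing, non-numeric or negative areas and duplicate
#' (sample, replicate, region, form) keys are rejected with their row number.
#'
#' @param path File path.
#' @param schema Named character vector mapping canonical column names to the
#'   file's column names; see [read_schema_config()].
#' @param delim `"\t"`, `","`, or `NULL` to sniff.
#' @return Tibble of canonical records: `sample_group`, `replicate`,
#'   `region_id`, `modifications`, `peak_area`.
#' @export
read_peak_area_table <- function(path, schema = default_schema(), delim = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "histoneptm_io_error")
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(header)) {
    rlang::abort(sprintf("empty peptidoform table: %s", path),
                 class = "histoneptm_io_error")
  }
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")),
                 class = "histoneptm_schema_error")
  }
  if (nrow(raw) == 0L) {
    rlang::abort(sprintf("peptidoform table has a header but no rows: %s", path),
                 class = "histoneptm_io_error")
  }
  out <- tibble::tibble(
    sample_group = raw[[schema[["sample_group"]]]],
    replicate = raw[[schema[["replicate"]]]],
    region_id = raw[[schema[["region_id"]]]],
    modifications = raw[[schema[["modifications"]]]],
    peak_area = raw[[schema[["peak_area"]]]]
  )

  area <- suppressWarnings(as.numeric(out$peak_area))
  bad_area <- which(is.na(area) | area < 0)
  if (length(bad_area) > 0L) {
    rlang::abort(sprintf("non-numeric or negative peak_area on data row(s): %s",
                         paste(bad_area, collapse = ", ")),
                 class = "histoneptm_bad_area")
  }
  rep_i <- suppressWarnings(as.integer(out$replicate))
  bad_rep <- which(is.na(rep_i) | rep_i < 1L)
  if (length(bad_rep) > 0L) {
    rlang::abort(sprintf("invalid replicate index on data row(s): %s",
                         paste(bad_rep, collapse = ", ")),
                 class = "histoneptm_bad_replicate")
  }
  out$peak_area <- area
  out$replicate <- rep_i
  out$modifications <- canonicalize_modstring(out$modifications, out$region_id)
  validate_records(out)
}

#' Validate a canonical record tibble
#'
#' Checks the uniqueness and non-negativity invariants of a peptidoform
#' record set after canonicalization.
#'
#' @param records Tibble with the canonical columns.
#' @return The records, invisibly unchanged (arranged for determinism).
#' @export
validate_records <- function(records) {
  needed <- names(default_schema())
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("records lack column(s): %s", paste(missing_cols, collapse = ", ")),
                 class = "histoneptm_schema_error")
  }
  key <- paste(records$sample_group, records$replicate, records$region_id,
               records$modifications, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    rlang::abort(sprintf("duplicate (sample, replicate, region, form) on data row(s): %s",
                         paste(dup, collapse = ", ")),
                 class = "histoneptm_duplicate_rows")
  }
  if (any(records$peak_area < 0)) {
    rlang::abort("negative peak areas present", class = "histoneptm_bad_area")
  }
  dplyr::arrange(records, .data$sample_group, .data$replicate, .data$region_id,
                 .data$modifications)
}

#' Write records in the native dialect
#'
#' UTF-8, tab-delimited, `"."` decimal separator.
#'
#' @param records Canonical record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptidoform_table <- function(records, path) {
  readr::write_tsv(validate_records(records), path, progress = FALSE)
  invisible(path)
}

#' Merge sample groups by summing areas per replicate pair
#'
#' Relabels the source groups to `target`, pairing replicate `i` of each
#' source and summing peak areas per (replicate, region, form). Unpaired
#' replicates are kept with the available areas, mirroring unequal detection
#' across tissues. Used to pool root- and shoot-derived samples of one
#' biological replicate into a whole-seedling record.
#'
#' @param records Canonical record tibble.
#' @param sources Character vector (length >= 2 distinct labels) of groups to
#'   merge.
#' @param target New group label; must not already exist.
#' @return Record tibble with the source groups replaced by `target`.
#' @export
merge_groups <- function(records, sources, target) {
  records <- validate_records(records)
  sources <- as.character(sources)
  if (anyDuplicated(sources) > 0L) {
    rlang::abort("merging a group with itself is not meaningful", class = "histoneptm_merge_error")
  }
  absent <- setdiff(sources, unique(records$sample_group))
  if (length(absent) > 0L) {
    rlang::abort(sprintf("source group(s) not present: %s", paste(absent, collapse = ", ")),
                 class = "histoneptm_merge_error")
  }
  if (target %in% unique(records$sample_group)) {
    rlang::abort(sprintf("target group label '%s' already present", target),
                 class = "histoneptm_merge_error")
  }
  merged <- records |>
    dplyr::filter(.data$sample_group %in% sources) |>
    dplyr::mutate(sample_group = target) |>
    dplyr::group_by(.data$sample_group, .data$replicate, .data$region_id,
                    .data$modifications) |>
    dplyr::summarise(peak_area = sum(.data$peak_area), .groups = "drop")
  rest <- dplyr::filter(records, !.data$sample_group %in% sources)
  validate_records(dplyr::bind_rows(rest, merged))
}
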