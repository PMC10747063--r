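#' Relative abundances of peptidoforms
#'
#' Converts peak areas into per-(sample, replicate, region) compositions: each
#' observed form's fraction is its area over the total area of the peptide in
#' that replicate, so every composition is closed to 1. Forms absent from a
#' replicate are not observed (no row), never zero.
#'
#' @param records Canonical record tibble (see [read_peak_area_table()]).
#' @param sample_group,replicate,region_id Optional filters.
#' @return Tibble `sample_group`, `replicate`, `region_id`, `modifications`,
#'   `fraction`.
#' @export
relative_abundance <- function(records, sample_group = NULL, replicate = NULL,
                               region_id = NULL) {
  records <- validate_records(records)
  if (!is.null(sample_group)) records <- records[records$sample_group %in% sample_group, ]
  if (!is.null(replicate)) records <- records[records$replicate %in% replicate, ]
  if (!is.null(region_id)) records <- records[records$region_id %in% region_id, ]
  if (nrow(records) == 0L) {
    rlang::abort("no records match the requested keys", class = "histoneptm_no_records")
  }
  out <- records |>
    dplyr::group_by(.data$sample_group, .data$replicate, .data$region_id) |>
    dplyr::mutate(.total = sum(.data$peak_area)) |>
    dplyr::ungroup()
  bad <- out[out$.total <= 0, c("sample_group", "replicate", "region_id")]
  if (nrow(bad) > 0L) {
    bad <- unique(bad)
    rlang::abort(sprintf("total peak area is zero; unquantifiable key(s): %s",
                         paste(sprintf("(%s, rep %d, %s)", bad$sample_group,
                                       bad$replicate, bad$region_id), collapse = "; ")),
                 class = "histoneptm_zero_total")
  }
  out |>
    dplyr::mutate(fraction = .data$peak_area / .data$.total) |>
    dplyr::select("sample_group", "replicate", "region_id", "modifications",
                  "fraction")
}

#' Format an H3.1:H3.3 ratio as printed text
#'
#' One decimal, `"a:1"`, with the integer style (`"3:1"`) used when the
#' rounded ratio has no fractional part except in the balanced case, printed
#' `"1.0:1.0"`. Presentational only; never used in computation.
#'
#' @param p_h31 H3.1 fraction in (0, 1).
#' @return String such as `"3:1"`, `"1.3:1"`, `"1.0:1.0"`.
#' @export
format_variant_ratio <- function(p_h31) {
  a <- round(p_h31 / (1 - p_h31), 1)
  if (abs(a - 1) < 1e-12) return("1.0:1.0")
  if (abs(a - round(a)) < 1e-12) sprintf("%d:1", as.integer(round(a)))
  else sprintf("%.1f:1", a)
}

#' H3 variant proportions from the unique K27--R40 peptides
#'
#' Per replicate, the H3.1 proportion is the total H3.1K27--R40 peak area
#' over the summed total of both variant peptides; the group value is the
#' median across replicates (per-replicate values are retained for box-plots
#' and t-tests).
#'
#' @param records Canonical record tibble containing both variant regions.
#' @param sample_group Optional group filter.
#' @return List with `replicates` (tibble `sample_group`, `replicate`,
#'   `p_h31`, `p_h33`) and `group` (tibble `sample_group`, `n_replicates`,
#'   `p_h31`, `p_h33`, `ratio_text`).
#' @export
variant_proportion <- function(records, sample_group = NULL) {
  records <- validate_records(records)
  if (!is.null(sample_group)) records <- records[records$sample_group %in% sample_group, ]
  v <- records |>
    dplyr::filter(.data$region_id %in% c("H3.1K27-R40", "H3.3K27-R40")) |>
    dplyr::group_by(.data$sample_group, .data$replicate, .data$region_id) |>
    dplyr::summarise(total = sum(.data$peak_area), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region_id", values_from = "total")
  for (col in c("H3.1K27-R40", "H3.3K27-R40")) {
    if (!col %in% names(v)) v[[col]] <- NA_real_
  }
  v <- v[!is.na(v[["H3.1K27-R40"]]) & !is.na(v[["H3.3K27-R40"]]), ]
  if (nrow(v) == 0L) {
    rlang::abort("no replicate has both H3.1 and H3.3 K27-R40 peptides quantified",
                 class = "histoneptm_no_shared_replicates")
  }
  reps <- tibble::tibble(
    sample_group = v$sample_group,
    replicate = v$replicate,
    p_h31 = v[["H3.1K27-R40"]] / (v[["H3.1K27-R40"]] + v[["H3.3K27-R40"]])
  )
  reps$p_h33 <- 1 - reps$p_h31
  grp <- reps |>
    dplyr::group_by(.data$sample_group) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     p_h31 = stats::median(.data$p_h31), .groups = "drop") |>
    dplyr::mutate(p_h33 = 1 - .data$p_h31,
                  ratio_text = vapply(.data$p_h31, format_variant_ratio, character(1)))
  list(replicates = dplyr::arrange(reps, .data$sample_group, .data$replicate),
       group = dplyr::arrange(grp, .data$sample_group))
}

#' Marginalize a composition onto one site
#'
#' Sums peptidoform fractions over all co-modification states to obtain the
#' abundance of each mutually exclusive mark (unmod/me1/me2/me3/ac) at one
#' residue; closure is inherited from the composition.
#'
#' @param composition Composition tibble from [relative_abundance()].
#' @param site Site label, e.g. `"K27"`; must belong to each composition's
#'   region.
#' @return Tibble `sample_group`, `replicate`, `region_id`, `variant_scope`,
#'   `site`, `mark`, `fraction` (marks absent from all forms get fraction 0).
#' @export
marginalize_site <- function(composition, site) {
  regs <- unique(composition$region_id)
  for (r in regs) {
    reg <- region_info(r)
    if (!site %in% reg$sites[[1]]) {
      rlang::abort(sprintf("site '%s' is not in region '%s'", site, r),
                   class = "histoneptm_bad_site")
    }
  }
  scope <- stats::setNames(peptide_regions()$variant_scope, peptide_regions()$region_id)
  # parse each distinct (region, form) once; forms repeat across replicates
  lut <- dplyr::distinct(composition, .data$region_id, .data$modifications)
  lut$mark <- vapply(seq_len(nrow(lut)), function(i) {
    parse_modstring(lut$modifications[i], lut$region_id[i], quiet = TRUE)[[site]]
  }, character(1))
  out <- composition |>
    dplyr::left_join(lut, by = c("region_id", "modifications")) |>
    dplyr::mutate(variant_scope = unname(scope[.data$region_id])) |>
    dplyr::group_by(.data$sample_group, .data$replicate, .data$region_id,
                    .data$variant_scope, mark = .data$mark) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop")
  # complete over the admissible marks so downstream tables are rectangular
  grid <- dplyr::bind_rows(lapply(regs, function(r) {
    tibble::tibble(region_id = r, mark = allowed_marks(site, r))
  }))
  keys <- dplyr::distinct(out, .data$sample_group, .data$replicate,
                          .data$region_id, .data$variant_scope)
  dplyr::inner_join(keys, grid, by = "region_id",
                    relationship = "many-to-many") |>
    dplyr::left_join(out, by = c("sample_group", "replicate", "region_id",
                                 "variant_scope", "mark")) |>
    dplyr::mutate(fraction = dplyr::coalesce(.data$fraction, 0), site = site) |>
    dplyr::select("sample_group", "replicate", "region_id", "variant_scope",
                  "site", "mark", "fraction") |>
    dplyr::arrange(.data$sample_group, .data$replicate, .data$region_id,
                   .data$mark)
}

#' Variant-weighted site-mark profile
#'
#' Combines the variant-resolved K27/K36 mark profiles into the overall
#' (variant-agnostic) profile, weighting by the sample's H3.1/H3.3
#' proportions: `combined = p_h31 * H3.1 + (1 - p_h31) * H3.3`. This is how
#' marks on the variant-distinguishing K27--R40 peptide are quantified
#' "regardless of origin" while the variant ratio is still honoured.
#'
#' @param profile_h31,profile_h33 Site-mark tibbles from
#'   [marginalize_site()], restricted to the H3.1 / H3.3 regions, matching in
#'   sample, replicate and site.
#' @param vp Variant proportions from [variant_proportion()].
#' @param weights `"group-median"` (default; the reported quantification) or
#'   `"replicate"` to weight each replicate by its own proportion.
#' @return Site-mark tibble with `variant_scope = "combined"`.
#' @export
combine_variants <- function(profile_h31, profile_h33, vp,
                             weights = c("group-median", "replicate")) {
  weights <- match.arg(weights)
  if (!all(profile_h31$variant_scope == "H3.1") ||
      !all(profile_h33$variant_scope == "H3.3")) {
    rlang::abort("profiles must be variant-resolved (H3.1 and H3.3 scopes)",
                 class = "histoneptm_scope_error")
  }
  if (!setequal(unique(profile_h31$site), unique(profile_h33$site))) {
    rlang::abort("site mismatch between variant profiles", class = "histoneptm_scope_error")
  }
  key <- c("sample_group", "replicate", "site", "mark")
  joined <- dplyr::inner_join(
    dplyr::select(profile_h31, dplyr::all_of(key), f31 = "fraction"),
    dplyr::select(profile_h33, dplyr::all_of(key), f33 = "fraction"),
    by = key
  )
  if (nrow(joined) == 0L) {
    rlang::abort("no matching (sample, replicate, site, mark) rows between profiles",
                 class = "histoneptm_scope_error")
  }
  if (weights == "group-median") {
    w <- dplyr::select(vp$group, "sample_group", "p_h31")
    joined <- dplyr::inner_join(joined, w, by = "sample_group")
  } else {
    w <- dplyr::select(vp$replicates, "sample_group", "replicate", "p_h31")
    joined <- dplyr::inner_join(joined, w, by = c("sample_group", "replicate"))
  }
  joined |>
    dplyr::mutate(fraction = .data$p_h31 * .data$f31 + (1 - .data$p_h31) * .data$f33,
                  region_id = "H3K27-R40", variant_scope = "combined") |>
    dplyr::select("sample_group", "replicate", "region_id", "variant_scope",
                  "site", "mark", "fraction") |>
    dplyr::arrange(.data$sample_group, .data$replicate, .data$mark)
}

#' Acetylation-degree profile of a peptide
#'
#' Each form contributes its fraction to the degree equal to its number of
#' acetylated lysines (e.g. tri- and tetra-acetylated H4G4--R17 forms signal
#' hyperacetylation).
#'
#' @param composition Composition tibble from [relative_abundance()].
#' @return Tibble `sample_group`, `replicate`, `region_id`, `degree`
#'   (0..number of lysines in the region), `fraction`; degrees closed to 1.
#' @export
acetyl_degree <- function(composition) {
  n_ac <- function(text) {
    if (is.na(text) || !nzchar(text)) return(0L)
    sum(grepl(":ac$", strsplit(text, ";", fixed = TRUE)[[1]]))
  }
  max_deg <- stats::setNames(lengths(peptide_regions()$sites), peptide_regions()$region_id)
  out <- composition |>
    dplyr::mutate(degree = vapply(.data$modifications, n_ac, integer(1))) |>
    dplyr::group_by(.data$sample_group, .data$replicate, .data$region_id,
                    .data$degree) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop")
  full_deg <- out |>
    dplyr::distinct(.data$sample_group, .data$replicate, .data$region_id) |>
    dplyr::rowwise() |>
    dplyr::mutate(degree = list(0:max_deg[[.data$region_id]])) |>
    tidyr::unnest("degree") |>
    dplyr::ungroup()
  dplyr::left_join(full_deg, out,
                   by = c("sample_group", "replicate", "region_id", "degree")) |>
    dplyr::mutate(fraction = dplyr::coalesce(.data$fraction, 0)) |>
    dplyr::arrange(.data$sample_group, .data$replicate, .data$region_id,
                   .data$degree)
}
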