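#' Assemble site-level mark profiles for every region
#'
#' Marginalizes each region's compositions onto each of its modifiable sites
#' and, for the variant-resolved K27/K36 sites, appends the variant-weighted
#' combined profile (see [combine_variants()]).
#'
#' @param composition Composition tibble from [relative_abundance()].
#' @param vp Variant proportions from [variant_proportion()], required for
#'   the combined K27/K36 profiles; pass `NULL` to skip them.
#' @return Site-mark tibble across all regions and sites.
#' @export
site_mark_profiles <- function(composition, vp = NULL) {
  regs <- peptide_regions()
  out <- list()
  for (i in seq_len(nrow(regs))) {
    r <- regs$region_id[i]
    sub <- composition[composition$region_id == r, ]
    if (nrow(sub) == 0L) next
    for (s in regs$sites[[i]]) {
      out[[length(out) + 1L]] <- marginalize_site(sub, s)
    }
  }
  out <- dplyr::bind_rows(out)
  if (!is.null(vp)) {
    for (s in c("K27", "K36")) {
      p31 <- out[out$variant_scope == "H3.1" & out$site == s, ]
      p33 <- out[out$variant_scope == "H3.3" & out$site == s, ]
      if (nrow(p31) > 0L && nrow(p33) > 0L) {
        out <- dplyr::bind_rows(out, combine_variants(p31, p33, vp))
      }
    }
  }
  out
}

#' Default run configuration
#'
#' @param input `"preset"` (synthetic study-design-like data) or the path of
#'   a peptidoform table.
#' @param seed Integer seed for every stochastic stage.
#' @param sigma Log-normal noise sigma for synthetic input.
#' @param n_replicates Replicates per synthetic group.
#' @param merges List of `list(sources = ..., target = ...)` directives.
#' @param comparisons List of ordered pairs of group labels for the stats
#'   stage (explicit, no all-vs-all default).
#' @param cluster_groups Optional character vector restricting the clustered
#'   groups (default: all).
#' @param welch Use Welch's t-test instead of Student's pooled test.
#' @param out_dir Output directory.
#' @return A `histoneptm_config` list.
#' @export
run_config <- function(input = "preset", seed = 1L, sigma = 0.25,
                       n_replicates = 6L, merges = list(),
                       comparisons = list(c("7ds", "cR"), c("7ds", "cS"),
                                          c("cR", "cS")),
                       cluster_groups = NULL, welch = FALSE,
                       out_dir = tempfile("histoneptm_run_")) {
  structure(list(input = input, seed = as.integer(seed), sigma = sigma,
                 n_replicates = as.integer(n_replicates), merges = merges,
                 comparisons = comparisons, cluster_groups = cluster_groups,
                 welch = welch, out_dir = out_dir),
            class = "histoneptm_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [run_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return A `histoneptm_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- run_config()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
                 class = "histoneptm_config_error")
  }
  if (!is.null(raw$comparisons)) raw$comparisons <- lapply(raw$comparisons, unlist)
  do.call(run_config, raw)
}

#' Run the full quantification pipeline
#'
#' read/generate -> merge -> relative abundance -> variant proportions ->
#' site marginalization and variant weighting -> acetylation degrees ->
#' per-form group statistics -> pivot-coordinate clustering. All tables are
#' written as TSV, dendrograms as Newick, and a JSON manifest records
#' versions, seed, configuration hash, runtime decisions (merge semantics,
#' zero-replacement deltas, dropped features) and the output checksums.
#' Identical configuration and seed give an identical manifest hash.
#'
#' @param config A `histoneptm_config`, see [run_config()].
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "histoneptm_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  decisions <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                   class = "histoneptm_pipeline_error", parent = e)
    })
  }

  records <- stage("input", {
    if (identical(config$input, "preset")) {
      generate_dataset(paper_like_preset(config$n_replicates),
                       noise_model(sigma = config$sigma, seed = config$seed))
    } else {
      read_peak_area_table(config$input)
    }
  })
  for (m in config$merges) {
    records <- stage("merge", merge_groups(records, m$sources, m$target))
    decisions <- c(decisions, sprintf(
      "merged %s -> %s by summing areas per replicate index; unpaired replicates retained",
      paste(m$sources, collapse = "+"), m$target))
  }

  comp <- stage("relative_abundance", relative_abundance(records))
  vp <- stage("variant_proportion", variant_proportion(records))
  marks <- stage("site_marks", site_mark_profiles(comp, vp))
  degrees <- stage("acetyl_degree", acetyl_degree(comp))
  decisions <- c(decisions,
                 "combined K27/K36 marks weighted by the group-median variant proportion")

  stats_tabs <- list()
  for (cmp in config$comparisons) {
    res <- stage("stats", compare_groups(comp, cmp[1], cmp[2], welch = config$welch))
    skipped <- attr(res, "skipped")
    if (length(skipped) > 0L) {
      decisions <- c(decisions, sprintf("comparison %s vs %s skipped features: %s",
                                        cmp[1], cmp[2], paste(skipped, collapse = "; ")))
    }
    stats_tabs[[sprintf("%s_vs_%s", cmp[1], cmp[2])]] <- res
  }

  clus_comp <- comp
  if (!is.null(config$cluster_groups)) {
    clus_comp <- comp[comp$sample_group %in% config$cluster_groups, ]
  }
  mat <- stage("cluster", build_profile_matrix(clus_comp, scope = "all-peptides"))
  dropped <- attr(mat, "dropped_features")
  if (length(dropped) > 0L) {
    decisions <- c(decisions, sprintf("features dropped matrix-wide before clustering: %s",
                                      paste(dropped, collapse = ", ")))
  }
  hc <- stage("cluster", hclust_average(mat))

  safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
  paths <- c(records = "records.tsv", compositions = "compositions.tsv",
             variant_replicates = "variant_proportions_replicates.tsv",
             variant_groups = "variant_proportions_groups.tsv",
             site_marks = "site_marks.tsv", acetyl_degrees = "acetyl_degrees.tsv",
             linkage = "linkage_all_peptides.tsv",
             newick = "cluster_all_peptides.newick")
  out <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(records, out(paths["records"]), progress = FALSE)
  readr::write_tsv(comp, out(paths["compositions"]), progress = FALSE)
  readr::write_tsv(vp$replicates, out(paths["variant_replicates"]), progress = FALSE)
  readr::write_tsv(vp$group, out(paths["variant_groups"]), progress = FALSE)
  readr::write_tsv(marks, out(paths["site_marks"]), progress = FALSE)
  readr::write_tsv(degrees, out(paths["acetyl_degrees"]), progress = FALSE)
  linkage <- tibble::tibble(step = seq_along(hc$height),
                            child1 = hc$merge[, 1], child2 = hc$merge[, 2],
                            height = hc$height)
  readr::write_tsv(linkage, out(paths["linkage"]), progress = FALSE)
  writeLines(cluster_newick(hc), out(paths["newick"]))
  for (nm in names(stats_tabs)) {
    f <- sprintf("stats_%s.tsv", safe_name(nm))
    readr::write_tsv(stats_tabs[[nm]], out(f), progress = FALSE)
    paths[nm] <- f
  }

  region_groups <- unique(peptide_regions()$region_group[
    peptide_regions()$region_id %in% unique(records$region_id)])
  checksums <- tools::md5sum(file.path(config$out_dir, unname(paths)))
  names(checksums) <- unname(paths)
  manifest <- list(
    package = "histoneptm",
    package_version = as.character(utils::packageVersion("histoneptm")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    groups = sort(unique(records$sample_group)),
    n_groups = length(unique(records$sample_group)),
    regions = region_groups,
    n_regions = length(region_groups),
    decisions = decisions,
    outputs = as.list(checksums)
  )
  manifest$manifest_hash <- rlang::hash(manifest)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
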