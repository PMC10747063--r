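#' Histone peptide regions
#'
#' The four tryptic (Arg-C-like, propionylated) histone peptides quantified by
#' the pipeline, with the K27--R40 peptide resolved per H3 variant. Site labels
#' use protein residue numbering (K27 = residue 27 of H3); no sequence-internal
#' offsets are exposed anywhere in the package.
#'
#' @return A tibble with one row per region: `region_id`, `region_group`
#'   (variant-collapsed peptide identity), `sequence`, `start` (protein
#'   coordinate of the first residue), `variant_scope` (`"H3.1"`, `"H3.3"` or
#'   `"n/a"` for peptides shared between variants), and `sites` (list-column of
#'   modifiable residue labels).
#' @examples
#' peptide_regions()
#' @export
peptide_regions <- function() {
  tibble::tibble(
    region_id = c("H3K9-R17", "H3K18-R26", "H3.1K27-R40", "H3.3K27-R40",
                  "H4G4-R17"),
    region_group = c("H3K9-R17", "H3K18-R26", "H3K27-R40", "H3K27-R40",
                     "H4G4-R17"),
    sequence = c("KSTGGKAPR", "KQLATKAAR", "KSAPATGGVKKPHR", "KSAPTTGGVKKPHR",
                 "GKGGKGLGKGGAKR"),
    start = c(9L, 18L, 27L, 27L, 4L),
    variant_scope = c("n/a", "n/a", "H3.1", "H3.3", "n/a"),
    sites = list(c("K9", "K14"), c("K18", "K23"), c("K27", "K36"),
                 c("K27", "K36"), c("K5", "K8", "K12", "K16"))
  )
}

# marks a site can carry; me3 is only admitted where it is observed on
# histone tails (K9, K27) plus K36 (admitted by the data model but flagged
# on parse). Propionylation is sample-prep chemistry, never a mark.
.mark_levels <- c("unmod", "me1", "me2", "me3", "ac")

#' Marks allowed at a modifiable site
#'
#' @param site Site label in protein coordinates, e.g. `"K27"`.
#' @param region_id One of the labels in [peptide_regions()].
#' @return Character vector of admissible marks, always starting with
#'   `"unmod"`.
#' @export
allowed_marks <- function(site, region_id) {
  reg <- region_info(region_id)
  if (!site %in% reg$sites[[1]]) {
    rlang::abort(
      sprintf("site '%s' is not a modifiable site of region '%s' (sites: %s)",
              site, region_id, paste(reg$sites[[1]], collapse = ", ")),
      class = "histoneptm_bad_site"
    )
  }
  if (site %in% c("K9", "K27", "K36")) .mark_levels
  else setdiff(.mark_levels, "me3")
}

region_info <- function(region_id) {
  regs <- peptide_regions()
  hit <- regs[regs$region_id == region_id, ]
  if (nrow(hit) != 1L) {
    rlang::abort(
      sprintf("unknown region_id '%s'; known regions: %s", region_id,
              paste(regs$region_id, collapse = ", ")),
      class = "histoneptm_bad_region"
    )
  }
  hit
}

#' Enumerate the full modification state space of a region
#'
#' Cartesian product of the admissible marks over the region's modifiable
#' sites, each state rendered as a canonical modification string (see
#' [format_modstring()]). The fully unmodified state is the empty string.
#'
#' @inheritParams allowed_marks
#' @return Character vector of canonical modification strings; the first
#'   element is always `""` (fully unmodified).
#' @examples
#' length(enumerate_modstates("H3.1K27-R40"))  # 5 x 5 = 25
#' @export
enumerate_modstates <- function(region_id) {
  reg <- region_info(region_id)
  sites <- reg$sites[[1]]
  grids <- lapply(sites, allowed_marks, region_id = region_id)
  names(grids) <- sites
  grid <- expand.grid(grids, stringsAsFactors = FALSE)
  vapply(seq_len(nrow(grid)), function(i) {
    st <- as.character(grid[i, ])
    names(st) <- sites
    format_modstring(st)
  }, character(1))
}

site_position <- function(site) as.integer(sub("^[A-Z]", "", site))
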