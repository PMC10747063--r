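#' Parse a compact modification string
#'
#' The native dialect is a semicolon- or space-delimited list of `site:mark`
#' tokens, e.g. `"K27:me1;K36:me2"`. Unlisted sites are unmodified; token
#' order is irrelevant; propionyl tokens (sample-prep derivatization, not a
#' biological mark) are dropped with a notice and the residue is treated as
#' unmodified.
#'
#' @param text Modification string; `""` (or `NA`) means fully unmodified.
#' @param region_id Region the peptide belongs to, see [peptide_regions()].
#' @param quiet Suppress the propionyl-drop notice.
#' @return Named character vector: one mark per modifiable site of the region,
#'   in site order.
#' @examples
#' parse_modstring("K27:me1;K36:me2", "H3.1K27-R40")
#' parse_modstring("", "H4G4-R17")
#' @export
parse_modstring <- function(text, region_id, quiet = FALSE) {
  reg <- region_info(region_id)
  sites <- reg$sites[[1]]
  state <- stats::setNames(rep("unmod", length(sites)), sites)
  if (is.na(text) || !nzchar(trimws(text))) return(state)

  tokens <- strsplit(trimws(text), "[; ]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  for (tok in tokens) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      rlang::abort(sprintf("malformed modification token '%s' (expected site:mark)", tok),
                   class = "histoneptm_bad_modstring")
    }
    site <- parts[1]
    mark <- parts[2]
    if (mark %in% c("prop", "propionyl", "pr")) {
      if (!quiet) rlang::inform(sprintf("dropping propionyl token '%s' (derivatization, not a mark)", tok),
                                class = "histoneptm_propionyl_dropped")
      next
    }
    if (!site %in% sites) {
      rlang::abort(sprintf("site '%s' does not belong to region '%s' (sites: %s)",
                           site, region_id, paste(sites, collapse = ", ")),
                   class = "histoneptm_bad_site")
    }
    if (!mark %in% allowed_marks(site, region_id)) {
      rlang::abort(sprintf("mark '%s' is not admissible at %s of region '%s'",
                           mark, site, region_id),
                   class = "histoneptm_bad_mark")
    }
    if (state[[site]] != "unmod" && state[[site]] != mark) {
      rlang::abort(sprintf("conflicting marks for site '%s': '%s' vs '%s'",
                           site, state[[site]], mark),
                   class = "histoneptm_conflicting_marks")
    }
    if (site == "K36" && mark == "me3" && !quiet) {
      rlang::warn("K36:me3 admitted by the data model but rarely reported; check the assignment",
                  class = "histoneptm_k36me3_flag")
    }
    state[[site]] <- mark
  }
  state
}

#' Format a modification state as its canonical string
#'
#' Canonical form: non-unmodified sites only, in ascending residue order,
#' joined by `";"`; the fully unmodified state is `""`.
#'
#' @param state Named character vector site -> mark, as returned by
#'   [parse_modstring()].
#' @return A single string.
#' @export
format_modstring <- function(state) {
  ord <- order(site_position(names(state)))
  state <- state[ord]
  keep <- state != "unmod"
  if (!any(keep)) return("")
  paste(sprintf("%s:%s", names(state)[keep], state[keep]), collapse = ";")
}

#' Canonicalize modification strings
#'
#' Round-trips each string through [parse_modstring()]/[format_modstring()],
#' normalising token order, dropping propionyl tokens and validating sites
#' and marks against the region.
#'
#' @param text Character vector of modification strings (`NA` = unmodified).
#' @param region_id Character vector of region labels, recycled against
#'   `text`.
#' @inheritParams parse_modstring
#' @return Character vector of canonical strings.
#' @export
canonicalize_modstring <- function(text, region_id, quiet = TRUE) {
  n <- max(length(text), length(region_id))
  text <- rep_len(text, n)
  region_id <- rep_len(region_id, n)
  vapply(seq_len(n), function(i) {
    format_modstring(parse_modstring(text[i], region_id[i], quiet = quiet))
  }, character(1))
}

#' Convert a Skyline-style modified sequence to the native dialect
#'
#' Accepts bracketed mass shifts after the modified residue, e.g.
#' `"K[+42.0106]SAPATGGVK[+14.0157]KPHR"`, and maps each shift to a mark by
#' nearest monoisotopic delta mass (tolerance 0.01 Da): me1 14.0157, me2
#' 28.0313, me3 42.0470, ac 42.0106, propionyl 56.0262 and
#' methyl-propionyl 70.0419 (both canonicalized away). Acetyl and trimethyl
#' are near-isobaric, so at least two decimals are required.
#'
#' @param modified_sequence Skyline-like peptide string with `[+mass]` tags.
#' @param region_id Target region (the bare sequence must match it).
#' @return Canonical modification string.
#' @examples
#' modstring_from_skyline("K[+14.0157]SAPATGGVK[+28.0313]KPHR", "H3.1K27-R40")
#' @export
modstring_from_skyline <- function(modified_sequence, region_id) {
  reg <- region_info(region_id)
  deltas <- c(me1 = 14.0157, me2 = 28.0313, me3 = 42.0470, ac = 42.0106,
              prop = 56.0262, prop_me = 70.0419)
  bare <- gsub("\\[[^]]*\\]", "", modified_sequence)
  if (bare != reg$sequence) {
    rlang::abort(sprintf("sequence '%s' does not match region '%s' (%s)",
                         bare, region_id, reg$sequence),
                 class = "histoneptm_sequence_mismatch")
  }
  state <- stats::setNames(rep("unmod", length(reg$sites[[1]])), reg$sites[[1]])
  pos <- 0L
  rest <- modified_sequence
  while (nzchar(rest)) {
    ch <- substr(rest, 1L, 1L)
    rest <- substr(rest, 2L, nchar(rest))
    pos <- pos + 1L
    if (grepl("^\\[", rest)) {
      m <- regmatches(rest, regexpr("^\\[\\+?(-?[0-9.]+)\\]", rest))
      mass <- as.numeric(gsub("[^0-9.-]", "", m))
      rest <- sub("^\\[[^]]*\\]", "", rest)
      if (!grepl("\\.[0-9]{2}", m)) {
        rlang::abort(sprintf("mass tag '%s' needs >= 2 decimals to resolve near-isobaric marks", m),
                     class = "histoneptm_ambiguous_mass")
      }
      hit <- which.min(abs(deltas - mass))
      if (abs(deltas[hit] - mass) > 0.01) {
        rlang::abort(sprintf("mass shift %+.4f at %s%d matches no known mark", mass, ch, pos + reg$start - 1L),
                     class = "histoneptm_unknown_mass")
      }
      mark <- names(deltas)[hit]
      if (mark %in% c("prop", "prop_me")) {
        # propionyl-only residues are unmodified; methyl-propionyl is me1
        if (mark == "prop_me") mark <- "me1" else next
      }
      site <- sprintf("%s%d", ch, pos + reg$start - 1L)
      if (!site %in% names(state)) {
        rlang::abort(sprintf("modified residue %s is not a modifiable site of '%s'", site, region_id),
                     class = "histoneptm_bad_site")
      }
      state[[site]] <- mark
    }
  }
  format_modstring(state)
}
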