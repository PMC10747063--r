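#' Build a peptidoform profile from independent site marginals
#'
#' Takes one marginal mark distribution per modifiable site and forms the
#' product profile over the region's enumerated state space (sites treated as
#' independent). States receiving zero probability are omitted: the generator
#' never emits them, matching the convention that unobserved forms are
#' missing, not zero.
#'
#' @param region_id Region label, see [peptide_regions()].
#' @param marginals Named list site -> named numeric over that site's
#'   admissible marks, each summing to 1.
#' @return Named numeric vector: canonical modification string -> fraction,
#'   summing to 1.
#' @export
profile_from_marginals <- function(region_id, marginals) {
  reg <- region_info(region_id)
  sites <- reg$sites[[1]]
  if (!setequal(names(marginals), sites)) {
    rlang::abort(sprintf("marginals must cover exactly the sites of '%s': %s",
                         region_id, paste(sites, collapse = ", ")),
                 class = "histoneptm_bad_site")
  }
  for (s in sites) {
    mk <- marginals[[s]]
    if (is.null(names(mk)) || !all(names(mk) %in% allowed_marks(s, region_id))) {
      rlang::abort(sprintf("marginal for %s has marks outside its admissible set", s),
                   class = "histoneptm_bad_mark")
    }
    if (abs(sum(mk) - 1) > 1e-9) {
      rlang::abort(sprintf("marginal for %s does not sum to 1", s),
                   class = "histoneptm_domain_error")
    }
  }
  states <- enumerate_modstates(region_id)
  prob <- vapply(states, function(st) {
    asg <- parse_modstring(st, region_id, quiet = TRUE)
    prod(vapply(sites, function(s) {
      p <- marginals[[s]][asg[[s]]]
      if (is.na(p)) 0 else unname(p)
    }, numeric(1)))
  }, numeric(1))
  prob <- prob[prob > 0]
  prob / sum(prob)
}

#' Define a synthetic sample group
#'
#' @param label Group label.
#' @param variant_p31 True H3.1 fraction of the H3 pool in (0, 1).
#' @param profiles Named list region_id -> named probability vector over
#'   canonical modification strings (see [profile_from_marginals()]); must
#'   cover all five regions.
#' @param n_replicates Biological replicates (default 6, matching an n = 5-6
#'   design).
#' @param scale Expected total peak area per peptide region (arbitrary
#'   intensity units).
#' @param dropout_rate Fraction of each replicate's lowest-abundance forms
#'   set missing, per region (detection dropout; in `[0, 1)`).
#' @return A `histoneptm_design` list.
#' @export
group_design <- function(label, variant_p31, profiles, n_replicates = 6L,
                         scale = 1e6, dropout_rate = 0) {
  stopifnot(variant_p31 > 0, variant_p31 < 1, scale > 0,
            dropout_rate >= 0, dropout_rate < 1, n_replicates >= 1L)
  regs <- peptide_regions()$region_id
  if (!setequal(names(profiles), regs)) {
    rlang::abort(sprintf("profiles must cover exactly the regions: %s",
                         paste(regs, collapse = ", ")),
                 class = "histoneptm_bad_region")
  }
  for (r in regs) {
    p <- profiles[[r]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      rlang::abort(sprintf("profile for %s is not a closed composition", r),
                   class = "histoneptm_domain_error")
    }
    bad <- setdiff(names(p), enumerate_modstates(r))
    if (length(bad) > 0L) {
      rlang::abort(sprintf("profile state(s) outside the state space of %s: %s",
                           r, paste(bad, collapse = ", ")),
                   class = "histoneptm_bad_modstring")
    }
  }
  structure(list(label = label, n_replicates = as.integer(n_replicates),
                 variant_p31 = variant_p31, profiles = profiles,
                 scale = scale, dropout_rate = dropout_rate),
            class = "histoneptm_design")
}

#' Log-normal intensity noise model
#'
#' @param sigma Standard deviation of the log-normal multiplicative noise
#'   applied to region totals and to within-peptide form intensities
#'   (default 0.25).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `histoneptm_noise` list.
#' @export
noise_model <- function(sigma = 0.25, seed = 1L) {
  stopifnot(sigma >= 0, is.finite(seed))
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "histoneptm_noise")
}

#' Generate a synthetic peptidoform peak-area table
#'
#' For each group x replicate: one log-normal total area per peptide region;
#' the K27--R40 total is split between the H3.1 and H3.3 peptides by the
#' design's `variant_p31`; within each region the total is distributed over
#' the profile's forms after perturbing the profile with per-form log-normal
#' noise (renormalised, so noise moves the composition but conserves the
#' region total); finally the `dropout_rate` fraction of the replicate's
#' lowest-abundance forms in each region is set missing.
#'
#' @param designs List of [group_design()] objects with distinct labels.
#' @param noise A [noise_model()].
#' @return Canonical peptidoform record tibble.
#' @export
generate_dataset <- function(designs, noise = noise_model()) {
  if (inherits(designs, "histoneptm_design")) designs <- list(designs)
  if (length(designs) == 0L) {
    rlang::abort("designs must be non-empty", class = "histoneptm_domain_error")
  }
  labels <- vapply(designs, `[[`, character(1), "label")
  if (anyDuplicated(labels) > 0L) {
    rlang::abort("design labels must be distinct", class = "histoneptm_domain_error")
  }
  variant_regions <- c("H3.1K27-R40", "H3.3K27-R40")
  region_order <- peptide_regions()$region_id
  others <- setdiff(region_order, variant_regions)
  withr::with_seed(noise$seed, {
    chunks <- vector("list", length(designs))
    for (di in seq_along(designs)) {
      d <- designs[[di]]
      n <- d$n_replicates
      base <- dplyr::bind_rows(lapply(region_order, function(r) {
        w <- d$profiles[[r]]
        w <- w[w > 0]
        tibble::tibble(region_id = r, modifications = names(w), w = unname(w))
      }))
      # one shared K27-R40 pool total per replicate, split exactly by
      # variant_p31; independent totals for the shared peptides
      t_k27 <- d$scale * stats::rlnorm(n, 0, noise$sigma)
      t_other <- matrix(d$scale * stats::rlnorm(n * length(others), 0, noise$sigma),
                        nrow = n, dimnames = list(NULL, others))
      full <- base[rep(seq_len(nrow(base)), times = n), ]
      full$replicate <- rep(seq_len(n), each = nrow(base))
      full$noisy <- full$w * stats::rlnorm(nrow(full), 0, noise$sigma)
      tot <- numeric(nrow(full))
      h31 <- full$region_id == "H3.1K27-R40"
      h33 <- full$region_id == "H3.3K27-R40"
      tot[h31] <- t_k27[full$replicate[h31]] * d$variant_p31
      tot[h33] <- t_k27[full$replicate[h33]] * (1 - d$variant_p31)
      for (r in others) {
        sel <- full$region_id == r
        tot[sel] <- t_other[full$replicate[sel], r]
      }
      full$tot <- tot
      full <- full |>
        dplyr::group_by(.data$replicate, .data$region_id) |>
        dplyr::mutate(peak_area = .data$tot * .data$noisy / sum(.data$noisy))
      if (d$dropout_rate > 0) {
        full <- dplyr::filter(full,
          rank(.data$peak_area, ties.method = "first") >
            min(round(d$dropout_rate * dplyr::n()), dplyr::n() - 1L))
      }
      full <- dplyr::ungroup(full)
      chunks[[di]] <- tibble::tibble(
        sample_group = d$label, replicate = full$replicate,
        region_id = full$region_id, modifications = full$modifications,
        peak_area = full$peak_area
      )
    }
    validate_records(dplyr::bind_rows(chunks))
  })
}

# per-group site-marginal tables for the preset; only the anchored entries
# (variant ratios; 7ds K27me1 27%/13%; cR H3.3K27me1 ~24%) are study-derived,
# everything else is a synthetic default documented as such.
preset_marginals <- function() {
  m <- function(...) c(...)
  seven <- list(
    "H3K9-R17" = list(K9 = m(unmod = .25, me1 = .20, me2 = .30, me3 = .05, ac = .20),
                      K14 = m(unmod = .55, me1 = .05, me2 = .05, ac = .35)),
    "H3K18-R26" = list(K18 = m(unmod = .60, me1 = .05, me2 = .05, ac = .30),
                       K23 = m(unmod = .55, me1 = .10, me2 = .05, ac = .30)),
    "H3.1K27-R40" = list(K27 = m(unmod = .40, me1 = .27, me2 = .18, me3 = .05, ac = .10),
                         K36 = m(unmod = .45, me1 = .20, me2 = .25, me3 = 0, ac = .10)),
    "H3.3K27-R40" = list(K27 = m(unmod = .50, me1 = .13, me2 = .12, me3 = .05, ac = .20),
                         K36 = m(unmod = .40, me1 = .25, me2 = .25, me3 = 0, ac = .10)),
    "H4G4-R17" = list(K5 = m(unmod = .75, ac = .25), K8 = m(unmod = .75, ac = .25),
                      K12 = m(unmod = .70, ac = .30), K16 = m(unmod = .55, ac = .45))
  )
  croot <- list(
    "H3K9-R17" = list(K9 = m(unmod = .33, me1 = .30, me2 = .17, me3 = .05, ac = .15),
                      K14 = m(unmod = .65, me1 = .05, me2 = .05, ac = .25)),
    "H3K18-R26" = list(K18 = m(unmod = .70, me1 = .05, me2 = .05, ac = .20),
                       K23 = m(unmod = .65, me1 = .10, me2 = .05, ac = .20)),
    "H3.1K27-R40" = list(K27 = m(unmod = .38, me1 = .30, me2 = .20, me3 = .02, ac = .10),
                         K36 = m(unmod = .35, me1 = .30, me2 = .28, me3 = 0, ac = .07)),
    "H3.3K27-R40" = list(K27 = m(unmod = .42, me1 = .24, me2 = .12, me3 = .04, ac = .18),
                         K36 = m(unmod = .33, me1 = .30, me2 = .28, me3 = 0, ac = .09)),
    "H4G4-R17" = list(K5 = m(unmod = .78, ac = .22), K8 = m(unmod = .78, ac = .22),
                      K12 = m(unmod = .74, ac = .26), K16 = m(unmod = .58, ac = .42))
  )
  cshoot <- list(
    "H3K9-R17" = list(K9 = m(unmod = .36, me1 = .30, me2 = .14, me3 = .07, ac = .13),
                      K14 = m(unmod = .66, me1 = .05, me2 = .05, ac = .24)),
    "H3K18-R26" = list(K18 = m(unmod = .70, me1 = .05, me2 = .05, ac = .20),
                       K23 = m(unmod = .66, me1 = .09, me2 = .05, ac = .20)),
    "H3.1K27-R40" = list(K27 = m(unmod = .40, me1 = .22, me2 = .26, me3 = .04, ac = .08),
                         K36 = m(unmod = .36, me1 = .22, me2 = .34, me3 = 0, ac = .08)),
    "H3.3K27-R40" = list(K27 = m(unmod = .46, me1 = .16, me2 = .14, me3 = .06, ac = .18),
                         K36 = m(unmod = .35, me1 = .24, me2 = .31, me3 = 0, ac = .10)),
    "H4G4-R17" = list(K5 = m(unmod = .77, ac = .23), K8 = m(unmod = .77, ac = .23),
                      K12 = m(unmod = .73, ac = .27), K16 = m(unmod = .56, ac = .44))
  )
  oneyear <- purrr::map2(croot, cshoot, function(a, b) {
    purrr::map2(a, b, function(x, y) (x + y[names(x)]) / 2)
  })
  list(`7ds` = seven, cR = croot, cS = cshoot,
       `NaB-cR` = croot, `NaB-cS` = croot,
       `TSA-cR` = cshoot, `TSA-cS` = cshoot,
       `1y-cR` = oneyear, `1y-cS` = oneyear)
}

#' Study-design-like preset of synthetic group designs
#'
#' Nine groups emulating a seedling/callus HDAC-inhibitor design: 7-day
#' seedlings (`7ds`), 20-day root/shoot calli (`cR`, `cS`), HDACi-treated
#' calli (`NaB-cR`, `NaB-cS`, `TSA-cR`, `TSA-cS`) and one-year calli
#' (`1y-cR`, `1y-cS`). Anchored values: H3.1 fractions converted from the
#' reported ratios (7ds 3:1 -> 0.75; cR 1.3:1 -> 0.565; cS 1.8:1 -> 0.643;
#' NaB-cR 2:1 -> 2/3; TSA-cR 1.0:1.0 -> 0.50; TSA-cS and 1y-cR 1.4:1 ->
#' 0.583; 1y-cS 1.8:1 -> 0.643) and the 7ds variant-specific K27me1 levels
#' (H3.1 27%, H3.3 13%) plus cR H3.3K27me1 24%. Every other profile entry is
#' a synthetic default; NaB-cS (no reported ratio) is set cS-like (0.643).
#' NaB-treated groups share the cR form profiles and TSA-treated groups the
#' cS profiles, encoding the reported similarity structure (NaB calli
#' resemble root calli, TSA calli resemble shoot calli). Root-derived callus
#' groups carry detection dropout (rate 0.12) mirroring the lower peptide
#' recovery from root material.
#'
#' @param n_replicates Replicates per group (default 6).
#' @return Named list of [group_design()] objects.
#' @export
paper_like_preset <- function(n_replicates = 6L) {
  p31 <- c(`7ds` = 0.75, cR = 0.565, cS = 0.643, `NaB-cR` = 2 / 3,
           `NaB-cS` = 0.643, `TSA-cR` = 0.50, `TSA-cS` = 0.583,
           `1y-cR` = 0.583, `1y-cS` = 0.643)
  dropout <- c(`7ds` = 0, cR = 0.12, cS = 0, `NaB-cR` = 0.12, `NaB-cS` = 0,
               `TSA-cR` = 0.12, `TSA-cS` = 0, `1y-cR` = 0.12, `1y-cS` = 0)
  margs <- preset_marginals()
  designs <- lapply(names(p31), function(g) {
    profiles <- lapply(names(margs[[g]]), function(r) {
      profile_from_marginals(r, margs[[g]][[r]])
    })
    names(profiles) <- names(margs[[g]])
    group_design(g, variant_p31 = unname(p31[[g]]), profiles = profiles,
                 n_replicates = n_replicates, dropout_rate = unname(dropout[[g]]))
  })
  names(designs) <- names(p31)
  designs
}

#' Simulate alr-scale feature values for two groups
#'
#' Feature-level simulator for calibrating the t-test layer: replicate alr
#' values are normal with a between-group mean shift. The "large effect"
#' configuration is `shift = 2`, `sigma = 0.5`, `n_per_group = 6`; the null
#' is `shift = 0`.
#'
#' @param n_features Number of independent features.
#' @param n_per_group Replicates per group (default 6).
#' @param shift Between-group mean shift on the alr (log2-odds) scale.
#' @param sigma Replicate standard deviation on the alr scale.
#' @param seed Integer seed.
#' @return Tibble `feature`, `sample_group` (`"A"`/`"B"`), `replicate`,
#'   `alr_value`.
#' @export
simulate_alr_features <- function(n_features, n_per_group = 6L, shift = 0,
                                  sigma = 0.5, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n <- n_features * n_per_group
    tibble::tibble(
      feature = rep(rep(seq_len(n_features), each = n_per_group), 2L),
      sample_group = rep(c("A", "B"), each = n),
      replicate = rep(rep(seq_len(n_per_group), n_features), 2L),
      alr_value = c(stats::rnorm(n, 0, sigma), stats::rnorm(n, shift, sigma))
    )
  })
}
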