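test_that("relative abundance is area over peptide total", {
  rec <- tibble::tibble(
    sample_group = "g", replicate = 1L, region_id = "H3.1K27-R40",
    modifications = c("K27:me1", "K27:me2"), peak_area = c(80, 20)
  )
  comp <- relative_abundance(rec)
  expect_equal(comp$fraction[comp$modifications == "K27:me1"], 0.8)
  expect_equal(comp$fraction[comp$modifications == "K27:me2"], 0.2)
  # single observed form closes to 1
  comp1 <- relative_abundance(rec[1, ])
  expect_equal(comp1$fraction, 1)
})

test_that("relative abundance matches the area/sum oracle on random vectors", {
  withr::with_seed(11, {
    for (i in 1:20) {
      areas <- stats::runif(6, 0.1, 100)
      forms <- enumerate_modstates("H3.1K27-R40")[2:7]
      rec <- tibble::tibble(sample_group = "g", replicate = 1L,
                            region_id = "H3.1K27-R40",
                            modifications = forms, peak_area = areas)
      comp <- relative_abundance(rec)
      oracle <- areas / sum(areas)
      expect_equal(comp$fraction[match(forms, comp$modifications)], oracle,
                   tolerance = 1e-12)
      expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
    }
  })
})

test_that("zero-total peptides are flagged unquantifiable", {
  rec <- tibble::tibble(sample_group = "g", replicate = 1L,
                        region_id = "H4G4-R17",
                        modifications = c("", "K5:ac"), peak_area = c(0, 0))
  expect_error(relative_abundance(rec), "rep 1", class = "histoneptm_zero_total")
})

test_that("variant ratio text follows the printed style", {
  expect_identical(format_variant_ratio(0.75), "3:1")
  expect_identical(format_variant_ratio(0.5), "1.0:1.0")
  expect_identical(format_variant_ratio(0.565), "1.3:1")
  expect_identical(format_variant_ratio(0.7), "2.3:1")
})

test_that("variant proportions use per-replicate totals and the group median", {
  mk <- function(p31, rep_i) tibble::tibble(
    sample_group = "g", replicate = rep_i,
    region_id = c("H3.1K27-R40", "H3.3K27-R40"),
    modifications = "K27:me1", peak_area = c(p31, 1 - p31) * 100
  )
  # constant 0.75 across three replicates -> "3:1"
  vp <- variant_proportion(dplyr::bind_rows(mk(0.75, 1L), mk(0.75, 2L), mk(0.75, 3L)))
  expect_equal(vp$group$p_h31, 0.75)
  expect_identical(vp$group$ratio_text, "3:1")
  # balanced -> "1.0:1.0"
  vp <- variant_proportion(dplyr::bind_rows(mk(0.5, 1L), mk(0.5, 2L)))
  expect_identical(vp$group$ratio_text, "1.0:1.0")
  # odd-length set: median 0.7 -> 2.3:1
  vp <- variant_proportion(dplyr::bind_rows(mk(0.6, 1L), mk(0.7, 2L), mk(0.8, 3L)))
  expect_equal(vp$group$p_h31, 0.7)
  expect_identical(vp$group$ratio_text, "2.3:1")
  expect_identical(nrow(vp$replicates), 3L)
})

test_that("variant proportion requires a shared replicate", {
  rec <- tibble::tibble(
    sample_group = "g", replicate = c(1L, 2L),
    region_id = c("H3.1K27-R40", "H3.3K27-R40"),
    modifications = "K27:me1", peak_area = c(10, 10)
  )
  expect_error(variant_proportion(rec), class = "histoneptm_no_shared_replicates")
})

test_that("site marginalization sums fractions over co-modification states", {
  comp <- tibble::tibble(
    sample_group = "g", replicate = 1L, region_id = "H3.1K27-R40",
    modifications = c("K27:me1", "K27:me1;K36:me1", ""),
    fraction = c(0.4, 0.1, 0.5)
  )
  mk <- marginalize_site(comp, "K27")
  expect_equal(mk$fraction[mk$mark == "me1"], 0.5)
  expect_equal(mk$fraction[mk$mark == "unmod"], 0.5)
  expect_equal(sum(mk$fraction), 1, tolerance = 1e-9)
  expect_identical(unique(mk$variant_scope), "H3.1")
  # fully unmodified composition
  comp0 <- tibble::tibble(sample_group = "g", replicate = 1L,
                          region_id = "H3.1K27-R40", modifications = "",
                          fraction = 1)
  mk0 <- marginalize_site(comp0, "K36")
  expect_equal(mk0$fraction[mk0$mark == "unmod"], 1)
  expect_error(marginalize_site(comp, "K9"), class = "histoneptm_bad_site")
})

test_that("marginals over the full K27xK36 state space match enumeration", {
  states <- enumerate_modstates("H3.1K27-R40")
  withr::with_seed(21, {
    for (i in 1:10) {
      frac <- random_composition(length(states))
      comp <- tibble::tibble(sample_group = "g", replicate = 1L,
                             region_id = "H3.1K27-R40",
                             modifications = states, fraction = frac)
      for (s in c("K27", "K36")) {
        mk <- marginalize_site(comp, s)
        oracle <- vapply(mk$mark, function(m) {
          sum(frac[vapply(states, function(st) {
            parse_modstring(st, "H3.1K27-R40", quiet = TRUE)[[s]] == m
          }, logical(1))])
        }, numeric(1))
        expect_equal(mk$fraction, unname(oracle), tolerance = 1e-12)
        expect_equal(sum(mk$fraction), 1, tolerance = 1e-9)
      }
    }
  })
})

test_that("variant weighting reproduces the seedling K27me1 worked example", {
  prof <- function(scope, me1) tibble::tibble(
    sample_group = "7ds", replicate = 1L,
    region_id = paste0(scope, "K27-R40"), variant_scope = scope,
    site = "K27", mark = c("unmod", "me1"), fraction = c(1 - me1, me1)
  )
  vp <- list(group = tibble::tibble(sample_group = "7ds", p_h31 = 0.75),
             replicates = tibble::tibble(sample_group = "7ds", replicate = 1L,
                                         p_h31 = 0.75))
  cmb <- combine_variants(prof("H3.1", 0.27), prof("H3.3", 0.13), vp)
  expect_equal(cmb$fraction[cmb$mark == "me1"] * 100, 23.5)
  expect_equal(sum(cmb$fraction), 1, tolerance = 1e-9)
})

test_that("variant weighting is convex and symmetric", {
  mkprof <- function(scope, f) tibble::tibble(
    sample_group = "g", replicate = 1L, region_id = paste0(scope, "K27-R40"),
    variant_scope = scope, site = "K27",
    mark = c("unmod", "me1", "me2", "me3", "ac"), fraction = f
  )
  marks <- c("unmod", "me1", "me2", "me3", "ac")
  aligned <- function(cmb) cmb$fraction[match(marks, cmb$mark)]
  withr::with_seed(31, {
    f31 <- random_composition(5)
    f33 <- random_composition(5)
    mkvp <- function(p) list(
      group = tibble::tibble(sample_group = "g", p_h31 = p),
      replicates = tibble::tibble(sample_group = "g", replicate = 1L, p_h31 = p))
    # degenerate weight returns the H3.1 profile unchanged
    cmb <- combine_variants(mkprof("H3.1", f31), mkprof("H3.3", f33), mkvp(1))
    expect_equal(aligned(cmb), f31, tolerance = 1e-12)
    # equal profiles are a fixed point for any weight
    cmb <- combine_variants(mkprof("H3.1", f31), mkprof("H3.3", f31), mkvp(0.3))
    expect_equal(aligned(cmb), f31, tolerance = 1e-12)
    # exchanging (profile, weight) pairs leaves the result unchanged
    a <- combine_variants(mkprof("H3.1", f31), mkprof("H3.3", f33), mkvp(0.7))
    b <- combine_variants(mkprof("H3.1", f33), mkprof("H3.3", f31), mkvp(0.3))
    expect_equal(aligned(a), aligned(b), tolerance = 1e-12)
  })
})

test_that("acetylation degrees count ac marks per form", {
  comp <- tibble::tibble(
    sample_group = "g", replicate = 1L, region_id = "H4G4-R17",
    modifications = c("K5:ac;K8:ac;K12:ac", "K5:ac;K8:ac;K12:ac;K16:ac", ""),
    fraction = c(0.1, 0.05, 0.85)
  )
  deg <- acetyl_degree(comp)
  expect_equal(deg$fraction[deg$degree == 3], 0.1)
  expect_equal(deg$fraction[deg$degree == 4], 0.05)
  expect_equal(deg$fraction[deg$degree == 0], 0.85)
  expect_equal(sum(deg$fraction), 1, tolerance = 1e-9)
  # fully unmodified composition: all mass at degree 0
  comp0 <- dplyr::mutate(comp[3, ], fraction = 1)
  deg0 <- acetyl_degree(comp0)
  expect_equal(deg0$fraction, c(1, 0, 0, 0, 0))
})

test_that("degree histogram matches a brute-force ac count on random data", {
  states <- enumerate_modstates("H4G4-R17")
  withr::with_seed(41, {
    frac <- random_composition(length(states))
    comp <- tibble::tibble(sample_group = "g", replicate = 1L,
                           region_id = "H4G4-R17",
                           modifications = states, fraction = frac)
    deg <- acetyl_degree(comp)
    n_ac <- vapply(states, function(st) {
      sum(parse_modstring(st, "H4G4-R17", quiet = TRUE) == "ac")
    }, integer(1))
    oracle <- vapply(0:4, function(d) sum(frac[n_ac == d]), numeric(1))
    expect_equal(deg$fraction, oracle, tolerance = 1e-12)
  })
})
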