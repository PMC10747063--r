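test_that("identical seeds give identical datasets; different seeds differ", {
  des <- paper_like_preset(n_replicates = 2L)
  a <- generate_dataset(des, noise_model(sigma = 0.25, seed = 7))
  b <- generate_dataset(des, noise_model(sigma = 0.25, seed = 7))
  c <- generate_dataset(des, noise_model(sigma = 0.25, seed = 8))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("the noiseless limit recovers the design profile exactly", {
  des <- paper_like_preset(n_replicates = 2L)
  des <- lapply(des, function(d) { d$dropout_rate <- 0; d })
  rec <- generate_dataset(des, noise_model(sigma = 0, seed = 1))
  comp <- relative_abundance(rec)
  for (g in c("7ds", "cR")) {
    for (r in c("H3.1K27-R40", "H4G4-R17")) {
      sub <- comp[comp$sample_group == g & comp$replicate == 1L &
                    comp$region_id == r, ]
      prof <- des[[g]]$profiles[[r]]
      prof <- prof[prof > 0]
      expect_equal(sub$fraction[match(names(prof), sub$modifications)],
                   unname(prof), tolerance = 1e-9)
    }
  }
  # and the variant split is exact
  vp <- variant_proportion(rec)
  expect_equal(vp$replicates$p_h31[vp$replicates$sample_group == "7ds"],
               rep(0.75, 2), tolerance = 1e-12)
})

test_that("preset anchors match the reported study values", {
  des <- paper_like_preset()
  expect_length(des, 9L)
  expect_equal(des[["7ds"]]$variant_p31, 0.75)
  expect_equal(des[["TSA-cR"]]$variant_p31, 0.50)
  expect_equal(des[["cR"]]$variant_p31, 0.565)
  expect_equal(des[["NaB-cR"]]$variant_p31, 2 / 3, tolerance = 1e-12)
  # K27me1 marginal mass: 27% on H3.1, 13% on H3.3 in seedlings
  k27me1_mass <- function(prof) {
    sum(prof[grepl("K27:me1(;|$)", names(prof))])
  }
  expect_equal(k27me1_mass(des[["7ds"]]$profiles[["H3.1K27-R40"]]), 0.27,
               tolerance = 1e-9)
  expect_equal(k27me1_mass(des[["7ds"]]$profiles[["H3.3K27-R40"]]), 0.13,
               tolerance = 1e-9)
  # similarity structure: HDACi groups share control-calli profiles
  expect_identical(des[["NaB-cS"]]$profiles, des[["cR"]]$profiles)
  expect_identical(des[["TSA-cR"]]$profiles, des[["cS"]]$profiles)
})

test_that("designs validate their profiles and parameters", {
  des <- paper_like_preset()[["7ds"]]
  expect_error(group_design("x", 0.5, des$profiles[-1]),
               class = "histoneptm_bad_region")
  bad <- des$profiles
  names(bad[["H4G4-R17"]])[1] <- "K9:me1"
  expect_error(group_design("x", 0.5, bad), class = "histoneptm_bad_modstring")
  bad <- des$profiles
  bad[["H4G4-R17"]] <- bad[["H4G4-R17"]] * 2
  expect_error(group_design("x", 0.5, bad), class = "histoneptm_domain_error")
  expect_error(generate_dataset(list(), noise_model()),
               class = "histoneptm_domain_error")
  expect_error(generate_dataset(list(des, des), noise_model()),
               class = "histoneptm_domain_error")
})

test_that("dropout removes the lowest-abundance forms at the design rate", {
  des <- paper_like_preset(n_replicates = 6L)
  target <- des[["cR"]]$dropout_rate
  n_states <- vapply(des[["cR"]]$profiles, function(p) sum(p > 0), integer(1))
  realized <- numeric(0)
  for (seed in 1:60) {
    rec <- generate_dataset(des["cR"], noise_model(sigma = 0.25, seed = seed))
    counts <- dplyr::count(rec, replicate, region_id)
    full <- n_states[counts$region_id]
    realized <- c(realized, 1 - counts$n / full)
  }
  expect_lt(abs(mean(realized) - target), 0.05)
  # dropped forms are the smallest: every surviving area exceeds the largest
  # dropped one within each replicate x region (checked on the noiseless case)
  d0 <- des[["cR"]]
  d0$dropout_rate <- 0
  full_rec <- generate_dataset(list(d0), noise_model(sigma = 0.25, seed = 3))
  drop_rec <- generate_dataset(des["cR"], noise_model(sigma = 0.25, seed = 3))
  key <- function(x) paste(x$replicate, x$region_id, x$modifications)
  dropped <- full_rec[!key(full_rec) %in% key(drop_rec), ]
  for (i in seq_len(6)) {
    for (r in unique(full_rec$region_id)) {
      dr <- dropped[dropped$replicate == i & dropped$region_id == r, ]
      kept <- drop_rec[drop_rec$replicate == i & drop_rec$region_id == r, ]
      if (nrow(dr) > 0) expect_lt(max(dr$peak_area), min(kept$peak_area))
    }
  }
})

test_that("group-median variant estimates recover the design proportion", {
  des <- paper_like_preset(n_replicates = 6L)[c("7ds", "cR")]
  hits <- 0L
  n_seeds <- 40L
  for (seed in seq_len(n_seeds)) {
    rec <- generate_dataset(des, noise_model(sigma = 0.25, seed = seed))
    vp <- variant_proportion(rec)
    ok <- abs(vp$group$p_h31[vp$group$sample_group == "7ds"] - 0.75) <= 0.03 &&
      abs(vp$group$p_h31[vp$group$sample_group == "cR"] - 0.565) <= 0.03
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("alr feature simulation is seeded and shifts group B", {
  sim <- simulate_alr_features(50, n_per_group = 6, shift = 2, sigma = 0.5,
                               seed = 5)
  expect_identical(sim, simulate_alr_features(50, 6, 2, 0.5, seed = 5))
  expect_identical(nrow(sim), 50L * 6L * 2L)
  expect_gt(mean(sim$alr_value[sim$sample_group == "B"]) -
              mean(sim$alr_value[sim$sample_group == "A"]), 1.5)
})
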