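#' Multiplicative zero replacement
#'
#' Replaces zero parts of a composition by `delta` and rescales the positive
#' parts by `(1 - z * delta) / sum(positive parts)` (z = number of zeros), so
#' the output is strictly positive, closed to 1, and preserves the ratios
#' among originally positive parts.
#'
#' @param x Numeric composition (non-negative, at least one positive part).
#' @param delta Replacement value for each zero part; must satisfy
#'   `z * delta < 1`.
#' @return Strictly positive composition summing to 1.
#' @examples
#' zero_replace(c(0.8, 0.2, 0), delta = 0.01)
#' @export
zero_replace <- function(x, delta) {
  if (length(x) < 2L) {
    rlang::abort("a composition needs at least 2 parts", class = "histoneptm_domain_error")
  }
  if (any(x < 0) || all(x == 0)) {
    rlang::abort("composition must be non-negative with at least one positive part",
                 class = "histoneptm_domain_error")
  }
  x <- x / sum(x)
  z <- sum(x == 0)
  if (z == 0L) return(x)
  if (z * delta >= 1) {
    rlang::abort("delta too large: z * delta must be < 1", class = "histoneptm_domain_error")
  }
  out <- x
  out[x == 0] <- delta
  out[x > 0] <- x[x > 0] * (1 - z * delta) / sum(x[x > 0])
  out
}

#' Default per-feature replacement delta
#'
#' 0.65 times the smallest positive fraction observed for the feature across
#' the dataset, a standard multiplicative-replacement heuristic.
#'
#' @param fractions Numeric vector of observed fractions for one feature.
#' @return Scalar delta.
#' @export
default_delta <- function(fractions) {
  pos <- fractions[!is.na(fractions) & fractions > 0]
  if (length(pos) == 0L) {
    rlang::abort("feature has no positive fractions; cannot derive a delta",
                 class = "histoneptm_domain_error")
  }
  0.65 * min(pos)
}

#' Two-part additive log-ratio (base 2)
#'
#' `alr2(x) = log2(x / (1 - x))`: the log2 ratio of one form's relative
#' abundance to the summed abundance of all other forms of the peptide.
#' Strictly increasing; antisymmetric about x = 0.5.
#'
#' @param x Fractions strictly inside (0, 1).
#' @return Numeric vector of log2 odds.
#' @examples
#' alr2(0.8)  # log2(4) = 2
#' @export
alr2 <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    rlang::abort("alr2 requires 0 < x < 1 (apply zero_replace first)",
                 class = "histoneptm_domain_error")
  }
  log2(x / (1 - x))
}

#' Two-sample t-test on log-ratio values with significance tiers
#'
#' Student's pooled-variance t-test by default (Welch behind a flag),
#' two-sided. Tiers: `significant` if p < 0.05, `trend` if 0.05 <= p < 0.1
#' (the measure-zero boundary p = 0.05 goes to `trend`), otherwise `ns`.
#'
#' @param values_a,values_b Numeric vectors (alr-transformed abundances), each
#'   of length >= 2.
#' @param feature,group_a,group_b Labels carried into the result.
#' @param welch Use Welch's unequal-variance test instead of the pooled one.
#' @return One-row tibble: `feature`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_alr_a`, `mean_alr_b`, `t_statistic`, `p_value`, `tier`.
#' @export
group_ttest <- function(values_a, values_b, feature = NA_character_,
                        group_a = "A", group_b = "B", welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    rlang::abort("each group needs at least 2 replicates", class = "histoneptm_insufficient_n")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      rlang::abort("both groups have zero variance with different means; t undefined",
                   class = "histoneptm_degenerate_test")
    }
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  }
  p <- unname(tt$p.value)
  tibble::tibble(
    feature = feature, group_a = group_a, group_b = group_b,
    n_a = length(values_a), n_b = length(values_b),
    mean_alr_a = mean(values_a), mean_alr_b = mean(values_b),
    t_statistic = unname(tt$statistic), p_value = p,
    tier = significance_tier(p)
  )
}

significance_tier <- function(p) {
  dplyr::case_when(p < 0.05 ~ "significant",
                   p < 0.1 ~ "trend",
                   TRUE ~ "ns")
}

#' Per-feature group comparison of compositional abundances
#'
#' For every feature (by default each region x modified form; pass a
#' site-mark table with `feature_cols = c("region_id", "site", "mark")` for
#' marginal marks), transforms the replicate fractions by [alr2()] and runs
#' [group_ttest()] between two sample groups. Features with fewer than
#' `min_n` replicates in either group are skipped; the skip reasons are
#' attached as the `"skipped"` attribute. Benjamini-Hochberg q-values are
#' appended in a separate column; inference mirrors the uncorrected two-tier
#' scheme.
#'
#' @param x Long tibble with `sample_group`, `replicate`, a `fraction`
#'   column, and the feature-identifying columns.
#' @param group_a,group_b Group labels to compare (in this order).
#' @param feature_cols Columns jointly identifying a feature.
#' @param min_n Minimum replicates per group (default 2).
#' @param welch Use Welch's t-test.
#' @param delta Zero replacement delta passed to [zero_replace()] when a
#'   replicate carries an exact zero; `NULL` uses [default_delta()] per
#'   feature. Fractions of 0 or 1 only arise from explicit zero areas.
#' @return Tibble of [group_ttest()] rows plus `q_value`, ordered by p-value.
#' @export
compare_groups <- function(x, group_a, group_b,
                           feature_cols = c("region_id", "modifications"),
                           min_n = 2L, welch = FALSE, delta = NULL) {
  stopifnot(all(feature_cols %in% names(x)))
  x <- x[x$sample_group %in% c(group_a, group_b), , drop = FALSE]
  if (nrow(x) == 0L) {
    rlang::abort(sprintf("no rows for groups '%s' / '%s'", group_a, group_b),
                 class = "histoneptm_no_records")
  }
  x$.feature <- do.call(paste, c(x[feature_cols], sep = " | "))
  feats <- sort(unique(x$.feature))
  skipped <- character(0)
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    sub <- x[x$.feature == feats[i], ]
    va <- sub$fraction[sub$sample_group == group_a]
    vb <- sub$fraction[sub$sample_group == group_b]
    if (length(va) < min_n || length(vb) < min_n) {
      skipped <- c(skipped, sprintf("%s: n_a=%d, n_b=%d below min_n=%d",
                                    feats[i], length(va), length(vb), min_n))
      next
    }
    vals <- c(va, vb)
    if (any(vals <= 0 | vals >= 1)) {
      d <- if (is.null(delta)) default_delta(vals) else delta
      vals <- pmin(pmax(vals, d), 1 - d)
      va <- vals[seq_along(va)]
      vb <- vals[-seq_along(va)]
    }
    rows[[i]] <- group_ttest(alr2(va), alr2(vb), feature = feats[i],
                             group_a = group_a, group_b = group_b, welch = welch)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    rlang::abort("no feature had enough replicates in both groups",
                 class = "histoneptm_insufficient_n")
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- dplyr::arrange(out, .data$p_value)
  attr(out, "skipped") <- skipped
  out
}
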