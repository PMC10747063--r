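#' Build the clustering profile matrix
#'
#' Averages replicate compositions per sample group (forms missing from a
#' replicate are treated as not observed: the mean is taken over the
#' replicates in which the form was seen, then the group composition is
#' re-closed), drops features not quantified in every clustered unit
#' (logged in the `"dropped_features"` attribute), replaces any residual
#' zeros multiplicatively, and transforms each region's composition into
#' pivot coordinates.
#'
#' @param composition Composition tibble from [relative_abundance()].
#' @param scope `"all-peptides"` (one matrix concatenating every region's
#'   pivot coordinates, the summary-dendrogram analogue) or `"per-peptide"`
#'   (a named list of matrices, one per region).
#' @param unit `"group-mean"` (default; rows are sample groups) or
#'   `"replicate"` (rows are sample x replicate units).
#' @param delta Zero-replacement delta; `NULL` derives it per feature with
#'   [default_delta()].
#' @return Numeric matrix (or named list of matrices) with row names equal to
#'   the clustered units and attributes `"features"` and
#'   `"dropped_features"`.
#' @export
build_profile_matrix <- function(composition,
                                 scope = c("all-peptides", "per-peptide"),
                                 unit = c("group-mean", "replicate"),
                                 delta = NULL) {
  scope <- match.arg(scope)
  unit <- match.arg(unit)
  if (unit == "group-mean") {
    prof <- composition |>
      dplyr::group_by(.data$sample_group, .data$region_id, .data$modifications) |>
      dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop") |>
      dplyr::group_by(.data$sample_group, .data$region_id) |>
      dplyr::mutate(fraction = .data$fraction / sum(.data$fraction)) |>
      dplyr::ungroup() |>
      dplyr::mutate(row_unit = .data$sample_group)
  } else {
    prof <- dplyr::mutate(composition,
                          row_unit = paste(.data$sample_group, .data$replicate, sep = "/"))
  }
  units <- sort(unique(prof$row_unit))
  per_region <- function(region) {
    sub <- prof[prof$region_id == region, ]
    # the unmodified form is the empty string; prefix so it can be a column
    wide <- tidyr::pivot_wider(
      dplyr::select(sub, "row_unit", "modifications", "fraction"),
      names_from = "modifications", values_from = "fraction",
      names_prefix = "form:"
    )
    wide <- wide[match(units, wide$row_unit), , drop = FALSE]
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- units
    keep <- colSums(is.na(m)) == 0L
    dropped <- colnames(m)[!keep]
    m <- m[, keep, drop = FALSE]
    if (ncol(m) == 0L) {
      rlang::abort(sprintf("region '%s': no feature quantified in every clustered unit", region),
                   class = "histoneptm_empty_features")
    }
    m <- m / rowSums(m)  # re-close after the matrix-wide drop
    if (any(m == 0)) {
      # per-feature deltas (0.65 x smallest positive fraction observed for
      # that feature), multiplicative replacement row-wise
      deltas <- if (is.null(delta)) apply(m, 2L, default_delta) else rep(delta, ncol(m))
      for (i in seq_len(nrow(m))) {
        zeros <- m[i, ] == 0
        if (any(zeros)) {
          m[i, zeros] <- deltas[zeros]
          m[i, !zeros] <- m[i, !zeros] * (1 - sum(deltas[zeros])) / sum(m[i, !zeros])
        }
      }
    }
    pc <- t(apply(m, 1L, pivot_coordinates))
    if (ncol(m) == 2L) pc <- matrix(pc, ncol = 1L, dimnames = list(units, NULL))
    colnames(pc) <- sprintf("%s|z%d", region, seq_len(ncol(pc)))
    attr(pc, "features") <- colnames(m)
    attr(pc, "dropped_features") <- dropped
    pc
  }
  regions <- sort(unique(prof$region_id))
  mats <- lapply(regions, per_region)
  names(mats) <- regions
  if (scope == "per-peptide") return(mats)
  out <- do.call(cbind, mats)
  attr(out, "features") <- unlist(lapply(mats, attr, "features"), use.names = FALSE)
  attr(out, "dropped_features") <- unlist(lapply(mats, attr, "dropped_features"),
                                          use.names = FALSE)
  out
}

#' Average-linkage hierarchical clustering of PTM profiles
#'
#' Euclidean distances between the rows of a pivot-coordinate matrix,
#' agglomerated by unweighted average linkage (UPGMA). Average linkage is
#' monotone, so merge heights are non-decreasing.
#'
#' @param profiles Numeric matrix with one row per clustered unit (from
#'   [build_profile_matrix()]).
#' @return Object of class `c("histoneptm_clust", "hclust")` with the usual
#'   `merge`, `height`, `order`, `labels` components and the coordinate
#'   matrix attached as `$coordinates`.
#' @export
hclust_average <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) {
    rlang::abort("clustering needs at least 2 rows", class = "histoneptm_domain_error")
  }
  if (anyNA(profiles)) {
    rlang::abort("profile matrix contains missing values; drop those features first",
                 class = "histoneptm_domain_error")
  }
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = "average")
  hc$coordinates <- profiles
  class(hc) <- c("histoneptm_clust", "hclust")
  hc
}

#' Cut a cluster tree into its top k clusters
#'
#' @param hc Result of [hclust_average()].
#' @param k Number of clusters.
#' @return List of character vectors (cluster memberships), ordered by the
#'   first label of each cluster.
#' @export
top_clusters <- function(hc, k) {
  ct <- stats::cutree(hc, k = k)
  split(names(ct), ct) |> unname()
}

#' Export a dendrogram as a Newick string
#'
#' Merge heights become branch lengths via the standard ultrametric
#' conversion.
#'
#' @param hc Result of [hclust_average()].
#' @return Newick string terminated by `";"`.
#' @export
cluster_newick <- function(hc) {
  phy <- ape::as.phylo(stats::as.hclust(hc))
  ape::write.tree(phy)
}
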