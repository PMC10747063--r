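#' Pivot coordinates of a composition
#'
#' Pivot coordinates are the special case of isometric log-ratio (ilr)
#' coordinates in which the j-th coordinate contrasts part j against the
#' geometric mean of all later parts:
#' \deqn{z_j = \sqrt{\frac{D-j}{D-j+1}}\,\ln\frac{x_{(j)}}{\mathrm{gm}(x_{(j+1)},\dots,x_{(D)})},\qquad j = 1,\dots,D-1,}
#' with parts taken in `pivot_order` and natural logarithms. Because any ilr
#' basis is an isometry of the Aitchison geometry, Euclidean distances
#' between pivot coordinates equal Aitchison distances between the
#' compositions and do not depend on the pivot order.
#'
#' @param x Strictly positive composition of D >= 2 parts (closed internally).
#' @param pivot_order Permutation of `seq_along(x)` (or of `names(x)`);
#'   defaults to the input order.
#' @return Numeric vector of length D - 1.
#' @examples
#' pivot_coordinates(c(1, 1, 1) / 3)  # the barycenter maps to the origin
#' @export
pivot_coordinates <- function(x, pivot_order = seq_along(x)) {
  if (length(x) < 2L) {
    rlang::abort("pivot coordinates need D >= 2 parts", class = "histoneptm_domain_error")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort("all parts must be strictly positive; apply zero_replace first",
                 class = "histoneptm_domain_error")
  }
  if (is.character(pivot_order)) pivot_order <- match(pivot_order, names(x))
  if (length(pivot_order) != length(x) || anyNA(pivot_order) ||
      !setequal(pivot_order, seq_along(x))) {
    rlang::abort("pivot_order must be a permutation of the parts",
                 class = "histoneptm_domain_error")
  }
  x <- x[pivot_order]
  x <- x / sum(x)
  D <- length(x)
  lx <- log(x)
  # gm of the tail via reverse cumulative mean of logs
  tail_mean <- rev(cumsum(rev(lx)))[-1] / (D - seq_len(D - 1))
  sqrt((D - seq_len(D - 1)) / (D - seq_len(D - 1) + 1)) * (lx[-D] - tail_mean)
}
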