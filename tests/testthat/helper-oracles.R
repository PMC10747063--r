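# Independent brute-force oracles used to cross-check the implementation.

# UPGMA by naive O(n^3) recomputation: inter-cluster distance is the mean of
# all cross-pair distances in the ORIGINAL matrix. Returns the cophenetic
# matrix and the sorted merge heights; both are invariant to tie-breaking.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  coph <- matrix(0, n, n)
  cl <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(cl) > 1L) {
    k <- length(cl)
    bd <- Inf
    best <- c(NA_integer_, NA_integer_)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        dij <- mean(d[cl[[i]], cl[[j]]])
        if (dij < bd) {
          bd <- dij
          best <- c(i, j)
        }
      }
    }
    i <- best[1]
    j <- best[2]
    for (a in cl[[i]]) for (b in cl[[j]]) coph[a, b] <- coph[b, a] <- bd
    heights <- c(heights, bd)
    cl[[i]] <- c(cl[[i]], cl[[j]])
    cl[[j]] <- NULL
  }
  list(cophenetic = coph, heights = sort(heights))
}

# Aitchison distance via the clr transform (independent of pivot coordinates)
aitchison_dist_clr <- function(x, y) {
  lx <- log(x / sum(x))
  ly <- log(y / sum(y))
  sqrt(sum(((lx - mean(lx)) - (ly - mean(ly)))^2))
}

random_composition <- function(D, min_frac = 0) {
  repeat {
    x <- stats::rgamma(D, shape = 1)
    x <- x / sum(x)
    if (all(x > min_frac)) return(x)
  }
}
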