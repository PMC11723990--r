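## Flow-cytometry genome-size estimation and ploidy assignment.
##
## DAPI-stained nuclei of the sample are co-chopped with an internal
## standard (Nicotiana tabacum, 1C = 4.6 pg, so 2C = 9.2 pg); the ratio
## of G1-peak fluorescence means converts directly to a 2C holoploid
## genome size. Ploidy follows either by rounding against a monoploid
## (1Cx) size or by 1-D clustering of a cohort's sizes. The reported pg
## values are interpreted as 2C holoploid sizes, consistent with the
## observed ranges and chromosome counts (2n = 36x). Peak detection from
## raw FCS histograms is out of scope; inputs are instrument-reported
## peak means.

#' Convert a G1 peak pair to a 2C genome size
#'
#' @param sample_peak,standard_peak G1-peak fluorescence means (a.u.)
#'   of the sample and the internal standard; vectorized.
#' @param standard_2C_pg 2C DNA amount of the standard in pg
#'   (default 9.2 = 2 x 4.6 for *N. tabacum*).
#' @return 2C genome size(s) in pg: `sample_peak / standard_peak * standard_2C_pg`.
#' @export
genome_size <- function(sample_peak, standard_peak, standard_2C_pg = 9.2) {
  if (any(!is.finite(sample_peak)) || any(!is.finite(standard_peak)) ||
      any(sample_peak <= 0) || any(standard_peak <= 0)) {
    stop("peak means must be positive")
  }
  if (any(standard_2C_pg <= 0)) stop("standard_2C_pg must be positive")
  sample_peak / standard_peak * standard_2C_pg
}

#' Assign a ploidy level to a 2C genome size
#'
#' Picks the allowed x-multiplier minimising `|gs_2C - x * monoploid_1Cx|`.
#' Confidence is `1 - residual / (monoploid_1Cx / 2)` clipped to the
#' unit interval;
#' a residual at or beyond half a monoploid genome (including the exact
#' midpoint between two levels) is unassignable.
#'
#' @param gs_2C 2C genome size in pg (scalar).
#' @param monoploid_1Cx monoploid genome size in pg (default 6.5,
#'   about half the diploid group mean).
#' @param allowed integer ploidies considered (default 2:4).
#' @return a `ploidy_call`: list with `genome_size_2C`, `ploidy`,
#'   `method`, `confidence`.
#' @export
assign_ploidy <- function(gs_2C, monoploid_1Cx = 6.5, allowed = 2:4) {
  stopifnot(length(gs_2C) == 1L, monoploid_1Cx > 0, length(allowed) >= 1L)
  if (!is.finite(gs_2C) || gs_2C <= 0) stop("genome size must be positive")
  allowed <- sort(as.integer(allowed))
  resid <- abs(gs_2C - allowed * monoploid_1Cx)
  half <- monoploid_1Cx / 2
  if (min(resid) >= half) {
    stop(sprintf("unassignable: 2C = %.3g pg is >= %.3g pg from every allowed euploid level",
                 gs_2C, half))
  }
  ploidy <- allowed[which.min(resid)]
  ploidy_call(gs_2C, ploidy, method = "per_x_rounding",
              confidence = max(0, min(1, 1 - min(resid) / half)))
}

ploidy_call <- function(gs_2C, ploidy, method, confidence) {
  structure(list(genome_size_2C = gs_2C, ploidy = as.integer(ploidy),
                 method = method, confidence = confidence),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("<ploidy_call: 2C = %.2f pg -> %dx (%s, confidence %.2f)>\n",
              x$genome_size_2C, x$ploidy, x$method, x$confidence))
  invisible(x)
}

## Exact 1-D k-means by dynamic programming over sorted values.
## Returns cluster index per (sorted-order) value and the optimal
## within-cluster sum of squares.
kmeans_1d_dp <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1L, k <= n)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  sse <- function(i, j) {            # cost of cluster xs[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  for (j in 1:n) D[1L, j] <- sse(1L, j)
  if (k > 1L) {
    for (q in 2:k) {
      for (j in q:n) {
        for (i in q:j) {
          cand <- D[q - 1L, i - 1L] + sse(i, j)
          if (cand < D[q, j]) {
            D[q, j] <- cand
            B[q, j] <- i
          }
        }
      }
    }
  }
  cl_sorted <- integer(n)
  j <- n
  for (q in k:1) {
    i <- B[q, j]
    cl_sorted[i:j] <- q
    j <- i - 1L
  }
  cl <- integer(n)
  cl[ord] <- cl_sorted
  list(cluster = cl, wss = D[k, n])
}

#' Cluster a cohort's genome sizes into ploidy groups
#'
#' Sizes are clustered by exact dynamic-programming k-means on the
#' sorted values. The number of clusters is chosen by the largest
#' relative gap criterion: k = 1 + the number of gaps between
#' consecutive sorted sizes exceeding `rel_gap` times the data range
#' (capped to `k_range`). Clusters are ordered by mean and mapped to
#' ploidies by anchoring the smallest cluster (default 2x); the
#' remaining clusters get the nearest integer multiple of the implied
#' monoploid size.
#'
#' @param sizes numeric vector of 2C genome sizes in pg (length >= 2).
#' @param k_range candidate cluster counts (default 1:4).
#' @param anchor_ploidy ploidy of the smallest-size cluster (default 2).
#' @param rel_gap fraction of the data range a between-cluster gap must
#'   exceed (default 0.15).
#' @return list of `ploidy_call`s (method `"cluster"`), one per size,
#'   with the chosen `k` in attribute `"k"`.
#' @export
cluster_ploidy <- function(sizes, k_range = 1:4, anchor_ploidy = 2L,
                           rel_gap = 0.15) {
  stopifnot(length(sizes) >= 2L, all(sizes > 0), all(k_range >= 1L))
  xs <- sort(sizes)
  rng <- xs[length(xs)] - xs[1L]
  big_gaps <- if (rng > 0) sum(diff(xs) > rel_gap * rng) else 0L
  k <- min(max(k_range), max(min(k_range), 1L + big_gaps), length(sizes))
  fit <- kmeans_1d_dp(sizes, k)
  means <- tapply(sizes, fit$cluster, mean)
  ord <- order(means)                      # cluster labels by increasing mean
  rank_of <- match(fit$cluster, ord)
  means_sorted <- means[ord]
  implied_1Cx <- means_sorted[1L] / anchor_ploidy
  ploidies <- pmax(1L, round(means_sorted / implied_1Cx))
  calls <- lapply(seq_along(sizes), function(i) {
    p <- ploidies[rank_of[i]]
    resid <- abs(sizes[i] - p * implied_1Cx)
    ploidy_call(sizes[i], p, method = "cluster",
                confidence = max(0, min(1, 1 - resid / (implied_1Cx / 2))))
  })
  names(calls) <- names(sizes)
  attr(calls, "k") <- k
  attr(calls, "cluster_means") <- as.numeric(means_sorted)
  calls
}

#' Expected somatic chromosome number
#'
#' The complex has a base number of x = 36 chromosomes, so diploids show
#' 2n = 72 and triploids 2n = 108 at mitotic metaphase.
#'
#' @param ploidy integer ploidy level (x-multiplier).
#' @param base_x base chromosome number (default 36).
#' @return `ploidy * base_x`.
#' @export
expected_chromosomes <- function(ploidy, base_x = 36L) {
  stopifnot(all(ploidy >= 1L), all(base_x >= 1L))
  as.integer(ploidy) * as.integer(base_x)
}

#' Read a flow-cytometry peak table
#'
#' @param path CSV with columns `sample_id`, `sample_peak`,
#'   `standard_peak` and optionally `standard_2C_pg`.
#' @return data.frame with a `genome_size_2C` column appended.
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sample_peak", "standard_peak")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("flow CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(df$standard_2C_pg)) df$standard_2C_pg <- 9.2
  df$genome_size_2C <- genome_size(df$sample_peak, df$standard_peak,
                                   df$standard_2C_pg)
  df
}
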