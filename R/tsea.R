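# TCR set enrichment analysis (TSEA).
#
# Tests whether a set of clonotypes (e.g. those re-detected in a host
# organ) concentrates among the high-frequency ranks of a reference
# repertoire (the grafted cell product). The primary statistic is the
# standardized mean rank of the hits, whose null moments under sampling
# without replacement from ranks 1..N have closed forms; significance comes
# from a permutation null over random same-size key sets, with the add-one
# estimator so p-values are never zero. A GSEA-style running-sum enrichment
# score and a windowed "worm" density (fixed neutral level 1) accompany the
# test for visualization parity with barcode plots.

#' Rank a graft repertoire by clone frequency
#'
#' Clones sorted by descending UMI count, ties broken deterministically by
#' lexicographic clone key; frequencies normalized to sum to 1.
#'
#' @param graft A non-empty `RepertoireTable`.
#' @param level Clonotype key level.
#' @return A tibble of class `RankedReference` with columns `rank`,
#'   `clone_key`, `frequency` (non-increasing); the tie policy is recorded
#'   in attribute `"tie_policy"`.
#' @export
rank_reference <- function(graft, level = "nt") {
  stopifnot(inherits(graft, "RepertoireTable"))
  if (graft$total_umis == 0L) stop("cannot rank an empty graft repertoire")
  keys <- clone_keys(graft, level)
  counts <- graft$records$umi_count
  ord <- order(-counts, keys)
  out <- tibble(
    rank = seq_along(ord),
    clone_key = keys[ord],
    frequency = counts[ord] / sum(counts)
  )
  attr(out, "tie_policy") <- "count_desc_then_lexicographic_key"
  class(out) <- c("RankedReference", class(out))
  out
}

null_mean_rank_moments <- function(N, k) {
  e0 <- (N + 1) / 2
  v0 <- if (k == N) 0 else (N - k) / (N - 1) * (N^2 - 1) / 12 / k
  list(mean = e0, sd = sqrt(v0))
}

standardized_mean_rank <- function(ranks, N) {
  k <- length(ranks)
  m <- null_mean_rank_moments(N, k)
  if (m$sd == 0) return(0)
  (m$mean - mean(ranks)) / m$sd
}

running_sum_es <- function(hit_ranks, N) {
  k <- length(hit_ranks)
  if (k == N) return(0)
  r <- sort(hit_ranks)
  i <- seq_len(k)
  at_hit <- i / k - (r - i) / (N - k)
  before_hit <- (i - 1) / k - (r - 1 - (i - 1)) / (N - k)
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' TCR set enrichment test
#'
#' Tests whether the query clonotypes sit higher in the frequency-ranked
#' reference than random same-size sets. Query keys absent from the
#' reference carry no rank; they are excluded from the statistic and
#' reported in `n_absent` (an all-absent query is an error, not a silent
#' zero).
#'
#' @param query Character vector of clonotype keys (duplicates removed).
#' @param ref A [rank_reference()] result.
#' @param n_perm Number of permutations (`>= 99`); p-values use the add-one
#'   estimator `(1 + #extreme) / (n_perm + 1)`.
#' @param seed Integer seed for the permutation draws.
#' @param alternative `"toward_top"` (one-sided enrichment toward rank 1,
#'   default) or `"two_sided"`.
#' @param window,step Worm density window and step (defaults: window
#'   `ceiling(N / 25)`, step = window). See [worm_density()].
#' @return A list of class `TseaResult`: `query_size`, `hits`, `n_absent`,
#'   `mean_rank_stat`, `es`, `p_value`, `n_perm`, `alternative`, `worm`,
#'   `window`, `step`, `seed`.
#' @export
tsea_test <- function(query, ref, n_perm = 999L, seed = 1L,
                      alternative = c("toward_top", "two_sided"),
                      window = NULL, step = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(ref, "RankedReference"), is.character(query))
  if (n_perm < 99L) stop("n_perm must be at least 99")
  query <- unique(query)
  if (!length(query)) stop("query is empty")
  N <- nrow(ref)
  hit_ranks <- ref$rank[ref$clone_key %in% query]
  k <- length(hit_ranks)
  n_absent <- length(query) - k
  if (k == 0L) {
    stop("no query clonotype appears in the reference (", length(query),
         " keys checked)")
  }
  obs <- standardized_mean_rank(hit_ranks, N)
  effect <- function(s) if (alternative == "toward_top") s else abs(s)
  perm <- with_seed(derive_seed(seed, "tsea_perm"), {
    vapply(seq_len(n_perm), function(i) {
      standardized_mean_rank(sample.int(N, k), N)
    }, numeric(1))
  })
  p_value <- (1 + sum(effect(perm) >= effect(obs))) / (n_perm + 1)
  window <- as.integer(window %||% max(1L, ceiling(N / 25)))
  step <- as.integer(step %||% window)
  worm <- worm_density(query, ref, window = window, step = step)
  structure(
    list(query_size = length(query), hits = k, n_absent = n_absent,
         mean_rank_stat = obs, es = running_sum_es(hit_ranks, N),
         p_value = p_value, n_perm = as.integer(n_perm),
         alternative = alternative, worm = worm, window = window,
         step = step, seed = as.integer(seed)),
    class = "TseaResult"
  )
}

#' @export
print.TseaResult <- function(x, ...) {
  cat(sprintf(paste0("TSEA: %d query keys, %d hits (%d absent from reference)\n",
                     "  standardized mean rank = %.3f, ES = %.3f\n",
                     "  permutation p = %.4g (%d permutations, %s)\n"),
              x$query_size, x$hits, x$n_absent, x$mean_rank_stat, x$es,
              x$p_value, x$n_perm, x$alternative))
  invisible(x)
}

#' Windowed relative enrichment density ("worm")
#'
#' For each window position along the ranked reference, the hit density
#' inside the window divided by the overall hit density `k / N`. The
#' neutral level is 1 everywhere and identical across calls, so worms from
#' different organ/graft pairs share a fixed scale; the attainable bounds
#' `[0, N / window]` are attached as attribute `"scale_bounds"`.
#'
#' @param query Character vector of clonotype keys.
#' @param ref A [rank_reference()] result.
#' @param window Window width in ranks, `1 <= window <= N`.
#' @param step Window start spacing; the output has `ceiling(N / step)`
#'   entries.
#' @return Numeric vector of non-negative densities with attributes
#'   `"positions"` (window starts), `"neutral"` (1) and `"scale_bounds"`.
#'   An empty or all-absent query yields an all-zero worm with a warning.
#' @export
worm_density <- function(query, ref, window, step = window) {
  stopifnot(inherits(ref, "RankedReference"))
  N <- nrow(ref)
  if (!is_count_scalar(window) || window < 1 || window > N) {
    stop("window must lie in [1, ", N, "]")
  }
  if (!is_count_scalar(step) || step < 1) stop("step must be a positive integer")
  hit <- ref$clone_key %in% unique(query)
  k <- sum(hit)
  starts <- seq.int(1L, N, by = step)
  if (k == 0L) {
    warning("query has no hits in the reference; worm is all zero")
    dens <- numeric(length(starts))
  } else {
    dens <- vapply(starts, function(s) {
      e <- min(s + window - 1L, N)
      mean(hit[s:e]) / (k / N)
    }, numeric(1))
  }
  attr(dens, "positions") <- starts
  attr(dens, "neutral") <- 1
  attr(dens, "scale_bounds") <- c(0, N / window)
  dens
}
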