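# Rarefaction and inverse Simpson diversity.
#
# UMI counts are digital molecule counts, so rarefaction draws UMIs without
# replacement: the rarefied clone-size vector follows a multivariate
# hypergeometric distribution. Sampling is implemented by drawing `depth`
# distinct UMI indices and mapping them back to clones, which is exactly
# that distribution.

#' Downsample a repertoire to a fixed UMI depth
#'
#' Draws `depth` UMIs without replacement (multivariate hypergeometric) from
#' the table's clone-size vector. Clones that lose all their UMIs are
#' removed. No upsampling: requesting more UMIs than the table holds is an
#' error.
#'
#' @param x A `RepertoireTable`.
#' @param depth Target number of UMIs, `0 <= depth <= x$total_umis`.
#' @param seed Optional integer seed; when given, the draw is deterministic
#'   and the caller's RNG state is untouched.
#' @return A `RepertoireTable` with `total_umis == depth`.
#' @export
downsample <- function(x, depth, seed = NULL) {
  stopifnot(inherits(x, "RepertoireTable"), is_count_scalar(depth))
  if (depth > x$total_umis) {
    stop("requested depth ", depth, " exceeds total_umis ", x$total_umis,
         " of sample ", x$meta$sample_id, " (no upsampling)")
  }
  if (depth == x$total_umis) return(x)
  draw <- function() {
    counts <- x$records$umi_count
    if (depth == 0L || !length(counts)) return(integer(length(counts)))
    picked <- sample.int(x$total_umis, depth)
    tabulate(findInterval(picked - 0.5, c(0, cumsum(counts))), nbins = length(counts))
  }
  new_counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  records <- x$records
  records$umi_count <- new_counts
  records <- records[new_counts > 0L, , drop = FALSE]
  repertoire_table(records, x$meta)
}

#' Inverse Simpson index
#'
#' The effective number of equally sized clones, `1 / sum(p_i^2)` with
#' `p_i` the clone proportions. Equals the clone count for a perfectly even
#' repertoire and 1 for a monoclonal one; invariant to rescaling all counts.
#'
#' @param x A `RepertoireTable` (or a bare vector of positive counts).
#' @return A number in `[1, richness]`.
#' @export
inverse_simpson <- function(x) {
  counts <- if (inherits(x, "RepertoireTable")) x$records$umi_count else x
  counts <- counts[counts > 0]
  if (!length(counts)) {
    stop("inverse Simpson index is undefined for an empty repertoire")
  }
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Rarefied diversity profile across samples
#'
#' Computes the inverse Simpson index of each sample after downsampling to a
#' common depth, averaging over `n_reps` independent hypergeometric draws
#' (the standard deviation across repetitions is reported alongside). Each
#' sample gets its own seed derived from the global seed and its
#' `sample_id`, so adding samples never changes existing results.
#'
#' @param tables List of non-empty `RepertoireTable`s.
#' @param depth `"min_common"` (default; the smallest `total_umis` among the
#'   tables) or a fixed integer depth no larger than every table's total.
#' @param n_reps Number of independent downsampling repetitions (default 25).
#' @param seed Global integer seed.
#' @return A tibble with columns `sample_id`, `depth`, `n_reps`, `isi`,
#'   `isi_sd`, `seed`.
#' @export
diversity_profile <- function(tables, depth = "min_common", n_reps = 25L,
                              seed = 1L) {
  stopifnot(is.list(tables), length(tables) >= 1L, n_reps >= 1L)
  totals <- vapply(tables, function(t) t$total_umis, integer(1))
  ids <- vapply(tables, function(t) t$meta$sample_id, character(1))
  if (any(totals == 0L)) {
    stop("empty repertoire table(s): ", paste(ids[totals == 0L], collapse = ", "))
  }
  if (identical(depth, "min_common")) {
    depth <- min(totals)
  } else {
    stopifnot(is_count_scalar(depth), depth >= 1)
    if (any(depth > totals)) {
      stop("fixed depth ", depth, " exceeds total_umis of sample(s): ",
           paste(ids[depth > totals], collapse = ", "))
    }
  }
  rows <- lapply(seq_along(tables), function(i) {
    sample_seed <- derive_seed(seed, "diversity", ids[i])
    isis <- with_seed(sample_seed, {
      vapply(seq_len(n_reps),
             function(j) inverse_simpson(downsample(tables[[i]], depth)),
             numeric(1))
    })
    tibble(sample_id = ids[i], depth = as.integer(depth),
           n_reps = as.integer(n_reps), isi = mean(isis),
           isi_sd = if (n_reps > 1L) stats::sd(isis) else 0,
           seed = sample_seed)
  })
  dplyr::bind_rows(rows)
}
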