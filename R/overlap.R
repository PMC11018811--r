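# Pairwise repertoire similarity and UMI-sharing summaries.
#
# Morisita-Horn is the default index: bounded in [0, 1], defined on clone
# proportions, 1 iff the proportion vectors coincide and 0 iff the key sets
# are disjoint. The classical Morisita index (unbiased Simpson terms) is
# offered as a variant; it may exceed 1 for small samples. Directional and
# pooled UMI-overlap fractions feed circos-style sharing plots.

count_vector <- function(x, level = "nt") {
  stats::setNames(as.numeric(x$records$umi_count), clone_keys(x, level))
}

check_overlap_pair <- function(x, y) {
  stopifnot(inherits(x, "RepertoireTable"), inherits(y, "RepertoireTable"))
  if (x$total_umis == 0L || y$total_umis == 0L) {
    stop("overlap is undefined for empty repertoires")
  }
  if (!identical(table_chains(x), table_chains(y))) {
    stop("cannot compare repertoires of different chains (",
         x$meta$sample_id, " vs ", y$meta$sample_id, ")")
  }
}

#' Morisita-Horn overlap index
#'
#' `2 * sum(p_i q_i) / (sum(p_i^2) + sum(q_i^2))` over the union of
#' clonotype keys, with `p`, `q` the clone proportions of the two samples.
#'
#' @param x,y Non-empty `RepertoireTable`s of the same chain.
#' @param level Clonotype key level, `"nt"` or `"aa"`.
#' @return A number in `[0, 1]`.
#' @export
morisita_horn <- function(x, y, level = "nt") {
  check_overlap_pair(x, y)
  cx <- count_vector(x, level); cy <- count_vector(y, level)
  keys <- union(names(cx), names(cy))
  p <- unname(cx[keys]); p[is.na(p)] <- 0; p <- p / sum(p)
  q <- unname(cy[keys]); q[is.na(q)] <- 0; q <- q / sum(q)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

#' Classical Morisita overlap index
#'
#' Uses the unbiased Simpson concentration `lambda = sum(n_i (n_i - 1)) /
#' (N (N - 1))` in the denominator, so the index can slightly exceed 1 for
#' small samples (a warning flags that case).
#'
#' @inheritParams morisita_horn
#' @return A non-negative number (usually in `[0, 1]`; may exceed 1 for
#'   small samples).
#' @export
morisita_classical <- function(x, y, level = "nt") {
  check_overlap_pair(x, y)
  if (x$total_umis < 2L || y$total_umis < 2L) {
    stop("classical Morisita requires at least 2 UMIs per sample")
  }
  cx <- count_vector(x, level); cy <- count_vector(y, level)
  keys <- union(names(cx), names(cy))
  nx <- unname(cx[keys]); nx[is.na(nx)] <- 0
  ny <- unname(cy[keys]); ny[is.na(ny)] <- 0
  Nx <- sum(nx); Ny <- sum(ny)
  lx <- sum(nx * (nx - 1)) / (Nx * (Nx - 1))
  ly <- sum(ny * (ny - 1)) / (Ny * (Ny - 1))
  val <- 2 * sum(nx * ny) / ((lx + ly) * Nx * Ny)
  if (is.finite(val) && val > 1) {
    warning("classical Morisita index ", format(val, digits = 4),
            " exceeds 1 (small-sample bias)")
  }
  val
}

#' UMI-overlap fraction between two repertoires
#'
#' `directional`: the fraction of `x`'s UMIs belonging to clonotypes whose
#' key is also detected in `y`. `pooled`: the shared-clonotype UMI mass of
#' both samples over their combined total.
#'
#' @inheritParams morisita_horn
#' @param mode `"directional"` (x relative to y) or `"pooled"`.
#' @return A number in `[0, 1]`.
#' @export
umi_overlap_fraction <- function(x, y, mode = c("directional", "pooled"),
                                 level = "nt") {
  mode <- match.arg(mode)
  check_overlap_pair(x, y)
  cx <- count_vector(x, level); cy <- count_vector(y, level)
  shared <- intersect(names(cx), names(cy))
  if (mode == "directional") {
    sum(cx[shared]) / sum(cx)
  } else {
    (sum(cx[shared]) + sum(cy[shared])) / (sum(cx) + sum(cy))
  }
}

#' Pairwise overlap matrix
#'
#' Fills a samples-by-samples matrix with the chosen overlap statistic.
#' `morisita_horn` and `morisita_classical` matrices are symmetric;
#' `umi_fraction` is directional (entry `[i, j]` is the fraction of sample
#' i's UMIs shared with sample j). Pairs for which the statistic is
#' undefined become `NA` with a warning.
#'
#' @param tables List of `RepertoireTable`s (at least 2).
#' @param method `"morisita_horn"` (default), `"morisita_classical"` or
#'   `"umi_fraction"`.
#' @param level Clonotype key level, `"nt"` or `"aa"`.
#' @return A numeric matrix with sample ids as dimnames and the method in
#'   attribute `"method"`.
#' @export
pairwise_overlap <- function(tables,
                             method = c("morisita_horn", "morisita_classical",
                                        "umi_fraction"),
                             level = "nt") {
  method <- match.arg(method)
  stopifnot(is.list(tables), length(tables) >= 2L)
  ids <- vapply(tables, function(t) t$meta$sample_id, character(1))
  n <- length(tables)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  fun <- switch(method,
                morisita_horn = morisita_horn,
                morisita_classical = morisita_classical,
                umi_fraction = function(x, y, level) {
                  umi_overlap_fraction(x, y, mode = "directional", level = level)
                })
  failed <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (method != "umi_fraction" && j < i) {
        m[i, j] <- m[j, i]
        next
      }
      m[i, j] <- tryCatch(
        suppressWarnings(fun(tables[[i]], tables[[j]], level = level)),
        error = function(e) {
          failed <<- c(failed, paste0(ids[i], "~", ids[j]))
          NA_real_
        })
    }
  }
  if (length(failed)) {
    warning("overlap undefined for pair(s): ", paste(failed, collapse = ", "))
  }
  attr(m, "method") <- method
  m
}

#' Per-clonotype presence-pattern summary
#'
#' For every subset pattern of samples (encoded as a string of 0/1 flags in
#' sample order), counts the clonotypes detected in exactly that pattern and
#' their total UMI/cell mass. The masses sum to the union totals and the
#' clonotype counts to the size of the key union.
#'
#' @param tables List of `RepertoireTable`s (at least 2).
#' @param level Clonotype key level.
#' @return A tibble with columns `pattern`, `n_samples`, `n_clonotypes`,
#'   `total_mass`; sample order is recorded in attribute `"sample_ids"`.
#' @export
sharing_summary <- function(tables, level = "nt") {
  stopifnot(is.list(tables), length(tables) >= 2L)
  ids <- vapply(tables, function(t) t$meta$sample_id, character(1))
  vecs <- lapply(tables, count_vector, level = level)
  keys <- Reduce(union, lapply(vecs, names))
  present <- vapply(vecs, function(v) keys %in% names(v), logical(length(keys)))
  if (length(keys) == 1L) present <- matrix(present, nrow = 1L)
  mass <- vapply(vecs, function(v) {
    out <- unname(v[keys]); out[is.na(out)] <- 0; out
  }, numeric(length(keys)))
  if (length(keys) == 1L) mass <- matrix(mass, nrow = 1L)
  pattern <- apply(present, 1L, function(z) paste(as.integer(z), collapse = ""))
  agg_n <- table(pattern)
  agg_mass <- rowsum(rowSums(mass), pattern)
  out <- tibble(
    pattern = names(agg_n),
    n_samples = vapply(strsplit(names(agg_n), ""), function(z) sum(z == "1"),
                       integer(1)),
    n_clonotypes = as.integer(agg_n),
    total_mass = as.numeric(agg_mass[names(agg_n), 1L])
  )
  out <- out[order(-out$n_samples, out$pattern), ]
  attr(out, "sample_ids") <- ids
  out
}

#' Circos-ready pairwise link table
#'
#' One row per ordered sample pair with the shared clonotype mass and the
#' directional overlap fractions at both band endpoints, plus the pooled
#' fraction used for printed totals.
#'
#' @inheritParams sharing_summary
#' @return A tibble with columns `source`, `target`, `shared_mass`,
#'   `source_fraction`, `target_fraction`, `pooled_fraction`.
#' @export
overlap_links <- function(tables, level = "nt") {
  stopifnot(is.list(tables), length(tables) >= 2L)
  ids <- vapply(tables, function(t) t$meta$sample_id, character(1))
  rows <- list()
  for (i in seq_along(tables)) {
    for (j in seq_along(tables)) {
      if (j <= i) next
      cx <- count_vector(tables[[i]], level)
      cy <- count_vector(tables[[j]], level)
      shared <- intersect(names(cx), names(cy))
      rows[[length(rows) + 1L]] <- tibble(
        source = ids[i], target = ids[j],
        shared_mass = sum(cx[shared]) + sum(cy[shared]),
        source_fraction = sum(cx[shared]) / sum(cx),
        target_fraction = sum(cy[shared]) / sum(cy),
        pooled_fraction = (sum(cx[shared]) + sum(cy[shared])) / (sum(cx) + sum(cy))
      )
    }
  }
  dplyr::bind_rows(rows)
}
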