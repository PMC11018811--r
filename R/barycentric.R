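# Barycentric clone-distribution geometry over three compartments.
#
# Every clonotype detected in up to three compartments maps to a point in a
# triangle: the barycentric weights are the per-compartment contributions
# (summing to 1) and the bubble size is the clone's normalized abundance.
# Frequency mode normalizes counts by compartment depth first, so weights
# are invariant to sequencing-depth differences between compartments.

#' Barycentric coordinates of one clone across three compartments
#'
#' Frequency mode (default): `f_X = count_X / depth_X`, `w_X = f_X / sum(f)`
#' and `size = mean(f)`; weights are then invariant to rescaling any
#' compartment's depth. Raw mode: `w_X = count_X / sum(counts)` and
#' `size = sum(counts) / sum(depths)`, appropriate when depths are
#' comparable (e.g. replicate triangles).
#'
#' @param counts Numeric vector of 3 non-negative per-compartment counts,
#'   at least one positive.
#' @param depths Numeric vector of 3 per-compartment totals; must be
#'   positive wherever the clone was detected.
#' @param normalization `"frequency"` or `"raw"`.
#' @return A list of class `BarycentricPoint` with elements `weights`
#'   (summing to 1), `size`, `raw_counts`, `normalization`.
#' @export
barycentric_coordinates <- function(counts, depths,
                                    normalization = c("frequency", "raw")) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(counts), length(counts) == 3L,
            is.numeric(depths), length(depths) == 3L)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero counts: barycentric point undefined")
  if (any(counts > 0 & depths <= 0)) {
    stop("positive count in a compartment with non-positive depth")
  }
  if (normalization == "frequency") {
    f <- ifelse(counts > 0, counts / depths, 0)
    w <- f / sum(f)
    size <- mean(f)
  } else {
    w <- counts / sum(counts)
    size <- sum(counts) / sum(depths)
  }
  structure(list(weights = unname(w), size = size,
                 raw_counts = unname(counts), normalization = normalization),
            class = "BarycentricPoint")
}

#' Barycentric points for all clones of three compartments
#'
#' Builds the full clone-by-clone triangle map from three repertoire tables
#' (one per compartment): barycentric weights, normalized size, triangle
#' plotting coordinates (`tri_x = w2 + w3 / 2`, `tri_y = sqrt(3)/2 * w3`)
#' and the distribution class from [classify_distribution()].
#'
#' @param tables List of exactly 3 `RepertoireTable`s; their sample ids name
#'   the triangle corners.
#' @param normalization Passed to [barycentric_coordinates()].
#' @param dominance_threshold Passed to [classify_distribution()].
#' @param level Clonotype key level.
#' @return A tibble with columns `clone_key`, `w1`, `w2`, `w3`, `size`,
#'   `tri_x`, `tri_y`, `class`; corner sample ids in attribute
#'   `"compartments"`.
#' @export
barycentric_points <- function(tables, normalization = c("frequency", "raw"),
                               dominance_threshold = 0.9, level = "nt") {
  normalization <- match.arg(normalization)
  stopifnot(is.list(tables), length(tables) == 3L)
  ids <- vapply(tables, function(t) t$meta$sample_id, character(1))
  depths <- vapply(tables, function(t) as.numeric(t$total_umis), numeric(1))
  vecs <- lapply(tables, count_vector, level = level)
  keys <- sort(Reduce(union, lapply(vecs, names)))
  counts <- vapply(vecs, function(v) {
    out <- unname(v[keys]); out[is.na(out)] <- 0; out
  }, numeric(length(keys)))
  if (length(keys) == 1L) counts <- matrix(counts, nrow = 1L)
  if (normalization == "frequency") {
    f <- sweep(counts, 2L, depths, "/")
    w <- f / rowSums(f)
    size <- rowMeans(f)
  } else {
    w <- counts / rowSums(counts)
    size <- rowSums(counts) / sum(depths)
  }
  out <- tibble(
    clone_key = keys,
    w1 = w[, 1L], w2 = w[, 2L], w3 = w[, 3L],
    size = size,
    tri_x = w[, 2L] + w[, 3L] / 2,
    tri_y = sqrt(3) / 2 * w[, 3L],
    class = classify_distribution(w, dominance_threshold = dominance_threshold,
                                  compartments = ids)
  )
  out <- out[order(-out$size, out$clone_key), ]
  attr(out, "compartments") <- ids
  attr(out, "normalization") <- normalization
  out
}

#' Largest clones of a table or clone set
#'
#' The `n` largest clones, ties at the cutoff broken deterministically by
#' lexicographic clone key. For a `RepertoireTable` size means UMI count;
#' for a [barycentric_points()] tibble it means the normalized `size`
#' column. Asking for more clones than exist returns everything with a
#' warning.
#'
#' @param x A `RepertoireTable` or a barycentric points tibble.
#' @param n Number of clones to keep (`n >= 1`).
#' @return Object of the same type restricted to the top `n` clones.
#' @export
top_clones <- function(x, n) {
  stopifnot(is_count_scalar(n), n >= 1)
  if (inherits(x, "RepertoireTable")) {
    avail <- nrow(x$records)
    if (n > avail) {
      warning("requested ", n, " clones but only ", avail, " available")
      n <- avail
    }
    ord <- order(-x$records$umi_count, clone_keys(x))
    out <- x
    out$records <- x$records[ord[seq_len(n)], , drop = FALSE]
    out$total_umis <- as.integer(sum(out$records$umi_count))
    return(out)
  }
  if (is.data.frame(x) && all(c("clone_key", "size") %in% names(x))) {
    avail <- nrow(x)
    if (n > avail) {
      warning("requested ", n, " clones but only ", avail, " available")
      n <- avail
    }
    ord <- order(-x$size, x$clone_key)
    return(x[ord[seq_len(n)], , drop = FALSE])
  }
  stop("top_clones() expects a RepertoireTable or a barycentric points tibble")
}

#' Classify a clone's compartment distribution
#'
#' `restricted(X)` if all weight sits in compartment X; `biased(X)` if
#' compartment X holds at least `dominance_threshold` of the weight (but not
#' all of it); `ubiquitous` otherwise. The threshold must exceed 1/3, below
#' which "dominant" is meaningless for three compartments.
#'
#' @param weights Numeric vector of 3 barycentric weights, or a 3-column
#'   matrix of them (one clone per row).
#' @param dominance_threshold Number in `(1/3, 1]`; default 0.9.
#' @param compartments Character labels for the three compartments.
#' @return Character vector of classes, e.g. `"restricted(colon)"`,
#'   `"biased(spleen)"`, `"ubiquitous"`.
#' @export
classify_distribution <- function(weights, dominance_threshold = 0.9,
                                  compartments = c("A", "B", "C")) {
  if (!is.matrix(weights)) weights <- matrix(weights, nrow = 1L)
  stopifnot(ncol(weights) == 3L, length(compartments) == 3L)
  if (!is.numeric(dominance_threshold) || length(dominance_threshold) != 1L ||
      dominance_threshold <= 1 / 3 || dominance_threshold > 1) {
    stop("dominance_threshold must lie in (1/3, 1]")
  }
  if (any(abs(rowSums(weights) - 1) > 1e-8)) {
    stop("barycentric weights must sum to 1")
  }
  top <- max.col(weights, ties.method = "first")
  wmax <- weights[cbind(seq_len(nrow(weights)), top)]
  ifelse(wmax >= 1 - 1e-12, paste0("restricted(", compartments[top], ")"),
         ifelse(wmax >= dominance_threshold,
                paste0("biased(", compartments[top], ")"),
                "ubiquitous"))
}
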