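# V-beta (Trbv) gene-segment usage and set enrichment.
#
# Usage frequencies are computed per sample, weighting either by clonotype
# or by UMI; records with ambiguous multi-hit V calls are excluded by
# default (their number is reported). Designated segment sets are tested
# for enrichment in each group against all other groups with a two-sided
# Fisher exact test, Benjamini-Hochberg corrected across groups.

is_ambiguous_v <- function(records) {
  records$v_ambiguous | grepl(",", records$v_call, fixed = TRUE)
}

#' Gene-segment usage frequencies of one sample
#'
#' @param x A non-empty `RepertoireTable`.
#' @param weighting `"by_clone"` (each clonotype counts once, default) or
#'   `"by_umi"` (clonotypes weighted by UMI count).
#' @param ambig_policy `"exclude"` drops records with ambiguous multi-hit V
#'   calls (counting them); `"keep_first"` keeps them under their first hit.
#' @return A tibble of class `SegmentUsage` with columns `segment`, `count`,
#'   `freq` (summing to 1 over retained segments); attributes `sample_id`,
#'   `weighting`, `excluded_ambiguous`.
#' @export
segment_frequencies <- function(x, weighting = c("by_clone", "by_umi"),
                                ambig_policy = c("exclude", "keep_first")) {
  weighting <- match.arg(weighting)
  ambig_policy <- match.arg(ambig_policy)
  stopifnot(inherits(x, "RepertoireTable"))
  r <- x$records
  if (!nrow(r)) stop("segment usage is undefined for an empty table")
  ambiguous <- is_ambiguous_v(r)
  excluded <- 0L
  if (ambig_policy == "exclude") {
    excluded <- sum(ambiguous)
    r <- r[!ambiguous, , drop = FALSE]
    if (!nrow(r)) stop("all records carry ambiguous V calls; no usage left")
  }
  seg <- normalize_segment(vapply(strsplit(r$v_call, ",", fixed = TRUE),
                                  `[`, character(1), 1L))
  w <- if (weighting == "by_clone") rep(1, nrow(r)) else as.numeric(r$umi_count)
  agg <- rowsum(w, seg)
  out <- tibble(segment = rownames(agg), count = as.numeric(agg[, 1L]))
  out$freq <- out$count / sum(out$count)
  out <- out[order(-out$count, out$segment), ]
  structure(out, sample_id = x$meta$sample_id, weighting = weighting,
            excluded_ambiguous = excluded,
            class = c("SegmentUsage", class(out)))
}

#' Samples-by-segments usage matrix
#'
#' @param tables List of `RepertoireTable`s.
#' @inheritParams segment_frequencies
#' @return Numeric matrix of usage frequencies, samples in rows, segments in
#'   columns (union over samples, absent segments 0).
#' @export
segment_usage_matrix <- function(tables, weighting = c("by_clone", "by_umi"),
                                 ambig_policy = c("exclude", "keep_first")) {
  weighting <- match.arg(weighting)
  ambig_policy <- match.arg(ambig_policy)
  usages <- lapply(tables, segment_frequencies, weighting = weighting,
                   ambig_policy = ambig_policy)
  segs <- sort(Reduce(union, lapply(usages, function(u) u$segment)))
  m <- t(vapply(usages, function(u) {
    out <- stats::setNames(numeric(length(segs)), segs)
    out[u$segment] <- u$freq
    out
  }, numeric(length(segs))))
  rownames(m) <- vapply(tables, function(t) t$meta$sample_id, character(1))
  m
}

fisher_two_sided <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE),
                     alternative = "two.sided")$p.value
}

#' Enrichment of a gene-segment set across groups
#'
#' For each group, builds the 2x2 contingency table (units carrying an
#' in-set segment vs any other segment) x (this group vs all other groups),
#' computes a two-sided Fisher exact p-value and the sample odds ratio
#' (Haldane 0.5 correction when a cell is zero, flagged in the `haldane`
#' column), then adjusts p across groups with Benjamini-Hochberg. Segment
#' names are matched case-insensitively.
#'
#' @param groups Named list of `RepertoireTable`s (one per group; bulk) or
#'   of `PairedCloneSet`s (single-cell; the TRB V gene is used).
#' @param segment_set Character vector of segment names; default the three
#'   colon-enriched segments `TRBV12-1`, `TRBV12-2`, `TRBV26`.
#' @param unit Counting unit: `"clone"` (default for bulk), `"umi"`, or
#'   `"cell"` (for `PairedCloneSet`s).
#' @param ambig_policy Ambiguous-V policy for bulk tables, see
#'   [segment_frequencies()].
#' @return A tibble with one row per group: `group`, `set_in_group`,
#'   `nonset_in_group`, `set_in_rest`, `nonset_in_rest`, `odds_ratio`,
#'   `haldane`, `p`, `p_adj`.
#' @export
segment_set_enrichment <- function(groups,
                                   segment_set = c("TRBV12-1", "TRBV12-2",
                                                   "TRBV26"),
                                   unit = c("clone", "umi", "cell"),
                                   ambig_policy = c("exclude", "keep_first")) {
  unit <- match.arg(unit)
  ambig_policy <- match.arg(ambig_policy)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list")
  }
  segment_set <- normalize_segment(segment_set)

  unit_counts <- function(g) {
    if (inherits(g, "PairedCloneSet")) {
      seg <- normalize_segment(g$trb_v)
      w <- if (unit == "cell") as.numeric(g$cell_count) else rep(1, nrow(g))
    } else if (inherits(g, "RepertoireTable")) {
      r <- g$records
      keep <- if (ambig_policy == "exclude") !is_ambiguous_v(r) else rep(TRUE, nrow(r))
      r <- r[keep, , drop = FALSE]
      seg <- normalize_segment(vapply(strsplit(r$v_call, ",", fixed = TRUE),
                                      `[`, character(1), 1L))
      w <- if (unit == "umi") as.numeric(r$umi_count) else rep(1, nrow(r))
    } else {
      stop("groups must contain RepertoireTable or PairedCloneSet objects")
    }
    c(in_set = sum(w[seg %in% segment_set]), out_set = sum(w[!seg %in% segment_set]))
  }

  counts <- vapply(groups, unit_counts, numeric(2))
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning("group(s) with zero units excluded: ",
            paste(names(groups)[empty], collapse = ", "))
    counts <- counts[, !empty, drop = FALSE]
  }
  if (ncol(counts) < 2L) stop("need at least two non-empty groups")

  rows <- lapply(seq_len(ncol(counts)), function(i) {
    a <- counts["in_set", i]
    b <- counts["out_set", i]
    c_ <- sum(counts["in_set", -i])
    d <- sum(counts["out_set", -i])
    haldane <- any(c(a, b, c_, d) == 0)
    or_cells <- if (haldane) c(a, b, c_, d) + 0.5 else c(a, b, c_, d)
    tibble(
      group = colnames(counts)[i],
      set_in_group = a, nonset_in_group = b,
      set_in_rest = c_, nonset_in_rest = d,
      odds_ratio = (or_cells[1] * or_cells[4]) / (or_cells[2] * or_cells[3]),
      haldane = haldane,
      p = fisher_two_sided(a, b, c_, d)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sorted ascending,
#' `p_adj(i) = min over j >= i of min(1, p(j) * m / j)`, returned in the
#' input order. Thin validating wrapper around `stats::p.adjust`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p_values must be numbers in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
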