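# Reading, validating, pooling and writing clonotype tables.
#
# A "repertoire table" couples one sample's clonotype records (chain, V/J
# call, CDR3 nucleotide/amino-acid sequence, UMI count) with sample metadata.
# Clonotypes are keyed by (chain, v_call, j_call, cdr3_nt); V/J alleles and
# alignment scores are stripped before keying so bulk and single-cell keys
# are comparable.

.ORGANS     <- c("donor", "spleen", "liver", "colon", "other")
.TREATMENTS <- c("fresh", "allo", "poly")
.SETTINGS   <- c("donor_product", "GvHD", "noGvHD", "noBMT")

#' Sample metadata
#'
#' Describes the provenance of one repertoire sample: which organ it was
#' re-isolated from, which recipient animal, which in vitro expansion
#' protocol produced the graft (`fresh` = unexpanded, `allo` =
#' allo-antigen-driven, `poly` = polyclonal CD3/CD28 expansion) and which
#' experimental setting it belongs to. The graft itself carries
#' `organ = "donor"` and `setting = "donor_product"`; the two imply each
#' other.
#'
#' @param sample_id Unique sample identifier.
#' @param organ One of `"donor"`, `"spleen"`, `"liver"`, `"colon"`, `"other"`.
#' @param treatment One of `"fresh"`, `"allo"`, `"poly"`.
#' @param setting One of `"donor_product"`, `"GvHD"`, `"noGvHD"`, `"noBMT"`.
#' @param recipient_id Recipient animal identifier, or `NA` for pre-transfer
#'   samples.
#' @param replicate Replicate label, or `NA`.
#' @return A `SampleMeta` list.
#' @export
sample_meta <- function(sample_id, organ = "other", treatment = "fresh",
                        setting = "noBMT", recipient_id = NA_character_,
                        replicate = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  organ <- match.arg(organ, .ORGANS)
  treatment <- match.arg(treatment, .TREATMENTS)
  setting <- match.arg(setting, .SETTINGS)
  if ((organ == "donor") != (setting == "donor_product")) {
    stop("organ = \"donor\" and setting = \"donor_product\" imply each other ",
         "(sample ", sample_id, ")")
  }
  structure(
    list(sample_id = sample_id, organ = organ, treatment = treatment,
         setting = setting,
         recipient_id = as.character(recipient_id),
         replicate = as.character(replicate)),
    class = "SampleMeta"
  )
}

as_sample_meta <- function(meta) {
  if (inherits(meta, "SampleMeta")) return(meta)
  if (is.list(meta)) return(do.call(sample_meta, meta))
  stop("`meta` must be a SampleMeta object (see sample_meta())")
}

#' Construct a repertoire table
#'
#' Validates and aggregates clonotype records into a `RepertoireTable`.
#' Records sharing the clonotype key (chain, v_call, j_call, cdr3_nt) are
#' merged by summing their UMI counts. Rows that fail validation (zero or
#' missing count, CDR3 outside the A/C/G/T/N alphabet, unknown chain) are
#' dropped; per-reason drop counts are kept in the `"dropped"` attribute.
#'
#' @param records Data frame with columns `chain`, `v_call`, `j_call`,
#'   `cdr3_nt` and optionally `cdr3_aa`, `umi_count` (default 1) and
#'   `v_ambiguous` (default `FALSE`, marks multi-hit V calls).
#' @param meta A [sample_meta()] object (or list of its fields).
#' @return A `RepertoireTable`: list with elements `meta`, `records`
#'   (a tibble sorted by decreasing UMI count, ties by key) and `total_umis`.
#' @export
repertoire_table <- function(records, meta) {
  meta <- as_sample_meta(meta)
  stopifnot(is.data.frame(records))
  needed <- c("chain", "v_call", "j_call", "cdr3_nt")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as_tibble(records)
  if (is.null(records[["umi_count"]])) records$umi_count <- 1L
  if (is.null(records[["cdr3_aa"]])) records$cdr3_aa <- NA_character_
  if (is.null(records[["v_ambiguous"]])) records$v_ambiguous <- FALSE
  records$chain <- as.character(records$chain)
  records$v_call <- as.character(records$v_call)
  records$j_call <- as.character(records$j_call)
  records$cdr3_nt <- toupper(as.character(records$cdr3_nt))
  records$cdr3_aa <- as.character(records$cdr3_aa)
  records$umi_count <- suppressWarnings(as.numeric(records$umi_count))

  bad_chain <- is.na(records$chain) | !records$chain %in% c("TRA", "TRB")
  bad_cdr3 <- is.na(records$cdr3_nt) | !grepl("^[ACGTN]+$", records$cdr3_nt)
  bad_count <- is.na(records$umi_count) | records$umi_count < 0
  zero_count <- !bad_count & records$umi_count == 0
  keep <- !(bad_chain | bad_cdr3 | bad_count | zero_count)
  dropped <- c(invalid_chain = sum(bad_chain),
               invalid_cdr3 = sum(bad_cdr3 & !bad_chain),
               invalid_count = sum(bad_count & !bad_chain & !bad_cdr3),
               zero_count = sum(zero_count & !bad_chain & !bad_cdr3))
  records <- records[keep, c("chain", "v_call", "j_call", "cdr3_nt",
                             "cdr3_aa", "umi_count", "v_ambiguous")]

  if (nrow(records)) {
    key <- paste(records$chain, records$v_call, records$j_call,
                 records$cdr3_nt, sep = "|")
    if (anyDuplicated(key)) {
      umi <- rowsum(records$umi_count, key, reorder = FALSE)
      amb <- rowsum(as.numeric(records$v_ambiguous), key, reorder = FALSE) > 0
      first <- !duplicated(key)
      records <- records[first, ]
      ord_key <- key[first]
      records$umi_count <- as.numeric(umi[match(ord_key, rownames(umi)), 1L])
      records$v_ambiguous <- as.logical(amb[match(ord_key, rownames(amb)), 1L])
      key <- ord_key
    }
    records <- records[order(-records$umi_count, key), ]
  }
  records$umi_count <- as.integer(round(records$umi_count))

  structure(
    list(meta = meta, records = records,
         total_umis = as.integer(sum(records$umi_count))),
    dropped = dropped,
    class = "RepertoireTable"
  )
}

#' @export
print.RepertoireTable <- function(x, ...) {
  cat(sprintf("RepertoireTable '%s' (%s, %s, %s): %d clonotypes, %d UMIs\n",
              x$meta$sample_id, x$meta$organ, x$meta$treatment,
              x$meta$setting, nrow(x$records), x$total_umis))
  print(head(x$records, 10))
  if (nrow(x$records) > 10) cat("...", nrow(x$records) - 10, "more clonotypes\n")
  invisible(x)
}

#' Clonotype keys of a repertoire table
#'
#' @param x A `RepertoireTable`.
#' @param level `"nt"` (default) keys clones at the CDR3 nucleotide level,
#'   `"aa"` at the amino-acid level.
#' @return Character vector of keys, parallel to `x$records`.
#' @export
clone_keys <- function(x, level = c("nt", "aa")) {
  level <- match.arg(level)
  r <- x$records
  cdr3 <- if (level == "nt") r$cdr3_nt else r$cdr3_aa
  if (level == "aa" && anyNA(cdr3)) {
    stop("amino-acid keys requested but cdr3_aa is missing for some records")
  }
  paste(r$chain, r$v_call, r$j_call, cdr3, sep = "|")
}

table_chains <- function(x) sort(unique(x$records$chain))

#' Read an AIRR Rearrangement TSV
#'
#' Ingests a standard AIRR Rearrangement table (tab-separated, columns
#' `v_call`, `j_call`, `junction`, `duplicate_count`, optionally
#' `junction_aa` and `locus`). Allele suffixes are stripped from V/J calls,
#' duplicate clonotype keys are merged by summing counts, and rows with a
#' zero or missing duplicate count are dropped (their number is reported in
#' the `"dropped"` attribute of the result).
#'
#' @param path Path to the TSV file.
#' @param meta A [sample_meta()] describing the sample.
#' @return A [repertoire_table()].
#' @export
read_airr <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  needed <- c("v_call", "j_call", "junction", "duplicate_count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("AIRR file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop("AIRR file ", path, " contains no rearrangement rows")
  v_call <- strip_allele(df$v_call)
  chain <- if ("locus" %in% names(df)) df$locus else substr(v_call, 1, 3)
  tab <- repertoire_table(
    data.frame(chain = chain,
               v_call = v_call,
               j_call = strip_allele(df$j_call),
               cdr3_nt = df$junction,
               cdr3_aa = if ("junction_aa" %in% names(df)) df$junction_aa else NA,
               umi_count = suppressWarnings(as.numeric(df$duplicate_count)),
               stringsAsFactors = FALSE),
    meta
  )
  if (!nrow(tab$records)) stop("AIRR file ", path, ": no valid records after filtering")
  tab
}

#' Read a MiXCR-style clonotype export TSV
#'
#' Ingests a MiXCR-dialect export with columns `cloneCount`,
#' `allVHitsWithScore`, `allJHitsWithScore`, `nSeqCDR3` and optionally
#' `aaSeqCDR3`. V/J hits are truncated at the first allele/score delimiter
#' to plain segment names; records whose V field lists several hits are kept
#' with the first hit and flagged `v_ambiguous` (the ambiguity policy of the
#' segment-usage module decides their fate downstream). Rows with an
#' unparsable V call are excluded with a warning.
#'
#' @inheritParams read_airr
#' @return A [repertoire_table()].
#' @export
read_mixcr_tsv <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  needed <- c("cloneCount", "allVHitsWithScore", "allJHitsWithScore", "nSeqCDR3")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("MiXCR export ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop("MiXCR export ", path, " contains no clone rows")
  ambiguous <- grepl(",", df$allVHitsWithScore, fixed = TRUE)
  first_hit <- function(x) strip_allele(vapply(strsplit(x, ",", fixed = TRUE),
                                               `[`, character(1), 1L))
  v_call <- first_hit(df$allVHitsWithScore)
  j_call <- first_hit(df$allJHitsWithScore)
  bad_v <- is.na(v_call) | !grepl("^TR[AB]V", v_call, ignore.case = TRUE)
  if (any(bad_v)) {
    warning(sum(bad_v), " row(s) with unparsable V-call excluded from ", path)
  }
  keep <- !bad_v
  if (!any(keep)) stop("MiXCR export ", path, ": all rows excluded")
  tab <- repertoire_table(
    data.frame(chain = toupper(substr(v_call[keep], 1, 3)),
               v_call = v_call[keep],
               j_call = j_call[keep],
               cdr3_nt = df$nSeqCDR3[keep],
               cdr3_aa = if ("aaSeqCDR3" %in% names(df)) df$aaSeqCDR3[keep] else NA,
               umi_count = suppressWarnings(as.numeric(df$cloneCount[keep])),
               v_ambiguous = ambiguous[keep],
               stringsAsFactors = FALSE),
    meta
  )
  if (!nrow(tab$records)) stop("MiXCR export ", path, ": no valid records after filtering")
  tab
}

#' Reduce a 10x contig table to paired-chain single-cell clones
#'
#' Keeps only cell barcodes with exactly one productive, high-confidence TRA
#' contig and exactly one productive, high-confidence TRB contig (cells with
#' zero or multiple chains of either kind are dropped, with per-reason drop
#' counts attached), then aggregates identical paired keys into clones with
#' a cell count.
#'
#' @param path Path to a `filtered_contig_annotations`-style CSV with columns
#'   `barcode`, `chain`, `v_gene`, `j_gene`, `cdr3_nt`, `productive`,
#'   `high_confidence` (and optionally `sample_id`).
#' @param sample_id Optional sample label; defaults to the file's `sample_id`
#'   column or the file name.
#' @return A tibble of class `PairedCloneSet` with columns `tra_v`, `tra_j`,
#'   `cdr3a_nt`, `trb_v`, `trb_j`, `cdr3b_nt`, `cell_count`, sorted by
#'   decreasing cell count. Attributes: `drop_counts`, `n_cells_kept`,
#'   `sample_id`.
#' @export
read_sc_contigs <- function(path, sample_id = NULL) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  needed <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt",
              "productive", "high_confidence")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("contig table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sample_id <- sample_id %||% df[["sample_id"]][1] %||%
    if (is.character(path)) basename(path) else "sc_sample"

  truthy <- function(x) tolower(as.character(x)) %in% c("true", "t", "1", "yes")
  usable <- truthy(df$productive) & truthy(df$high_confidence) &
    df$chain %in% c("TRA", "TRB")
  n_low_quality <- sum(!usable)
  df <- df[usable, , drop = FALSE]
  df$v_gene <- strip_allele(df$v_gene)
  df$j_gene <- strip_allele(df$j_gene)

  n_tra <- table(factor(df$barcode)[df$chain == "TRA"])
  n_trb <- table(factor(df$barcode)[df$chain == "TRB"])
  barcodes <- unique(df$barcode)
  tra_of <- as.integer(n_tra[barcodes]); tra_of[is.na(tra_of)] <- 0L
  trb_of <- as.integer(n_trb[barcodes]); trb_of[is.na(trb_of)] <- 0L
  keep_bc <- barcodes[tra_of == 1L & trb_of == 1L]
  drop_counts <- c(
    low_quality_contigs = n_low_quality,
    no_tra = sum(tra_of == 0L & trb_of >= 1L),
    no_trb = sum(trb_of == 0L & tra_of >= 1L),
    multi_tra = sum(tra_of > 1L & trb_of >= 1L),
    multi_trb = sum(trb_of > 1L & tra_of == 1L)
  )
  if (!length(keep_bc)) {
    stop("no cells with exactly one productive TRA and one productive TRB ",
         "chain survive filtering (drops: ",
         paste(names(drop_counts), drop_counts, sep = "=", collapse = ", "), ")")
  }

  df <- df[df$barcode %in% keep_bc, , drop = FALSE]
  a <- df[df$chain == "TRA", c("barcode", "v_gene", "j_gene", "cdr3_nt")]
  b <- df[df$chain == "TRB", c("barcode", "v_gene", "j_gene", "cdr3_nt")]
  m <- merge(a, b, by = "barcode", suffixes = c("_a", "_b"))
  key <- paste(m$v_gene_a, m$j_gene_a, m$cdr3_nt_a,
               m$v_gene_b, m$j_gene_b, m$cdr3_nt_b, sep = "|")
  first <- !duplicated(key)
  counts <- as.integer(table(key)[key[first]])
  out <- tibble(
    tra_v = m$v_gene_a[first], tra_j = m$j_gene_a[first],
    cdr3a_nt = m$cdr3_nt_a[first],
    trb_v = m$v_gene_b[first], trb_j = m$j_gene_b[first],
    cdr3b_nt = m$cdr3_nt_b[first],
    cell_count = counts
  )
  out <- out[order(-out$cell_count,
                   paste(out$trb_v, out$trb_j, out$cdr3b_nt, sep = "|")), ]
  structure(out, drop_counts = drop_counts, n_cells_kept = length(keep_bc),
            sample_id = sample_id,
            class = c("PairedCloneSet", class(out)))
}

#' Pool repertoire tables into one merged table
#'
#' Clonotype-keyed union with summed UMI counts, used e.g. to merge the
#' organs of several recipients of the same graft before overlap analysis.
#' All tables must carry the same chain; mixing TRA with TRB tables is an
#' error.
#'
#' @param tables List of `RepertoireTable`s.
#' @param label `sample_id` for the pooled table.
#' @return A [repertoire_table()] whose `total_umis` is the sum of the
#'   inputs' totals.
#' @export
pool_samples <- function(tables, label) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (!all(vapply(tables, inherits, logical(1), "RepertoireTable"))) {
    stop("`tables` must be a list of RepertoireTable objects")
  }
  chain_sets <- unique(lapply(tables, table_chains))
  if (length(unique(unlist(chain_sets))) > 1L) {
    stop("cannot pool tables with different chains (",
         paste(unique(unlist(chain_sets)), collapse = " vs "), ")")
  }
  records <- dplyr::bind_rows(lapply(tables, function(t) t$records))
  organs <- unique(vapply(tables, function(t) t$meta$organ, character(1)))
  treatments <- unique(vapply(tables, function(t) t$meta$treatment, character(1)))
  settings <- unique(vapply(tables, function(t) t$meta$setting, character(1)))
  organ <- if (length(organs) == 1L) organs else "other"
  setting <- if (length(settings) == 1L) settings else "noBMT"
  if ((organ == "donor") != (setting == "donor_product")) {
    organ <- "other"; setting <- "noBMT"
  }
  meta <- sample_meta(
    sample_id = label,
    organ = organ,
    treatment = if (length(treatments) == 1L) treatments else "fresh",
    setting = setting,
    replicate = "pooled"
  )
  repertoire_table(records, meta)
}

#' Write a repertoire table as AIRR Rearrangement TSV
#'
#' Emits columns `sequence_id`, `locus`, `v_call`, `j_call`, `junction`,
#' `junction_aa`, `duplicate_count`. Reading the file back with
#' [read_airr()] reproduces the table's records exactly (up to order).
#'
#' @param x A `RepertoireTable`.
#' @param path Output file path.
#' @export
write_clonotype_table <- function(x, path) {
  stopifnot(inherits(x, "RepertoireTable"))
  r <- x$records
  out <- data.frame(
    sequence_id = if (nrow(r)) sprintf("%s_%06d", x$meta$sample_id, seq_len(nrow(r))) else character(0),
    locus = r$chain,
    v_call = r$v_call,
    j_call = r$j_call,
    junction = r$cdr3_nt,
    junction_aa = ifelse(is.na(r$cdr3_aa), "", r$cdr3_aa),
    duplicate_count = r$umi_count,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write clonotype table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
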