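# Fixture builders: small repertoire tables constructed in code.

# Deterministic A/C/G/T string for a clone label; the same label always maps
# to the same CDR3, so clones can be shared across fixture tables by name.
# Each character is encoded as four bases (fixed width), so distinct labels
# always map to distinct sequences.
nt_for <- function(label) {
  codes <- utf8ToInt(label)
  quads <- unlist(lapply(codes, function(cd) {
    c(cd %% 4, cd %/% 4 %% 4, cd %/% 16 %% 4, cd %/% 64 %% 4)
  }))
  paste(c("A", "C", "G", "T")[quads + 1], collapse = "")
}

make_table <- function(counts, sample_id = "s", chain = "TRB",
                       v = "TRBV1", j = "TRBJ1-1", organ = "other",
                       treatment = "fresh", setting = "noBMT", ...) {
  labels <- names(counts)
  if (is.null(labels)) labels <- paste0("clone", seq_along(counts))
  repertoire_table(
    data.frame(chain = chain,
               v_call = rep_len(v, length(counts)),
               j_call = rep_len(j, length(counts)),
               cdr3_nt = vapply(labels, nt_for, character(1)),
               umi_count = as.integer(counts),
               stringsAsFactors = FALSE),
    sample_meta(sample_id, organ = organ, treatment = treatment,
                setting = setting, ...)
  )
}

# Random table with `n` clones and geometric-ish counts, deterministic per
# seed; labels prefixed so different prefixes give disjoint clone sets.
random_table <- function(n, seed, prefix = "r", max_count = 50,
                         sample_id = paste0("rand", seed)) {
  set.seed(seed)
  counts <- sample.int(max_count, n, replace = TRUE)
  names(counts) <- paste0(prefix, seq_len(n))
  make_table(counts, sample_id = sample_id)
}

write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
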