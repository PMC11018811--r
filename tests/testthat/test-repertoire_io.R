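meta_s <- sample_meta("s1")

airr_row <- function(v, j, junction, count, locus = "TRB", aa = "") {
  data.frame(sequence_id = "x", locus = locus, v_call = v, j_call = j,
             junction = junction, junction_aa = aa, duplicate_count = count,
             stringsAsFactors = FALSE)
}

test_that("read_airr ingests, aggregates duplicate keys and drops zero counts", {
  rows <- rbind(
    airr_row("TRBV1*01", "TRBJ1-1", "TGTGCAAGC", 4),
    airr_row("TRBV2", "TRBJ1-2", "TGTGCAAGG", 2),
    airr_row("TRBV3", "TRBJ1-3", "TGTGCAAGT", 1)
  )
  tab <- read_airr(write_airr_fixture(rows), meta_s)
  expect_s3_class(tab, "RepertoireTable")
  expect_equal(nrow(tab$records), 3L)
  expect_equal(tab$total_umis, 7L)
  expect_true(all(tab$records$v_call %in% c("TRBV1", "TRBV2", "TRBV3")))

  # duplicate keys merged by summing counts
  rows2 <- rbind(
    airr_row("TRBV1*01", "TRBJ1-1", "TGTGCAAGC", 2),
    airr_row("TRBV1*02", "TRBJ1-1", "TGTGCAAGC", 3)
  )
  tab2 <- read_airr(write_airr_fixture(rows2), meta_s)
  expect_equal(nrow(tab2$records), 1L)
  expect_equal(tab2$records$umi_count, 5L)

  # zero-count row dropped and reported (oracle: manual row-by-row filter)
  rows3 <- rbind(airr_row("TRBV1", "TRBJ1-1", "TGTGCAAGC", 3),
                 airr_row("TRBV2", "TRBJ1-1", "TGTGCAAGA", 0))
  tab3 <- read_airr(write_airr_fixture(rows3), meta_s)
  expect_equal(nrow(tab3$records), 1L)
  expect_equal(unname(attr(tab3, "dropped")["zero_count"]), 1L)
})

test_that("read_airr fails loudly on malformed input", {
  rows <- airr_row("TRBV1", "TRBJ1-1", "TGTGCAAGC", 3)
  rows$duplicate_count <- NULL
  expect_error(read_airr(write_airr_fixture(rows), meta_s), "duplicate_count")
  empty <- write_airr_fixture(airr_row("TRBV1", "TRBJ1-1", "TGT", 1)[0, ])
  expect_error(read_airr(empty, meta_s), "no rearrangement rows")
  expect_error(read_airr(tempfile(), meta_s), "not found")
})

test_that("read_mixcr_tsv truncates V hits and flags multi-hit calls", {
  rows <- data.frame(
    cloneCount = c(10, 5, 3),
    allVHitsWithScore = c("TRBV12-1*00(1200)", "TRBV2*00(800),TRBV3*00(750)",
                          "TRBV5*00(500)"),
    allJHitsWithScore = c("TRBJ1-1*00(300)", "TRBJ1-2*00(280)", "TRBJ2-7*00(250)"),
    nSeqCDR3 = c("TGTGCAAGC", "TGTGCAAGG", "TGTGCAAGT"),
    stringsAsFactors = FALSE
  )
  tab <- read_mixcr_tsv(write_airr_fixture(rows), meta_s)
  expect_equal(tab$total_umis, 18L)
  r <- tab$records[order(-tab$records$umi_count), ]
  expect_equal(r$v_call[1], "TRBV12-1")
  expect_equal(r$v_call[2], "TRBV2")          # first hit of the multi-hit field
  expect_true(r$v_ambiguous[2])                # flagged, not dropped
  expect_false(any(r$v_ambiguous[c(1, 3)]))

  rows$allVHitsWithScore[2] <- "garbage"
  expect_warning(tab2 <- read_mixcr_tsv(write_airr_fixture(rows), meta_s),
                 "unparsable")
  expect_equal(nrow(tab2$records), 2L)
})

sc_contig <- function(barcode, chain, v, cdr3, productive = "True",
                      high_confidence = "True") {
  data.frame(barcode = barcode, chain = chain, v_gene = v,
             j_gene = ifelse(chain == "TRA", "TRAJ12", "TRBJ1-1"),
             cdr3_nt = cdr3, productive = productive,
             high_confidence = high_confidence, stringsAsFactors = FALSE)
}

test_that("read_sc_contigs keeps only single-pair cells and aggregates clones", {
  rows <- rbind(
    sc_contig("bc1", "TRA", "TRAV1", "TGTGCA"),  # intact cell
    sc_contig("bc1", "TRB", "TRBV1", "TGTGCC"),
    sc_contig("bc2", "TRA", "TRAV1", "TGTGCA"),  # double alpha -> dropped
    sc_contig("bc2", "TRA", "TRAV2", "TGTGCG"),
    sc_contig("bc2", "TRB", "TRBV1", "TGTGCC"),
    sc_contig("bc3", "TRB", "TRBV2", "TGTGCT"),  # no alpha -> dropped
    sc_contig("bc4", "TRA", "TRAV1", "TGTGCA"),  # same clone as bc1
    sc_contig("bc4", "TRB", "TRBV1", "TGTGCC"),
    sc_contig("bc5", "TRA", "TRAV1", "TGTGCA"),  # same clone again
    sc_contig("bc5", "TRB", "TRBV1", "TGTGCC"),
    sc_contig("bc6", "TRA", "TRAV9", "TGTGAA", productive = "False"),  # low qual
    sc_contig("bc6", "TRB", "TRBV9", "TGTGAC")
  )
  clones <- read_sc_contigs(rows, sample_id = "sc1")
  expect_s3_class(clones, "PairedCloneSet")
  expect_equal(nrow(clones), 1L)
  expect_equal(clones$cell_count, 3L)
  expect_equal(sum(clones$cell_count), attr(clones, "n_cells_kept"))
  drops <- attr(clones, "drop_counts")
  expect_equal(unname(drops["multi_tra"]), 1L)
  expect_gte(unname(drops["no_tra"]), 1L)

  only_bad <- rbind(sc_contig("b1", "TRA", "TRAV1", "TGTGCA"),
                    sc_contig("b2", "TRB", "TRBV1", "TGTGCC"))
  expect_error(read_sc_contigs(only_bad), "survive filtering")
})

test_that("pool_samples sums counts and respects chain boundaries", {
  x <- make_table(c(a = 3, b = 2), sample_id = "x")
  doubled <- pool_samples(list(x, x), "xx")
  expect_equal(sort(doubled$records$umi_count), c(4L, 6L))
  expect_equal(doubled$total_umis, 2L * x$total_umis)

  y10 <- random_table(10, seed = 1, prefix = "p")
  y20 <- random_table(20, seed = 2, prefix = "q")
  merged <- pool_samples(list(y10, y20), "m")
  expect_equal(nrow(merged$records), 30L)
  expect_equal(merged$total_umis, y10$total_umis + y20$total_umis)

  tra <- make_table(c(a = 1), chain = "TRA", v = "TRAV1", j = "TRAJ12")
  expect_error(pool_samples(list(x, tra), "bad"), "different chains")
})

test_that("pool_samples is associative and commutative on count maps", {
  a <- random_table(15, seed = 11, prefix = "a")
  b <- random_table(15, seed = 12, prefix = "a")   # overlapping keys
  c <- random_table(15, seed = 13, prefix = "b")   # disjoint from a, b
  canon <- function(t) {
    r <- t$records[order(clone_keys(t)), c("cdr3_nt", "umi_count")]
    rownames(r) <- NULL
    r
  }
  p1 <- pool_samples(list(a, b, c), "p")
  p2 <- pool_samples(list(c, pool_samples(list(b, a), "ba")), "p")
  expect_equal(canon(p1), canon(p2))
})

test_that("AIRR write/read round-trips the record multiset exactly", {
  tab <- random_table(100, seed = 5)
  tab$records$cdr3_nt[1] <- sub("A", "N", tab$records$cdr3_nt[1])  # N preserved
  tab <- repertoire_table(tab$records, tab$meta)
  path <- tempfile(fileext = ".tsv")
  write_clonotype_table(tab, path)
  back <- read_airr(path, tab$meta)
  canon <- function(t) {
    r <- as.data.frame(t$records[order(clone_keys(t)),
                                 c("chain", "v_call", "j_call", "cdr3_nt", "umi_count")])
    rownames(r) <- NULL
    r
  }
  expect_equal(canon(back), canon(tab))

  # empty table -> header-only file
  empty <- repertoire_table(tab$records[0, ], tab$meta)
  p2 <- tempfile(fileext = ".tsv")
  write_clonotype_table(empty, p2)
  expect_equal(length(readLines(p2)), 1L)
})

test_that("sample metadata validates its enums and the donor/organ pairing", {
  expect_error(sample_meta("s", organ = "donor", setting = "GvHD"), "imply")
  expect_error(sample_meta("s", organ = "spleen", setting = "donor_product"), "imply")
  expect_error(sample_meta("s", organ = "gut"), "arg")
  m <- sample_meta("s", organ = "donor", setting = "donor_product")
  expect_s3_class(m, "SampleMeta")
})
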