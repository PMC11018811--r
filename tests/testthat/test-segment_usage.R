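usage_fixture <- function() {
  repertoire_table(
    data.frame(chain = "TRB",
               v_call = c("TRBV1", "TRBV1", "TRBV2", "TRBV2,TRBV3"),
               j_call = "TRBJ1-1",
               cdr3_nt = c("TGTGCA", "TGTGCC", "TGTGCG", "TGTGCT"),
               umi_count = c(20, 10, 10, 5),
               v_ambiguous = c(FALSE, FALSE, FALSE, TRUE),
               stringsAsFactors = FALSE),
    sample_meta("u1"))
}

test_that("segment frequencies renormalize after ambiguity exclusion", {
  tab <- make_table(c(a = 7), v = "TRBV5")
  u <- segment_frequencies(tab)
  expect_equal(u$segment, "TRBV5")
  expect_equal(u$freq, 1)

  two <- repertoire_table(
    data.frame(chain = "TRB", v_call = c("TRBV1", "TRBV2"),
               j_call = "TRBJ1-1", cdr3_nt = c("TGTGCA", "TGTGCC"),
               umi_count = c(30, 10), stringsAsFactors = FALSE),
    sample_meta("u2"))
  by_umi <- segment_frequencies(two, weighting = "by_umi")
  expect_equal(setNames(by_umi$freq, by_umi$segment),
               c(TRBV1 = 0.75, TRBV2 = 0.25))
  by_clone <- segment_frequencies(two, weighting = "by_clone")
  expect_equal(sort(by_clone$freq), c(0.5, 0.5))

  u3 <- segment_frequencies(usage_fixture(), weighting = "by_clone")
  expect_equal(attr(u3, "excluded_ambiguous"), 1L)
  expect_equal(sum(u3$freq), 1)
  expect_equal(setNames(u3$freq, u3$segment), c(TRBV1 = 2 / 3, TRBV2 = 1 / 3))

  u4 <- segment_frequencies(usage_fixture(), ambig_policy = "keep_first")
  expect_equal(attr(u4, "excluded_ambiguous"), 0L)
  expect_equal(sum(u4$count), 4)

  all_amb <- repertoire_table(
    data.frame(chain = "TRB", v_call = "TRBV1,TRBV2", j_call = "TRBJ1-1",
               cdr3_nt = "TGTGCA", umi_count = 1, v_ambiguous = TRUE,
               stringsAsFactors = FALSE),
    sample_meta("u5"))
  expect_error(segment_frequencies(all_amb), "ambiguous")
})

test_that("segment matching is case-insensitive and hyphen-preserving", {
  tab <- make_table(c(a = 5, b = 5), v = c("Trbv12-1", "TRBV5"))
  u <- segment_frequencies(tab)
  expect_true("TRBV12-1" %in% u$segment)
  groups <- list(g1 = make_table(c(a = 5, b = 5), v = c("Trbv12-1", "TRBV5")),
                 g2 = make_table(c(c = 5, d = 5), v = c("TRBV5", "TRBV6")))
  enr <- segment_set_enrichment(groups, segment_set = c("trbv12-1"))
  expect_equal(enr$set_in_group[enr$group == "g1"], 1)
  expect_equal(enr$set_in_group[enr$group == "g2"], 0)
})

test_that("set enrichment reproduces hand-checked 2x2 Fisher results", {
  mk_group <- function(n_in, n_out, id) {
    v <- c(rep("TRBV12-1", n_in), rep("TRBV5", n_out))
    make_table(setNames(rep(1, n_in + n_out), paste0(id, seq_along(v))), v = v,
               sample_id = id)
  }
  balanced <- segment_set_enrichment(list(g1 = mk_group(5, 5, "a"),
                                          g2 = mk_group(5, 5, "b")),
                                     segment_set = "TRBV12-1")
  expect_equal(balanced$p, c(1, 1))
  expect_equal(balanced$odds_ratio, c(1, 1))

  # [[10, 0], [0, 10]]: exhaustive hypergeometric enumeration gives
  # p = 2 / choose(20, 10)
  extreme <- segment_set_enrichment(list(g1 = mk_group(10, 0, "a"),
                                         g2 = mk_group(0, 10, "b")),
                                    segment_set = "TRBV12-1")
  expect_equal(extreme$p, rep(2 / choose(20, 10), 2))
  expect_true(all(extreme$haldane))
  expect_true(all(extreme$p_adj >= extreme$p))
})

test_that("Fisher p agrees with fixed-margin enumeration on random tables", {
  # oracle: sum the probabilities of all tables with the observed margins
  # whose probability does not exceed the observed one
  enum_p <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(m, k)
    probs <- stats::dhyper(support, m, n, k)
    obs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(42)
  for (i in 1:60) {
    cells <- as.integer(stats::rmultinom(1, sample(8:40, 1), rep(1 / 4, 4)))
    expect_equal(tcrtrack:::fisher_two_sided(cells[1], cells[2],
                                             cells[3], cells[4]),
                 enum_p(cells[1], cells[2], cells[3], cells[4]))
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  p <- c(0.04, 0.001, 0.9, 0.02, 0.3)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("enrichment over PairedCloneSets counts cells", {
  contigs <- function(n, v, id) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(barcode = paste0(id, i),
                 chain = c("TRA", "TRB"), v_gene = c("TRAV1", v),
                 j_gene = c("TRAJ12", "TRBJ1-1"),
                 cdr3_nt = c("TGTGCA", paste0("TGTGC", substr("ACGT", (i %% 4) + 1,
                                                              (i %% 4) + 1))),
                 productive = "True", high_confidence = "True",
                 stringsAsFactors = FALSE)
    }))
  }
  g1 <- read_sc_contigs(rbind(contigs(6, "TRBV12-1", "a"),
                              contigs(4, "TRBV5", "b")), sample_id = "g1")
  g2 <- read_sc_contigs(contigs(10, "TRBV5", "c"), sample_id = "g2")
  enr <- segment_set_enrichment(list(colon = g1, spleen = g2),
                                segment_set = "TRBV12-1", unit = "cell")
  expect_equal(enr$set_in_group[enr$group == "colon"], 6)
  expect_equal(enr$set_in_group[enr$group == "spleen"], 0)
  expect_lt(enr$p[enr$group == "colon"], 0.05)
})
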