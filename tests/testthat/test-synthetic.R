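# Small configurations keep the generator tests fast; the default-size
# experiment is exercised by the acceptance suite.
small_config <- function(seed = 1, ...) {
  args <- list(n_clones = 600L, n_recipients = 2L,
               organ_depths = c(spleen = 4000L, liver = 4000L, colon = 4000L),
               product_depth = 6000L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

test_that("the donor repertoire is deterministic with unique clone keys", {
  cfg <- small_config()
  d1 <- simulate_donor_repertoire(cfg)
  d2 <- simulate_donor_repertoire(cfg)
  expect_identical(d1$table$records, d2$table$records)
  expect_identical(d1$truth, d2$truth)
  expect_equal(nrow(d1$table$records), 600L)
  expect_equal(anyDuplicated(d1$truth$clone_key), 0L)
  expect_setequal(unique(d1$truth$class),
                  c("alloreactive", "tissue_restricted", "bystander"))
})

test_that("class fractions follow the configured probabilities", {
  cfg <- sim_config(n_clones = 4000L, allo_fraction = 0.1, seed = 2)
  d <- simulate_donor_repertoire(cfg)
  n_allo <- sum(d$truth$class == "alloreactive")
  expect_lt(abs(n_allo - 400), 4 * sqrt(4000 * 0.1 * 0.9))
  tr <- d$truth[d$truth$class == "tissue_restricted", ]
  expect_gt(mean(tr$trb_v %in% c("TRBV12-1", "TRBV12-2", "TRBV26")), 0.75)
})

test_that("config validation is strict", {
  expect_error(sim_config(allo_fraction = 0.6, colon_biased_fraction = 0.5),
               "must be < 1")
  expect_error(sim_config(organ_depths = c(spleen = 10, liver = 10)), "colon")
  expect_error(sim_config(seeding_weights = list(
    alloreactive = c(spleen = 0.5, liver = 0.5, colon = 0.5),
    tissue_restricted = c(spleen = 0.1, liver = 0.1, colon = 0.8),
    bystander = c(spleen = 1/3, liver = 1/3, colon = 1/3))), "sum to 1")
  expect_error(sim_config(allo_gain = 0.5), "allo_gain")
})

test_that("expansion is the identity limit at zero culture noise", {
  cfg <- small_config(poly_noise = 0)
  d <- simulate_donor_repertoire(cfg)
  prod <- simulate_expansion(d$table, d$truth, "poly", cfg)
  expect_equal(prod$truth$product_proportion, d$truth$donor_proportion)
})

test_that("allo expansion shifts mass as configured", {
  cfg <- small_config(seed = 3)
  d <- simulate_donor_repertoire(cfg)
  allo <- simulate_expansion(d$table, d$truth, "allo", cfg)
  by_class <- function(truth, col) {
    tapply(truth[[col]], truth$class, sum)
  }
  before <- by_class(d$truth, "donor_proportion")
  after <- by_class(allo$truth, "product_proportion")
  expect_gt(after["alloreactive"], before["alloreactive"])
  expect_lt(after["tissue_restricted"], before["tissue_restricted"])
})

test_that("seeded organ tables hit their configured depth exactly", {
  cfg <- small_config(seed = 4)
  d <- simulate_donor_repertoire(cfg)
  prod <- simulate_expansion(d$table, d$truth, "poly", cfg)
  seeded <- simulate_seeding(prod$table, prod$truth, cfg)
  expect_length(seeded$tables, 2L * 3L)
  for (tab in seeded$tables) expect_equal(tab$total_umis, 4000L)
  organs <- vapply(seeded$tables, function(t) t$meta$organ, character(1))
  expect_equal(sort(unique(organs)), c("colon", "liver", "spleen"))
})

test_that("tissue-restricted clones concentrate in colon as the weights dictate", {
  # noise-free, gain-free configuration: pooled organ frequencies of the
  # planted clones should match the expectation ratio from the weights
  cfg <- small_config(seed = 5, seeding_noise = 0, invivo_allo_gain = 1,
                      colon_biased_fraction = 0.1,
                      organ_depths = c(spleen = 20000L, liver = 20000L,
                                       colon = 20000L))
  d <- simulate_donor_repertoire(cfg)
  prod <- simulate_expansion(d$table, d$truth, "poly", cfg)
  seeded <- simulate_seeding(prod$table, prod$truth, cfg)
  tr_keys <- seeded$truth$clone_key[seeded$truth$class == "tissue_restricted"]
  freq_in <- function(organ) {
    pooled <- pool_samples(seeded$tables[grepl(organ, names(seeded$tables))],
                           organ)
    sum(pooled$records$umi_count[clone_keys(pooled) %in% tr_keys]) /
      pooled$total_umis
  }
  observed_ratio <- freq_in("colon") / freq_in("spleen")
  # expectation from the weights, accounting for per-organ normalization
  tr <- seeded$truth$class == "tissue_restricted"
  expected_ratio <- (sum(seeded$truth$expected_freq_colon[tr]) /
                       sum(seeded$truth$expected_freq_spleen[tr]))
  expect_equal(observed_ratio, expected_ratio, tolerance = 0.15)
  expect_gt(observed_ratio, 4)
})

test_that("recipients share selection: matching organs overlap strongly", {
  cfg <- small_config(seed = 6)
  d <- simulate_donor_repertoire(cfg)
  prod <- simulate_expansion(d$table, d$truth, "allo", cfg)
  seeded <- simulate_seeding(prod$table, prod$truth, cfg)
  mh <- morisita_horn(seeded$tables$allo_R1_spleen,
                      seeded$tables$allo_R2_spleen)
  expect_gt(mh, 0.5)
})

test_that("spleen and liver repertoires are more alike than either is to colon", {
  ex <- simulate_experiment(sim_config(seed = 1))
  p <- function(o) pool_samples(ex$organs$poly[grepl(o, names(ex$organs$poly))], o)
  sl <- morisita_horn(p("spleen"), p("liver"))
  expect_gt(sl, morisita_horn(p("spleen"), p("colon")))
  expect_gt(sl, morisita_horn(p("liver"), p("colon")))
})

test_that("single-cell tables exercise the paired-chain filter as configured", {
  cfg0 <- small_config(seed = 7, sc_defect_fraction = 0)
  d <- simulate_donor_repertoire(cfg0)
  prod <- simulate_expansion(d$table, d$truth, "poly", cfg0)
  seeded <- simulate_seeding(prod$table, prod$truth, cfg0)
  one <- seeded$tables[1]
  sc <- simulate_sc_table(one, seeded$truth, cfg0, cells_per_sample = 300)
  clones <- read_sc_contigs(sc, sample_id = names(one))
  expect_equal(attr(clones, "n_cells_kept"), 300L)

  cfg2 <- small_config(seed = 7, sc_defect_fraction = 0.2)
  sc2 <- simulate_sc_table(one, seeded$truth, cfg2, cells_per_sample = 2000)
  clones2 <- read_sc_contigs(sc2, sample_id = names(one))
  kept <- attr(clones2, "n_cells_kept")
  # defective cells (missing or doubled alpha) are filtered out
  expect_lt(abs(kept / 2000 - 0.8), 4 * sqrt(0.2 * 0.8 / 2000))

  # clone proportions recovered from surviving cells (loose MC tolerance)
  tab <- one[[1]]
  top_key <- clone_keys(tab)[which.max(tab$records$umi_count)]
  truth_row <- match(top_key, seeded$truth$clone_key)
  sc_share <- sum(clones2$cell_count[clones2$cdr3b_nt ==
                                       seeded$truth$cdr3b_nt[truth_row]]) / kept
  bulk_share <- max(tab$records$umi_count) / tab$total_umis
  expect_lt(abs(sc_share - bulk_share),
            4 * sqrt(bulk_share * (1 - bulk_share) / kept) + 0.02)
})

test_that("the full experiment is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 8)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$products$allo$records, e2$products$allo$records)
  expect_identical(lapply(e1$organs$poly, function(t) t$records),
                   lapply(e2$organs$poly, function(t) t$records))
  e3 <- simulate_experiment(small_config(seed = 9))
  expect_false(identical(e1$products$allo$records, e3$products$allo$records))
})
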