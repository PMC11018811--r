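# Synthetic adoptive-transfer experiments with known ground truth.
#
# The generator emulates the statistical structure the analyses assume: a
# donor Treg repertoire with heavy-tailed clone sizes; polyclonal (diversity
# preserving) vs allo-selective (diversity narrowing) in vitro expansion;
# seeding of spleen, liver and colon in several recipients where dominant
# alloreactive clones span organs while small tissue-restricted clones,
# carrying designated V-beta segments, home to the colon; and UMI sampling
# at configurable depth. Every clone carries a class label so parameter-
# recovery tests can check each pipeline stage against the truth.

.TRBV_POOL <- c("TRBV1", "TRBV2", "TRBV3", "TRBV4", "TRBV5",
                "TRBV12-1", "TRBV12-2", "TRBV13-1", "TRBV13-2", "TRBV13-3",
                "TRBV14", "TRBV15", "TRBV16", "TRBV17", "TRBV19", "TRBV20",
                "TRBV23", "TRBV24", "TRBV26", "TRBV29", "TRBV30", "TRBV31")
.TRBJ_POOL <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5",
                "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5",
                "TRBJ2-7")
.TRAV_POOL <- c("TRAV1", "TRAV3-1", "TRAV4-2", "TRAV6-1", "TRAV7-2",
                "TRAV8-1", "TRAV9-1", "TRAV10", "TRAV12-1", "TRAV13-1",
                "TRAV14-1", "TRAV16", "TRAV17", "TRAV19", "TRAV21")
.TRAJ_POOL <- c("TRAJ2", "TRAJ5", "TRAJ9", "TRAJ12", "TRAJ15", "TRAJ21",
                "TRAJ23", "TRAJ27", "TRAJ31", "TRAJ33", "TRAJ37", "TRAJ40",
                "TRAJ43", "TRAJ49", "TRAJ56")
.ORGAN_NAMES <- c("spleen", "liver", "colon")
.CLONE_CLASSES <- c("alloreactive", "tissue_restricted", "bystander")

random_cdr3 <- function(n) {
  lens <- 3L * sample(10:15, n, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  # collision-checked so clonotype keys are unique by construction
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(3L * sample(10:15, length(dup), replace = TRUE),
                        function(l) paste(sample(c("A", "C", "G", "T"), l,
                                                 replace = TRUE),
                                          collapse = ""),
                        character(1))
  }
  seqs
}

#' Simulation configuration
#'
#' Defines one synthetic adoptive-transfer experiment. The defaults are the
#' generator's study conditions: 5000 donor clones with power-law
#' (alpha = 1.5) sizes, 5% alloreactive clones gaining 8-fold during
#' allo-selective culture (tissue-restricted clones depleted 8-fold there),
#' 3% of the remaining clones tissue-restricted and colon-tropic carrying
#' one of the designated V-beta segments, three recipients sequenced at
#' 20000 UMIs per organ. In vivo, alloreactive clones expand strongly
#' (`invivo_allo_gain`) and every clone receives one lognormal engraftment
#' factor (`seeding_noise`) shared across organs and recipients, so
#' recipients differ only by sampling noise.
#'
#' @param n_clones Number of donor clones.
#' @param clone_size_law `"power_law"` (Pareto tail, exponent `power_alpha`)
#'   or `"log_normal"` (`lnorm_meanlog`, `lnorm_sdlog`).
#' @param power_alpha,lnorm_meanlog,lnorm_sdlog Clone-size law parameters.
#' @param max_clone_freq Cap on any single donor clone's frequency (default
#'   1%): a fresh polyclonal repertoire is heavy-tailed but not dominated
#'   by one mega-clone, so the raw heavy-tail draw is truncated here.
#' @param allo_fraction Share of clones marked alloreactive, in (0, 1).
#' @param allo_gain Median expansion advantage (> 1) of alloreactive clones
#'   under allo-selective culture; tissue-restricted clones are depleted by
#'   the same factor there.
#' @param allo_gain_spread Lognormal sdlog of the per-clone allo-culture
#'   gain around `allo_gain`; heterogeneous stimulation is what narrows the
#'   repertoire rather than uniformly inflating one class.
#' @param poly_noise Lognormal jitter SD of clone proportions during culture
#'   (applied in both expansion modes).
#' @param colon_biased_fraction Share of non-alloreactive clones that are
#'   tissue-restricted (colon-tropic).
#' @param colon_biased_segments V-beta segments preferentially carried by
#'   tissue-restricted clones.
#' @param segment_bias Probability that a tissue-restricted clone carries a
#'   designated segment.
#' @param rare_segment_weight Relative sampling weight of the designated
#'   segments in the background V-beta pool (< 1: clones with these
#'   segments are under-represented in the graft at large, as the designated
#'   set is chosen for being rare outside the colon).
#' @param n_recipients Number of recipients per graft.
#' @param organ_depths Named UMI depths for spleen, liver, colon.
#' @param product_depth UMI depth of the sequenced cell product.
#' @param seeding_weights Per clone-class organ weights (non-negative, each
#'   summing to 1 over spleen/liver/colon).
#' @param invivo_allo_gain In vivo expansion factor of alloreactive clones
#'   in recipient organs.
#' @param seeding_noise Lognormal sdlog of the per-clone engraftment factor
#'   (shared across organs and recipients).
#' @param recipient_jitter Optional extra per-recipient lognormal sdlog
#'   (default 0: recipients share selection exactly).
#' @param sc_defect_fraction Fraction of simulated single cells with a
#'   defective contig set (missing or duplicated alpha chain).
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_clones = 5000L,
                       clone_size_law = c("power_law", "log_normal"),
                       power_alpha = 1.5,
                       lnorm_meanlog = 1, lnorm_sdlog = 1.2,
                       max_clone_freq = 0.01,
                       allo_fraction = 0.05,
                       allo_gain = 8,
                       allo_gain_spread = 1,
                       poly_noise = 0.25,
                       colon_biased_fraction = 0.03,
                       colon_biased_segments = c("TRBV12-1", "TRBV12-2",
                                                 "TRBV26"),
                       segment_bias = 0.9,
                       rare_segment_weight = 0.1,
                       n_recipients = 3L,
                       organ_depths = c(spleen = 20000L, liver = 20000L,
                                        colon = 20000L),
                       product_depth = 30000L,
                       seeding_weights = list(
                         alloreactive = c(spleen = 1/3, liver = 1/3, colon = 1/3),
                         tissue_restricted = c(spleen = 0.1, liver = 0.1,
                                               colon = 0.8),
                         bystander = c(spleen = 1/3, liver = 1/3, colon = 1/3)),
                       invivo_allo_gain = 12,
                       seeding_noise = 2.5,
                       recipient_jitter = 0,
                       sc_defect_fraction = 0.1,
                       seed = 1L) {
  clone_size_law <- match.arg(clone_size_law)
  stopifnot(is_count_scalar(n_clones), n_clones >= 2,
            power_alpha > 0, lnorm_sdlog >= 0,
            max_clone_freq > 0, max_clone_freq <= 1,
            allo_fraction > 0, allo_fraction < 1,
            allo_gain > 1, allo_gain_spread >= 0, poly_noise >= 0,
            colon_biased_fraction >= 0, colon_biased_fraction < 1,
            segment_bias >= 0, segment_bias <= 1,
            rare_segment_weight > 0, rare_segment_weight <= 1,
            is_count_scalar(n_recipients), n_recipients >= 1,
            is_count_scalar(product_depth), product_depth >= 1,
            invivo_allo_gain >= 1, seeding_noise >= 0, recipient_jitter >= 0,
            sc_defect_fraction >= 0, sc_defect_fraction < 1)
  if (allo_fraction + colon_biased_fraction >= 1) {
    stop("allo_fraction + colon_biased_fraction must be < 1")
  }
  if (!all(.ORGAN_NAMES %in% names(organ_depths))) {
    stop("organ_depths must name spleen, liver and colon")
  }
  organ_depths <- organ_depths[.ORGAN_NAMES]
  if (any(organ_depths < 0)) stop("organ depths must be non-negative")
  if (!all(.CLONE_CLASSES %in% names(seeding_weights))) {
    stop("seeding_weights must name classes: ",
         paste(.CLONE_CLASSES, collapse = ", "))
  }
  for (cl in .CLONE_CLASSES) {
    w <- seeding_weights[[cl]]
    if (!all(.ORGAN_NAMES %in% names(w)) || any(w < 0) ||
        abs(sum(w[.ORGAN_NAMES]) - 1) > 1e-8) {
      stop("seeding weights for class '", cl,
           "' must be non-negative over spleen/liver/colon and sum to 1")
    }
    seeding_weights[[cl]] <- w[.ORGAN_NAMES]
  }
  segs <- normalize_segment(colon_biased_segments)
  if (!length(segs)) stop("colon_biased_segments must be non-empty")
  structure(
    list(n_clones = as.integer(n_clones), clone_size_law = clone_size_law,
         power_alpha = power_alpha, max_clone_freq = max_clone_freq,
         lnorm_meanlog = lnorm_meanlog,
         lnorm_sdlog = lnorm_sdlog, allo_fraction = allo_fraction,
         allo_gain = allo_gain, allo_gain_spread = allo_gain_spread,
         poly_noise = poly_noise,
         colon_biased_fraction = colon_biased_fraction,
         colon_biased_segments = segs, segment_bias = segment_bias,
         rare_segment_weight = rare_segment_weight,
         n_recipients = as.integer(n_recipients),
         organ_depths = organ_depths,
         product_depth = as.integer(product_depth),
         seeding_weights = seeding_weights,
         invivo_allo_gain = invivo_allo_gain, seeding_noise = seeding_noise,
         recipient_jitter = recipient_jitter,
         sc_defect_fraction = sc_defect_fraction, seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

#' Simulate the donor Treg repertoire
#'
#' Draws `n_clones` clone sizes from the configured heavy-tailed law,
#' assigns every clone a class (alloreactive with probability
#' `allo_fraction`; tissue-restricted with probability
#' `colon_biased_fraction` among the rest; bystander otherwise), random V/J
#' identities for both chains and collision-checked CDR3 sequences.
#' Tissue-restricted clones carry a designated colon-biased V-beta segment
#' with probability `segment_bias`.
#'
#' @param config A [sim_config()].
#' @return A list: `table` (the fresh donor `RepertoireTable`, TRB chain)
#'   and `truth` (tibble with clone key, class, both chains' identities,
#'   donor count and proportion).
#' @export
simulate_donor_repertoire <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(derive_seed(config$seed, "donor"), {
    n <- config$n_clones
    sizes <- switch(config$clone_size_law,
      power_law = pmax(1L, as.integer(floor(runif(n)^(-1 / config$power_alpha)))),
      log_normal = pmax(1L, as.integer(ceiling(
        rlnorm(n, config$lnorm_meanlog, config$lnorm_sdlog))))
    )
    # truncate the heavy tail: no single clone above max_clone_freq
    for (i in 1:5) {
      sizes <- pmin(sizes, max(1L, as.integer(ceiling(config$max_clone_freq *
                                                        sum(sizes)))))
    }
    class <- rep("bystander", n)
    is_allo <- runif(n) < config$allo_fraction
    class[is_allo] <- "alloreactive"
    is_tr <- !is_allo & runif(n) < config$colon_biased_fraction
    class[is_tr] <- "tissue_restricted"

    seg_w <- ifelse(normalize_segment(.TRBV_POOL) %in%
                      config$colon_biased_segments,
                    config$rare_segment_weight, 1)
    trb_v <- sample(.TRBV_POOL, n, replace = TRUE, prob = seg_w)
    biased <- is_tr & runif(n) < config$segment_bias
    trb_v[biased] <- sample(config$colon_biased_segments, sum(biased),
                            replace = TRUE)
    trb_j <- sample(.TRBJ_POOL, n, replace = TRUE)
    tra_v <- sample(.TRAV_POOL, n, replace = TRUE)
    tra_j <- sample(.TRAJ_POOL, n, replace = TRUE)
    cdr3b <- random_cdr3(n)
    cdr3a <- random_cdr3(n)

    meta <- sample_meta("donor_fresh", organ = "donor", treatment = "fresh",
                        setting = "donor_product")
    table <- repertoire_table(
      data.frame(chain = "TRB", v_call = trb_v, j_call = trb_j,
                 cdr3_nt = cdr3b, umi_count = sizes,
                 stringsAsFactors = FALSE),
      meta
    )
    truth <- tibble(
      clone_key = paste("TRB", trb_v, trb_j, cdr3b, sep = "|"),
      class = class,
      trb_v = trb_v, trb_j = trb_j, cdr3b_nt = cdr3b,
      tra_v = tra_v, tra_j = tra_j, cdr3a_nt = cdr3a,
      donor_count = sizes,
      donor_proportion = sizes / sum(sizes)
    )
    list(table = table, truth = truth)
  })
}

#' Simulate in vitro expansion of the donor repertoire
#'
#' Both modes jitter clone proportions with lognormal culture noise
#' (`poly_noise`). Allo-selective culture additionally multiplies
#' alloreactive clones by `allo_gain` and depletes tissue-restricted clones
#' by the same factor (GI-responsive clones are lost during allo-antigen-
#' driven expansion). Proportions are renormalized and the sequenced
#' product's UMI counts drawn multinomially at `product_depth`.
#'
#' @param donor Output of [simulate_donor_repertoire()] (or its `$table`),
#'   paired with its truth.
#' @param truth The truth tibble from [simulate_donor_repertoire()].
#' @param mode `"poly"` or `"allo"`.
#' @param config The [sim_config()] used throughout.
#' @return A list: `table` (the product `RepertoireTable`) and `truth` with
#'   added columns `product_proportion` (pre-sampling) and `product_count`.
#' @export
simulate_expansion <- function(donor, truth, mode = c("poly", "allo"), config) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.list(donor) && !inherits(donor, "RepertoireTable")) donor <- donor$table
  stopifnot(inherits(donor, "RepertoireTable"))
  with_seed(derive_seed(config$seed, "expansion", mode), {
    p0 <- truth$donor_proportion
    factor <- exp(rnorm(length(p0), 0, config$poly_noise))
    if (mode == "allo") {
      # per-clone gains: heterogeneous allo-antigen stimulation (lognormal
      # around allo_gain) concentrates the repertoire on a subset of the
      # alloreactive clones; tissue-restricted clones are depleted
      gains <- config$allo_gain *
        exp(rnorm(length(p0), 0, config$allo_gain_spread))
      factor <- factor * ifelse(truth$class == "alloreactive", gains,
                                ifelse(truth$class == "tissue_restricted",
                                       1 / config$allo_gain, 1))
    }
    p1 <- p0 * factor
    p1 <- p1 / sum(p1)
    counts <- as.integer(rmultinom(1L, config$product_depth, p1))
    meta <- sample_meta(paste0(mode, "_product"), organ = "donor",
                        treatment = mode, setting = "donor_product")
    keep <- counts > 0L
    table <- repertoire_table(
      data.frame(chain = "TRB", v_call = truth$trb_v[keep],
                 j_call = truth$trb_j[keep], cdr3_nt = truth$cdr3b_nt[keep],
                 umi_count = counts[keep], stringsAsFactors = FALSE),
      meta
    )
    out_truth <- truth
    out_truth$product_proportion <- p1
    out_truth$product_count <- counts
    list(table = table, truth = out_truth)
  })
}

#' Simulate seeding of recipient organs
#'
#' Per-organ clone weights are the product proportions times the
#' class-specific organ weight, times a shared in vivo selection factor:
#' alloreactive clones expand `invivo_allo_gain`-fold and every clone draws
#' one lognormal engraftment factor (sdlog `seeding_noise`) applied in all
#' organs and recipients. Recipients are then independent multinomial
#' draws at the configured organ depths from the same weights, i.e. they
#' share selection and differ only by sampling noise (plus optional
#' `recipient_jitter`).
#'
#' @param product Output of [simulate_expansion()] (or its `$table`).
#' @param truth Truth tibble carrying `product_proportion`.
#' @param config The [sim_config()].
#' @return A list: `tables` (named list of `RepertoireTable`s, one per
#'   recipient and organ, e.g. `"allo_R1_colon"`) and `truth` with added
#'   engraftment factor and per-organ expected frequencies
#'   (`expected_freq_spleen` etc.).
#' @export
simulate_seeding <- function(product, truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.list(product) && !inherits(product, "RepertoireTable")) {
    product <- product$table
  }
  stopifnot(inherits(product, "RepertoireTable"))
  if (is.null(truth$product_proportion)) {
    stop("truth must carry product_proportion (run simulate_expansion first)")
  }
  mode <- product$meta$treatment
  with_seed(derive_seed(config$seed, "seeding", mode), {
    n <- nrow(truth)
    engraft <- exp(rnorm(n, 0, config$seeding_noise)) *
      ifelse(truth$class == "alloreactive", config$invivo_allo_gain, 1)
    class_w <- vapply(.ORGAN_NAMES, function(o) {
      vapply(truth$class, function(cl) config$seeding_weights[[cl]][[o]],
             numeric(1))
    }, numeric(n))
    if (n == 1L) class_w <- matrix(class_w, nrow = 1L,
                                   dimnames = list(NULL, .ORGAN_NAMES))
    base <- truth$product_proportion * engraft
    expected <- sapply(.ORGAN_NAMES, function(o) {
      w <- base * class_w[, o]
      if (sum(w) == 0) w else w / sum(w)
    })
    out_truth <- truth
    out_truth$engraft_factor <- engraft
    for (o in .ORGAN_NAMES) {
      out_truth[[paste0("expected_freq_", o)]] <- expected[, o]
    }

    tables <- list()
    for (r in seq_len(config$n_recipients)) {
      rid <- paste0("R", r)
      jitter <- if (config$recipient_jitter > 0) {
        exp(rnorm(n, 0, config$recipient_jitter))
      } else {
        rep(1, n)
      }
      for (o in .ORGAN_NAMES) {
        depth <- config$organ_depths[[o]]
        sid <- paste(mode, rid, o, sep = "_")
        meta <- sample_meta(sid, organ = o, treatment = mode,
                            setting = "GvHD", recipient_id = rid,
                            replicate = rid)
        if (depth == 0L) {
          warning("organ depth 0 for ", sid, "; emitting empty table")
          tables[[sid]] <- repertoire_table(
            data.frame(chain = character(0), v_call = character(0),
                       j_call = character(0), cdr3_nt = character(0)),
            meta)
          next
        }
        w <- base * class_w[, o] * jitter
        counts <- as.integer(rmultinom(1L, depth, w / sum(w)))
        keep <- counts > 0L
        tables[[sid]] <- repertoire_table(
          data.frame(chain = "TRB", v_call = truth$trb_v[keep],
                     j_call = truth$trb_j[keep],
                     cdr3_nt = truth$cdr3b_nt[keep],
                     umi_count = counts[keep], stringsAsFactors = FALSE),
          meta)
      }
    }
    list(tables = tables, truth = out_truth)
  })
}

#' Simulate single-cell paired-chain contig tables
#'
#' Draws cells from each seeded sample's clone proportions and emits 10x
#' `filtered_contig_annotations`-style rows (one TRA and one TRB contig per
#' intact cell, with alpha chains consistent with the clone's bulk beta
#' chain). A configurable fraction of cells is defective - missing the
#' alpha contig or carrying a second alpha from another clone - to exercise
#' the paired-chain filter.
#'
#' @param tables Named list of seeded `RepertoireTable`s.
#' @param truth Truth tibble (provides the paired alpha-chain identities).
#' @param config The [sim_config()].
#' @param cells_per_sample Cells drawn per sample.
#' @return A tibble of contig rows with columns `barcode`, `sample_id`,
#'   `chain`, `v_gene`, `j_gene`, `cdr3_nt`, `productive`,
#'   `high_confidence`, ready for [read_sc_contigs()] (per sample) or
#'   `write.csv`.
#' @export
simulate_sc_table <- function(tables, truth, config, cells_per_sample = 1000L) {
  stopifnot(inherits(config, "SimulationConfig"),
            is_count_scalar(cells_per_sample), cells_per_sample >= 1)
  with_seed(derive_seed(config$seed, "sc_table"), {
    all_rows <- list()
    for (sid in names(tables)) {
      tab <- tables[[sid]]
      idx <- match(clone_keys(tab), truth$clone_key)
      if (anyNA(idx)) stop("seeded table contains clones missing from truth")
      cells <- sample(seq_along(idx), cells_per_sample, replace = TRUE,
                      prob = tab$records$umi_count)
      defect <- runif(cells_per_sample) < config$sc_defect_fraction
      defect_type <- ifelse(runif(cells_per_sample) < 0.5, "missing_tra",
                            "extra_tra")
      for_cell <- function(i) {
        ti <- idx[cells[i]]
        bc <- sprintf("%s_%05d-1", sid, i)
        trb <- data.frame(barcode = bc, sample_id = sid, chain = "TRB",
                          v_gene = truth$trb_v[ti], j_gene = truth$trb_j[ti],
                          cdr3_nt = truth$cdr3b_nt[ti], productive = "True",
                          high_confidence = "True", stringsAsFactors = FALSE)
        tra <- data.frame(barcode = bc, sample_id = sid, chain = "TRA",
                          v_gene = truth$tra_v[ti], j_gene = truth$tra_j[ti],
                          cdr3_nt = truth$cdr3a_nt[ti], productive = "True",
                          high_confidence = "True", stringsAsFactors = FALSE)
        if (!defect[i]) return(rbind(tra, trb))
        if (defect_type[i] == "missing_tra") return(trb)
        other <- truth[sample(nrow(truth), 1L), ]
        tra2 <- tra
        tra2$v_gene <- other$tra_v; tra2$j_gene <- other$tra_j
        tra2$cdr3_nt <- other$cdr3a_nt
        rbind(tra, tra2, trb)
      }
      all_rows[[sid]] <- do.call(rbind, lapply(seq_len(cells_per_sample),
                                               for_cell))
    }
    as_tibble(do.call(rbind, all_rows))
  })
}

#' Simulate a complete adoptive-transfer experiment
#'
#' Convenience wrapper: donor repertoire, polyclonal and allo-selective
#' products, and organ seeding of both products in all recipients, all from
#' one config and fully deterministic given its seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `config`, `donor` (`$table`, `$truth`),
#'   `products` (`$poly`, `$allo` tables), `organs` (`$poly`, `$allo` named
#'   lists of organ tables) and `truths` (`$poly`, `$allo` truth tibbles
#'   with product and seeding columns).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  donor <- simulate_donor_repertoire(config)
  out <- list(config = config, donor = donor,
              products = list(), organs = list(), truths = list())
  for (mode in c("poly", "allo")) {
    prod <- simulate_expansion(donor$table, donor$truth, mode, config)
    seeded <- simulate_seeding(prod$table, prod$truth, config)
    out$products[[mode]] <- prod$table
    out$organs[[mode]] <- seeded$tables
    out$truths[[mode]] <- seeded$truth
  }
  out
}
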