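# End-to-end orchestration: simulate (or load) -> analyze -> report.
#
# A run config (R list or YAML file) names the input source and the
# analysis stages with their parameters. All stage parameters are validated
# before any stage runs (fail-fast); every output file is listed in a
# manifest with an MD5 checksum, and a rerun with the same config and seed
# reproduces identical checksums.

.KNOWN_STAGES <- c("diversity", "overlap", "barycentric", "tsea", "usage")

#' Validate a pipeline run configuration
#'
#' Checks the whole config before any computation: an output directory and
#' either a `simulation` section (passed to [sim_config()]) or a
#' `samplesheet` TSV must be present; stage names must be known; stage
#' parameters must be valid (e.g. `tsea$n_perm >= 99`); `tsea` requires a
#' graft reference, which the simulation provides (sample-sheet runs must
#' name a `graft_sample`).
#'
#' @param config A named list or the path of a YAML file.
#' @return The normalized config list, invisibly classed `RunConfig`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  config$seed <- as.integer(config$seed %||% 1L)
  has_sim <- !is.null(config$simulation)
  has_sheet <- !is.null(config$samplesheet)
  if (!has_sim && !has_sheet) {
    stop("config must provide a `simulation` section or a `samplesheet` path")
  }
  if (has_sim) {
    sim_args <- config$simulation
    if (isTRUE(sim_args) || length(sim_args) == 0L) sim_args <- list()
    sim_args$seed <- sim_args$seed %||% config$seed
    if (!is.null(sim_args$organ_depths)) {
      sim_args$organ_depths <- unlist(sim_args$organ_depths)
    }
    config$simulation_config <- do.call(sim_config, sim_args)
  } else if (!file.exists(config$samplesheet)) {
    stop("samplesheet not found: ", config$samplesheet)
  }
  stages <- config$stages %||% list()
  unknown <- setdiff(names(stages), .KNOWN_STAGES)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  }
  for (s in names(stages)) if (isTRUE(stages[[s]])) stages[[s]] <- list()
  if (!is.null(stages$diversity)) {
    n_reps <- stages$diversity$n_reps %||% 25L
    if (!is_count_scalar(n_reps) || n_reps < 1) stop("diversity$n_reps must be >= 1")
  }
  if (!is.null(stages$overlap)) {
    m <- stages$overlap$method %||% "morisita_horn"
    if (!m %in% c("morisita_horn", "morisita_classical", "umi_fraction")) {
      stop("overlap$method must be morisita_horn, morisita_classical or umi_fraction")
    }
  }
  if (!is.null(stages$barycentric)) {
    nm <- stages$barycentric$normalization %||% "frequency"
    if (!nm %in% c("frequency", "raw")) {
      stop("barycentric$normalization must be frequency or raw")
    }
    thr <- stages$barycentric$dominance_threshold %||% 0.9
    if (thr <= 1 / 3 || thr > 1) {
      stop("barycentric$dominance_threshold must lie in (1/3, 1]")
    }
  }
  if (!is.null(stages$tsea)) {
    n_perm <- stages$tsea$n_perm %||% 999L
    if (!is_count_scalar(n_perm) || n_perm < 99) stop("tsea$n_perm must be >= 99")
    if (!has_sim && is.null(config$graft_sample)) {
      stop("tsea requires a graft reference: simulation mode provides one, ",
           "sample-sheet mode must set config$graft_sample")
    }
  }
  config$stages <- stages
  class(config) <- c("RunConfig", "list")
  invisible(config)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

load_samplesheet <- function(config) {
  sheet <- read.delim(config$samplesheet, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("path", "sample_id", "organ", "treatment", "setting")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols)) {
    stop("samplesheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(config$samplesheet)
  tables <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$path[i]
    if (!file.exists(p)) p <- file.path(base, sheet$path[i])
    read_airr(p, sample_meta(
      sample_id = sheet$sample_id[i], organ = sheet$organ[i],
      treatment = sheet$treatment[i], setting = sheet$setting[i],
      recipient_id = sheet$recipient_id[i] %||% NA_character_,
      replicate = sheet$replicate[i] %||% NA_character_))
  })
  names(tables) <- sheet$sample_id
  tables
}

#' Run the clonal-tracking pipeline
#'
#' Validates the config (fail-fast), obtains the input repertoires (from
#' the synthetic generator or a sample sheet), runs the enabled analysis
#' stages in dependency order and writes all outputs plus a checksummed
#' manifest under `out_dir`. Reruns with an identical config and seed
#' produce byte-identical outputs.
#'
#' @param config A named list or YAML file path, see
#'   [validate_run_config()].
#' @return The manifest tibble (columns `file`, `md5`, `stage`), invisibly;
#'   also written to `out_dir/manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(path, stage) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      file = basename(path), md5 = unname(tools::md5sum(path)), stage = stage)
  }

  graft <- NULL
  if (!is.null(config$simulation_config)) {
    exper <- simulate_experiment(config$simulation_config)
    tables <- c(list(donor_fresh = exper$donor$table),
                stats::setNames(list(exper$products$poly, exper$products$allo),
                                c("poly_product", "allo_product")),
                exper$organs$poly, exper$organs$allo)
    for (sid in names(tables)) {
      p <- file.path(config$out_dir, paste0(sid, ".airr.tsv"))
      write_clonotype_table(tables[[sid]], p)
      note(p, "simulate")
    }
    for (mode in c("poly", "allo")) {
      p <- file.path(config$out_dir, paste0("truth_", mode, ".tsv"))
      write_tsv(as.data.frame(exper$truths[[mode]]), p)
      note(p, "simulate")
    }
    graft <- exper$products$allo
  } else {
    tables <- load_samplesheet(config)
    if (!is.null(config$graft_sample)) {
      if (!config$graft_sample %in% names(tables)) {
        stop("graft_sample '", config$graft_sample, "' not in samplesheet")
      }
      graft <- tables[[config$graft_sample]]
    }
  }

  stages <- config$stages
  if (!is.null(stages$diversity)) {
    div <- diversity_profile(unname(tables),
                             n_reps = stages$diversity$n_reps %||% 25L,
                             seed = config$seed)
    note(write_tsv(as.data.frame(div),
                   file.path(config$out_dir, "diversity.tsv")), "diversity")
  }
  if (!is.null(stages$overlap)) {
    method <- stages$overlap$method %||% "morisita_horn"
    m <- pairwise_overlap(unname(tables), method = method)
    df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    note(write_tsv(df, file.path(config$out_dir,
                                 paste0("overlap_", method, ".tsv"))), "overlap")
    links <- overlap_links(unname(tables))
    note(write_tsv(as.data.frame(links),
                   file.path(config$out_dir, "overlap_links.tsv")), "overlap")
  }
  if (!is.null(stages$barycentric)) {
    organ_sets <- split_organ_triples(tables)
    for (nm in names(organ_sets)) {
      pts <- barycentric_points(
        organ_sets[[nm]],
        normalization = stages$barycentric$normalization %||% "frequency",
        dominance_threshold = stages$barycentric$dominance_threshold %||% 0.9)
      note(write_tsv(as.data.frame(pts),
                     file.path(config$out_dir,
                               paste0("barycentric_", nm, ".tsv"))),
           "barycentric")
    }
  }
  if (!is.null(stages$tsea)) {
    if (is.null(graft)) stop("tsea stage needs a graft reference")
    ref <- rank_reference(graft)
    organ_tabs <- tables[vapply(tables, function(t)
      t$meta$organ %in% c("spleen", "liver", "colon"), logical(1))]
    rows <- list()
    for (sid in names(organ_tabs)) {
      res <- tsea_test(clone_keys(organ_tabs[[sid]]), ref,
                       n_perm = stages$tsea$n_perm %||% 999L,
                       seed = config$seed)
      rows[[sid]] <- tibble(sample_id = sid, query_size = res$query_size,
                            hits = res$hits, n_absent = res$n_absent,
                            mean_rank_stat = res$mean_rank_stat, es = res$es,
                            p_value = res$p_value, n_perm = res$n_perm)
      worm <- res$worm
      wdf <- data.frame(position = attr(worm, "positions"),
                        density = as.numeric(worm))
      note(write_tsv(wdf, file.path(config$out_dir,
                                    paste0("tsea_worm_", sid, ".tsv"))), "tsea")
    }
    note(write_tsv(as.data.frame(dplyr::bind_rows(rows)),
                   file.path(config$out_dir, "tsea.tsv")), "tsea")
  }
  if (!is.null(stages$usage)) {
    um <- segment_usage_matrix(unname(tables))
    df <- data.frame(sample_id = rownames(um), as.data.frame(um),
                     check.names = FALSE)
    note(write_tsv(df, file.path(config$out_dir, "segment_usage.tsv")),
         "usage")
    organ_groups <- group_tables_by_organ(tables)
    if (length(organ_groups) >= 2L) {
      enr <- segment_set_enrichment(
        organ_groups,
        segment_set = unlist(stages$usage$segment_set %||%
                               c("TRBV12-1", "TRBV12-2", "TRBV26")))
      note(write_tsv(as.data.frame(enr),
                     file.path(config$out_dir, "segment_enrichment.tsv")),
           "usage")
    }
  }

  manifest <- dplyr::bind_rows(manifest)
  write_tsv(as.data.frame(manifest), file.path(config$out_dir, "manifest.tsv"))
  invisible(manifest)
}

# Group organ tables of one treatment+recipient into spleen/liver/colon
# triples for barycentric triangles; pooled per treatment when recipients
# are present.
split_organ_triples <- function(tables) {
  organ_of <- vapply(tables, function(t) t$meta$organ, character(1))
  treat_of <- vapply(tables, function(t) t$meta$treatment, character(1))
  out <- list()
  for (tr in unique(treat_of)) {
    sel <- tables[treat_of == tr & organ_of %in% .ORGAN_NAMES]
    if (!length(sel)) next
    organs <- vapply(sel, function(t) t$meta$organ, character(1))
    if (!all(.ORGAN_NAMES %in% organs)) next
    triple <- lapply(.ORGAN_NAMES, function(o) {
      pool_samples(sel[organs == o], label = paste(tr, o, "pooled", sep = "_"))
    })
    out[[tr]] <- triple
  }
  out
}

group_tables_by_organ <- function(tables) {
  organ_of <- vapply(tables, function(t) t$meta$organ, character(1))
  out <- list()
  for (o in .ORGAN_NAMES) {
    sel <- tables[organ_of == o]
    if (length(sel)) out[[o]] <- pool_samples(sel, label = paste0(o, "_pooled"))
  }
  out
}
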