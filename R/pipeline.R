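#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of the `run_*` stage
#'   functions (input paths, thresholds, aggregation and sampler settings,
#'   output directory).
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

write_manifest <- function(dir, stage, config, inputs) {
  inputs <- as.character(inputs[!vapply(inputs, is.null, logical(1L))])
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("netrepurpose")),
    settings = config[!vapply(config, is.list, logical(1L))],
    input_checksums = as.list(tools::md5sum(inputs))
  )
  path <- file.path(dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the proximity screen and rank aggregation stage
#'
#' Loads the interactome, disease gene sets and drug-target network, scores
#' every drug against every gene set by closest proximity, aggregates the
#' per-gene-set rankings into a consensus, and writes the proximity/rank
#' tables, the consensus, and a reproducibility manifest.
#'
#' @param config list with `edge_list`, `gene_sets` (GMT path),
#'   `drug_targets` (TSV path) or `activity_records` (CSV path with raw
#'   activities), `outdir`, and optional `pactivity_threshold`,
#'   `activity_unit`, `unreachable`, `teleport`, `penalty_p`, `top_k`,
#'   `candidates`, `consensus_top_k`.
#' @return the `aggregation_result`, invisibly; side effect: files under
#'   `config$outdir`.
#' @export
run_screen <- function(config) {
  outdir <- cfg_get(config, "outdir", "results/screen")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  net <- load_interactome(config$edge_list)
  gene_sets <- read_gene_sets(config$gene_sets)
  dtn <- if (!is.null(config$drug_targets)) {
    read_drug_target_network(config$drug_targets)
  } else {
    filter_drug_targets(utils::read.csv(config$activity_records,
                                        stringsAsFactors = FALSE),
                        threshold_pactivity = cfg_get(config, "pactivity_threshold", 5),
                        unit = cfg_get(config, "activity_unit", "nM"))
  }
  pm <- proximity_screen(dtn, gene_sets, net,
                         unreachable = cfg_get(config, "unreachable", "infinity"))
  write_proximity(pm, outdir)
  lists <- ranked_lists(pm)
  if (length(lists) == 1L) {
    # a single gene set needs no aggregation: its ranking is the consensus
    agg <- structure(list(algorithm = "single-list", consensus = lists[[1L]],
                          stationary = NULL, mean_kendall = 0,
                          scores = c(`single-list` = 0)),
                     class = "aggregation_result")
  } else agg <- select_and_aggregate(
    lists,
    candidates = cfg_get(config, "candidates", c("MC3", "MC2", "MC1", "Borda")),
    penalty_p = cfg_get(config, "penalty_p", 0.5),
    top_k = config$top_k,
    teleport = cfg_get(config, "teleport", 0.05))
  ctk <- cfg_get(config, "consensus_top_k", length(agg$consensus))
  agg$consensus <- head(agg$consensus, ctk)
  write_consensus(agg, outdir)
  write_manifest(outdir, "screen", config,
                 c(config$edge_list, config$gene_sets,
                   config$drug_targets, config$activity_records))
  invisible(agg)
}

#' Run the rediscovery-rate validation stage
#'
#' Computes rediscovery-rate curves for the configured indication and for
#' every indication passing the clinical-data eligibility rule, against the
#' consensus produced by [run_screen()].
#'
#' @param config list with `consensus` (consensus TSV path) or
#'   `consensus_list` (character vector), `phase_table` (CSV path),
#'   `outdir`, and optional `indication`, `k_values`, `l`,
#'   `eligibility_min_drugs`.
#' @return data frame of rediscovery results, invisibly; side effect: TSV
#'   under `config$outdir`.
#' @export
run_validation <- function(config) {
  outdir <- cfg_get(config, "outdir", "results/validation")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  consensus <- if (!is.null(config$consensus_list)) config$consensus_list else {
    read.delim(config$consensus, stringsAsFactors = FALSE)$drug_id
  }
  table <- read_phase_table(config$phase_table)
  k_values <- cfg_get(config, "k_values", pmax(1L, floor(length(consensus) * c(0.05, 0.1, 0.2))))
  inds <- unique(c(cfg_get(config, "indication", character()),
                   eligible_indications(table,
                                        min_drugs = cfg_get(config, "eligibility_min_drugs", 100L))))
  if (length(inds) == 0L) stop("no indication to validate")
  out <- do.call(rbind, lapply(inds, function(i) {
    rediscovery_curve(consensus, table, i, k_values, l = config$l)
  }))
  write.table(out, file.path(outdir, "rediscovery.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(outdir, "validation", config,
                 c(config$consensus, config$phase_table))
  invisible(out)
}

#' Run the dose-response evidence stage
#'
#' Fits the Bayesian sigmoid model to every dataset in the input CSV,
#' applies the convergence check, computes hypothesis probabilities and
#' Bayes factors for the datasets that pass, and writes one JSON per
#' dataset plus a summary TSV (one row per drug-assay pair, suitable for an
#' evidence heatmap). A failed fit excludes that dataset with its reasons;
#' it does not abort the batch.
#'
#' @param config list with `dose_response` (CSV path) or `datasets` (named
#'   list of `dose_response_dataset`), `outdir`, and optional `seed`,
#'   `chains`, `draws`, `warmup`, `x_mode`, `rhat_max`, `ess_min`,
#'   `mcse_ratio_max`.
#' @return summary data frame, invisibly; side effects under
#'   `config$outdir`.
#' @export
run_doseresponse <- function(config) {
  outdir <- cfg_get(config, "outdir", "results/doseresponse")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  datasets <- if (!is.null(config$datasets)) config$datasets else {
    read_dose_response(config$dose_response)
  }
  seed <- cfg_get(config, "seed", 1L)
  rows <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    key <- names(datasets)[i]
    fit <- tryCatch(
      fit_dose_response(ds,
                        sampler = sampler_config(
                          chains = cfg_get(config, "chains", 4L),
                          draws = cfg_get(config, "draws", 1000L),
                          warmup = cfg_get(config, "warmup", 1000L),
                          thin = cfg_get(config, "thin", 80L),
                          seed = seed + i),
                        x_mode = cfg_get(config, "x_mode", "log10")),
      error = function(e) e)
    if (inherits(fit, "error")) {
      row <- data.frame(drug = ds$drug, assay = ds$assay, excluded = TRUE,
                        exclusion_reason = conditionMessage(fit),
                        median_fc = NA_real_, p_protective = NA_real_,
                        p_neutral = NA_real_, p_adverse = NA_real_,
                        bf = NA_real_, two_log_bf = NA_real_,
                        evidence_grade = NA_character_,
                        stringsAsFactors = FALSE)
      return(row)
    }
    chk <- check_fit(fit,
                     rhat_max = cfg_get(config, "rhat_max", 1.01),
                     ess_min = cfg_get(config, "ess_min", 400),
                     mcse_ratio_max = cfg_get(config, "mcse_ratio_max", 0.1))
    ht <- hypothesis_test(fit)
    result <- list(
      drug = ds$drug, assay = ds$assay,
      direction_of_benefit = ds$direction_of_benefit,
      excluded = !chk$pass, exclusion_reasons = chk$reasons,
      posterior_summary = lapply(as.data.frame(fit$samples), function(s) {
        list(median = median(s), q05 = quantile(s, 0.05)[[1L]],
             q95 = quantile(s, 0.95)[[1L]])
      }),
      diagnostics = fit$diagnostics,
      p_protective = ht$p_protective, p_neutral = ht$p_neutral,
      p_adverse = ht$p_adverse, bf = ht$bf, two_log_bf = ht$two_log_bf,
      bf_prior_corrected = ht$bf_prior_corrected,
      evidence_grade = ht$evidence_grade)
    jsonlite::write_json(result,
                         file.path(outdir, sprintf("%s.json", gsub("[^A-Za-z0-9_-]", "_", key))),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    data.frame(drug = ds$drug, assay = ds$assay, excluded = !chk$pass,
               exclusion_reason = paste(chk$reasons, collapse = "; "),
               median_fc = median(fit$samples[, "FC"]),
               p_protective = ht$p_protective, p_neutral = ht$p_neutral,
               p_adverse = ht$p_adverse, bf = ht$bf,
               two_log_bf = ht$two_log_bf,
               evidence_grade = ht$evidence_grade,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.table(out, file.path(outdir, "doseresponse_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(outdir, "doseresponse", config, c(config$dose_response))
  invisible(out)
}

#' Run the mechanistic path-enumeration stage
#'
#' Enumerates 1- to 3-edge drug-target-mediator-disease-gene paths for the
#' configured drugs against every gene set and writes the path table and
#' the mediator-by-gene-set summary.
#'
#' @param config list with `edge_list`, `gene_sets`, `drug_targets`,
#'   `drugs` (drug ids; default all), `outdir`, optional `max_edges`.
#' @return list with `paths` and `summary` data frames, invisibly.
#' @export
run_paths <- function(config) {
  outdir <- cfg_get(config, "outdir", "results/paths")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  net <- load_interactome(config$edge_list)
  gene_sets <- read_gene_sets(config$gene_sets)
  dtn <- read_drug_target_network(config$drug_targets)
  drugs <- cfg_get(config, "drugs", sort(unique(dtn$drug_id)))
  max_edges <- cfg_get(config, "max_edges", 3L)
  paths <- do.call(rbind, lapply(drugs, function(d) {
    do.call(rbind, lapply(gene_sets, function(gs) {
      p <- enumerate_paths(d, dtn, net, restrict_gene_set(gs, net), max_edges)
      if (nrow(p) > 0L) p$gene_set <- gs$name
      p
    }))
  }))
  rownames(paths) <- NULL
  summary <- if (!is.null(paths) && nrow(paths) > 0L && any(paths$n_edges == 3L)) {
    mediator_summary(paths, lapply(gene_sets, restrict_gene_set, net = net), net)
  } else {
    data.frame(target = character(), mediator = character(),
               gene_set = character(), n_adjacent = integer(),
               fraction = numeric(), stringsAsFactors = FALSE)
  }
  write_paths(paths, summary, outdir)
  write_manifest(outdir, "paths", config,
                 c(config$edge_list, config$gene_sets, config$drug_targets))
  invisible(list(paths = paths, summary = summary))
}
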