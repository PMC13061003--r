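#' Define a synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generators: a scale-free
#' interactome with a planted connected disease module, drugs whose targets
#' are placed near or far from the module with controlled strength, clinical
#' phases coupled to the planted proximity, and dose-response observations
#' drawn from the package's own heteroscedastic sigmoid model with known
#' fold changes. All generation is deterministic under `seed`.
#'
#' @param seed integer master seed.
#' @param n_genes interactome size (>= 10).
#' @param attachment preferential-attachment edges per new gene.
#' @param n_drugs number of drugs.
#' @param n_disease_genes planted module size (< n_genes).
#' @param targets_per_drug targets sampled per drug.
#' @param proximity_signal probability in `[0, 1]` that a drug's targets are
#'   placed within distance 1 of the disease module (1 = all drugs
#'   proximal, 0 = uniform placement).
#' @param phase_signal coupling in `[0, 1]` of clinical phase to planted
#'   proximity: with this probability a drug's phase is the deterministic
#'   map (proximal -> 4, distal -> 1), otherwise Binomial(4, 1/2) noise.
#' @param doses concentrations in uM for dose-response generation.
#' @param replicates replicates per concentration.
#' @param dose_response_truth data frame of ground-truth curve parameters
#'   (columns `drug`, `assay`, `fc_true`, `y0_true`, `k_true`, `ec50_true`,
#'   `sigma_true`, `direction`); `NULL` for the built-in default of one
#'   protective, one neutral and one adverse dataset per direction.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L, n_genes = 1000L, attachment = 3L,
                               n_drugs = 100L, n_disease_genes = 30L,
                               targets_per_drug = 3L,
                               proximity_signal = 0.5, phase_signal = 0.5,
                               doses = c(1, 3, 10), replicates = 5L,
                               dose_response_truth = NULL) {
  stopifnot(n_genes >= 10L, n_drugs >= 1L, n_disease_genes >= 1L,
            n_disease_genes < n_genes, targets_per_drug >= 1L,
            proximity_signal >= 0, proximity_signal <= 1,
            phase_signal >= 0, phase_signal <= 1,
            all(doses > 0), replicates >= 1L)
  if (is.null(dose_response_truth)) {
    dose_response_truth <- data.frame(
      drug = c("drugA", "drugA", "drugB", "drugB", "drugC", "drugC"),
      assay = rep(c("assay_down", "assay_up"), 3L),
      fc_true = c(0.3, 2.0, 1.0, 1.0, 2.0, 0.3),
      y0_true = 100,
      k_true = 3,
      ec50_true = log10(3),
      sigma_true = 0.05,
      direction = rep(c("decrease", "increase"), 3L),
      stringsAsFactors = FALSE
    )
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 attachment = as.integer(attachment),
                 n_drugs = as.integer(n_drugs),
                 n_disease_genes = as.integer(n_disease_genes),
                 targets_per_drug = as.integer(targets_per_drug),
                 proximity_signal = proximity_signal,
                 phase_signal = phase_signal,
                 doses = doses, replicates = as.integer(replicates),
                 dose_response_truth = dose_response_truth),
            class = "synthetic_scenario")
}

#' Generate a scale-free synthetic interactome
#'
#' Undirected preferential-attachment graph (heavy-tailed degrees, as in
#' real interactomes) with gene names `G0001`, `G0002`, ... Connected by
#' construction; deterministic under the scenario seed. The generator's own
#' edge count is recorded in the `declared_edges` graph attribute.
#'
#' @param scenario a `synthetic_scenario`.
#' @return an `igraph` interactome.
#' @export
make_interactome <- function(scenario) {
  set.seed(scenario$seed)
  g <- igraph::sample_pa(scenario$n_genes, power = 1,
                         m = scenario$attachment, directed = FALSE)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(scenario$n_genes))
  g <- igraph::set_graph_attr(g, "declared_edges", igraph::ecount(g))
  g
}

#' Plant a connected disease module in a synthetic interactome
#'
#' Grows a connected gene set by snowball sampling from a random seed gene:
#' at each step a uniformly chosen neighbour of the current set is added, so
#' the induced subgraph is connected (hence has at least size - 1 edges).
#'
#' @param net interactome from [make_interactome()].
#' @param scenario a `synthetic_scenario`.
#' @return a `gene_set` named `"planted_module"`.
#' @export
plant_disease_module <- function(net, scenario) {
  set.seed(scenario$seed + 1L)
  nodes <- igraph::V(net)$name
  current <- sample(nodes, 1L)
  while (length(current) < scenario$n_disease_genes) {
    nb <- unique(unlist(lapply(current, function(v) {
      igraph::V(net)$name[igraph::neighbors(net, v)]
    })))
    nb <- setdiff(nb, current)
    if (length(nb) == 0L) stop("cannot grow a connected module of the requested size")
    current <- c(current, sample(nb, 1L))
  }
  gene_set("planted_module", current, "synthetic")
}

#' Generate drugs with targets placed at controlled proximity
#'
#' Each drug is independently declared proximal with probability
#' `proximity_signal`; a proximal drug samples its targets from the disease
#' module and its distance-1 neighbourhood (so its closest proximity is at
#' most 1), otherwise targets are sampled uniformly from all genes. Mean
#' pActivity values are drawn uniformly in [5, 9], above the retention
#' threshold by construction.
#'
#' @param net interactome.
#' @param disease planted `gene_set`.
#' @param scenario a `synthetic_scenario`.
#' @return list with `dtn` (a `drug_target_network`) and `truth` (data
#'   frame `drug_id`, `proximal` — the planted ground-truth labels).
#' @export
make_drugs <- function(net, disease, scenario) {
  set.seed(scenario$seed + 2L)
  nodes <- igraph::V(net)$name
  near <- unique(c(disease$genes,
                   unlist(lapply(disease$genes, function(v) {
                     igraph::V(net)$name[igraph::neighbors(net, v)]
                   }))))
  drugs <- sprintf("D%03d", seq_len(scenario$n_drugs))
  proximal <- runif(scenario$n_drugs) < scenario$proximity_signal
  rows <- lapply(seq_along(drugs), function(i) {
    pool <- if (proximal[i]) near else nodes
    tg <- sample(pool, min(scenario$targets_per_drug, length(pool)))
    data.frame(drug_id = drugs[i], gene = tg,
               mean_pactivity = runif(length(tg), 5, 9),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("drug_id", "gene")]), , drop = FALSE]
  df <- df[order(df$drug_id, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  list(dtn = as_drug_target_network(df, 5),
       truth = data.frame(drug_id = drugs, proximal = proximal,
                          stringsAsFactors = FALSE))
}

#' Generate a clinical-phase table coupled to planted proximity
#'
#' For the planted indication each drug's phase is, with probability
#' `phase_signal`, the deterministic map proximal -> 4 / distal -> 1 and
#' otherwise an independent Binomial(4, 1/2) draw; `phase_signal = 0` gives
#' i.i.d. phases (null coupling), `phase_signal = 1` a fully deterministic
#' table whose rediscovery rate is known in closed form. Optional extra
#' indications carry i.i.d. Binomial(4, 1/2) phases.
#'
#' @param drug_truth the `truth` data frame from [make_drugs()].
#' @param scenario a `synthetic_scenario`.
#' @param indication name of the planted indication.
#' @param n_null_indications number of additional uncoupled indications.
#' @param seed optional seed override (defaults to `scenario$seed + 3`),
#'   letting callers redraw phases over many seeds on one fixed screen.
#' @return a `phase_table`.
#' @export
make_phase_table <- function(drug_truth, scenario, indication = "planted",
                             n_null_indications = 0L, seed = NULL) {
  set.seed(if (is.null(seed)) scenario$seed + 3L else seed)
  n <- nrow(drug_truth)
  deterministic <- runif(n) < scenario$phase_signal
  phase <- ifelse(deterministic,
                  ifelse(drug_truth$proximal, 4L, 1L),
                  rbinom(n, 4L, 0.5))
  out <- data.frame(drug_id = drug_truth$drug_id, indication = indication,
                    max_phase = as.integer(phase), stringsAsFactors = FALSE)
  if (n_null_indications > 0L) {
    extra <- do.call(rbind, lapply(seq_len(n_null_indications), function(j) {
      data.frame(drug_id = drug_truth$drug_id,
                 indication = sprintf("null_ind_%02d", j),
                 max_phase = rbinom(n, 4L, 0.5),
                 stringsAsFactors = FALSE)
    }))
    out <- rbind(out, extra)
  }
  phase_table(out)
}

#' Simulate dose-response datasets from the model's own data-generating
#' process
#'
#' Draws `y ~ Normal(mu(x), sigma_true * mu(x))` with the sigmoid mean
#' evaluated on the log10-concentration axis at the scenario's doses, one
#' dataset per row of the scenario's ground-truth table. Parameter
#' combinations yielding a non-positive mean are rejected (the
#' mean-proportional noise scale would be invalid).
#'
#' @param scenario a `synthetic_scenario`.
#' @return list with `datasets` (named list of `dose_response_dataset`) and
#'   `truth` (the ground-truth parameter table).
#' @export
make_dose_response <- function(scenario) {
  set.seed(scenario$seed + 4L)
  tt <- scenario$dose_response_truth
  x <- rep(log10(scenario$doses), each = scenario$replicates)
  conc <- rep(scenario$doses, each = scenario$replicates)
  datasets <- lapply(seq_len(nrow(tt)), function(i) {
    y0 <- tt$y0_true[i]
    y1 <- tt$fc_true[i] * y0
    mu <- sigmoid_mean(x, y0, y1, tt$k_true[i], tt$ec50_true[i])
    if (any(mu <= 0)) stop("ground-truth parameters give non-positive mean response")
    y <- rnorm(length(x), mu, tt$sigma_true[i] * mu)
    dose_response_dataset(tt$drug[i], tt$assay[i], tt$direction[i],
                          conc, y, "vehicle")
  })
  names(datasets) <- paste(tt$drug, tt$assay, sep = "|")
  list(datasets = datasets, truth = tt)
}

#' Generate a full synthetic scenario in memory
#'
#' Runs every generator of the scenario and returns the objects plus the
#' ground-truth sidecar.
#'
#' @param scenario a `synthetic_scenario`.
#' @return list with `net`, `disease`, `dtn`, `drug_truth`, `phases`,
#'   `dose_response` (datasets + truth) and `scenario`.
#' @export
generate_scenario <- function(scenario) {
  net <- make_interactome(scenario)
  disease <- plant_disease_module(net, scenario)
  drugs <- make_drugs(net, disease, scenario)
  phases <- make_phase_table(drugs$truth, scenario)
  dr <- make_dose_response(scenario)
  list(net = net, disease = disease, dtn = drugs$dtn,
       drug_truth = drugs$truth, phases = phases,
       dose_response = dr, scenario = scenario)
}

#' Write a generated scenario to the pipeline's file formats
#'
#' Emits exactly the formats the analysis stages consume — edge-list TSV,
#' GMT gene sets, drug-target TSV, phase CSV, dose-response CSV — plus a
#' `truth.json` sidecar carrying the seed and every planted ground-truth
#' label, so downstream checks never re-derive truth from generator
#' internals.
#'
#' @param generated output of [generate_scenario()].
#' @param dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_scenario <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "interactome_edges.tsv"),
    gmt = file.path(dir, "disease_modules.gmt"),
    dtn = file.path(dir, "drug_targets.tsv"),
    phases = file.path(dir, "clinical_phases.csv"),
    doses = file.path(dir, "dose_response.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_interactome(generated$net, paths[["edges"]])
  write_gene_sets(list(generated$disease), paths[["gmt"]])
  write_drug_target_network(generated$dtn, paths[["dtn"]])
  utils::write.csv(as.data.frame(generated$phases), paths[["phases"]],
                   row.names = FALSE, quote = FALSE)
  dr_rows <- do.call(rbind, lapply(generated$dose_response$datasets, function(d) {
    data.frame(drug = d$drug, assay = d$assay,
               direction_of_benefit = d$direction_of_benefit,
               control_type = d$control_type,
               concentration_uM = d$concentration_uM,
               bioactivity = d$bioactivity, stringsAsFactors = FALSE)
  }))
  utils::write.csv(dr_rows, paths[["doses"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    seed = generated$scenario$seed,
    scenario = generated$scenario[setdiff(names(generated$scenario),
                                          "dose_response_truth")],
    drug_truth = generated$drug_truth,
    dose_response_truth = generated$dose_response$truth,
    declared_edges = igraph::graph_attr(generated$net, "declared_edges"),
    disease_genes = generated$disease$genes
  ), paths[["truth"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
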