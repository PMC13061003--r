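#' Enumerate short mechanistic paths from a drug to disease genes
#'
#' Enumerates simple paths of the form drug -> target (1 edge),
#' drug -> target -> disease gene (2 edges) and
#' drug -> target -> mediator -> disease gene (3 edges), where the
#' drug->target link counts as the first edge, consecutive genes are
#' interactome edges, and no gene repeats within a path. Mediators that are
#' themselves disease genes are excluded by default (such routes already
#' appear as 2-edge paths).
#'
#' @param drug drug identifier; must be present in `dtn`.
#' @param dtn a `drug_target_network`.
#' @param net `igraph` interactome.
#' @param disease a `gene_set` of disease genes.
#' @param max_edges maximum path length in edges (1, 2 or 3).
#' @param exclude_disease_mediators drop 3-edge paths whose mediator is a
#'   disease gene (default `TRUE`).
#' @return data frame with columns `drug`, `target`, `mediator` (`NA` for
#'   paths shorter than 3 edges), `disease_gene` (equal to `target` for
#'   1-edge paths, where the target is itself a disease gene) and `n_edges`.
#' @export
enumerate_paths <- function(drug, dtn, net, disease, max_edges = 3L,
                            exclude_disease_mediators = TRUE) {
  if (!max_edges %in% 1:3) stop("max_edges must be 1, 2 or 3")
  if (!drug %in% dtn$drug_id) stop(sprintf("drug '%s' absent from the drug-target network", drug))
  nodes <- igraph::V(net)$name
  targets <- intersect(drug_targets(dtn, drug), nodes)
  dis <- intersect(disease$genes, nodes)
  rows <- list()
  add <- function(target, mediator, gene, n_edges) {
    rows[[length(rows) + 1L]] <<- data.frame(
      drug = drug, target = target, mediator = mediator,
      disease_gene = gene, n_edges = n_edges, stringsAsFactors = FALSE)
  }
  for (t in targets) {
    if (t %in% dis) add(t, NA_character_, t, 1L)
    if (max_edges < 2L) next
    nb_t <- igraph::V(net)$name[igraph::neighbors(net, t)]
    for (g in intersect(nb_t, dis)) {
      if (g != t) add(t, NA_character_, g, 2L)
    }
    if (max_edges < 3L) next
    mediators <- setdiff(nb_t, t)
    if (exclude_disease_mediators) mediators <- setdiff(mediators, dis)
    for (m in mediators) {
      nb_m <- igraph::V(net)$name[igraph::neighbors(net, m)]
      for (g in intersect(nb_m, dis)) {
        if (g != t && g != m) add(t, m, g, 3L)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(drug = character(), target = character(),
                      mediator = character(), disease_gene = character(),
                      n_edges = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_edges, out$target, out$mediator, out$disease_gene,
                   na.last = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mediator interaction summary across gene sets
#'
#' For every (target, mediator) pair occurring in a 3-edge mechanistic path,
#' counts the distinct genes of each gene set adjacent to the mediator in
#' the interactome and the corresponding fraction of the set — the tabular
#' form of a mediator-by-gene-set heatmap. Counts are per distinct gene, so
#' they are invariant to how many paths traverse the mediator.
#'
#' @param paths path data frame from [enumerate_paths()] (possibly
#'   row-bound over drugs).
#' @param gene_sets list of `gene_set` objects.
#' @param net `igraph` interactome.
#' @return long-format data frame: `target`, `mediator`, `gene_set`,
#'   `n_adjacent`, `fraction`.
#' @export
mediator_summary <- function(paths, gene_sets, net) {
  if (nrow(paths) == 0L) stop("no paths supplied")
  p3 <- paths[paths$n_edges == 3L & !is.na(paths$mediator), , drop = FALSE]
  pairs <- unique(p3[c("target", "mediator")])
  if (nrow(pairs) == 0L) {
    return(data.frame(target = character(), mediator = character(),
                      gene_set = character(), n_adjacent = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    m <- pairs$mediator[i]
    nb <- igraph::V(net)$name[igraph::neighbors(net, m)]
    do.call(rbind, lapply(gene_sets, function(gs) {
      n_adj <- length(intersect(nb, gs$genes))
      data.frame(target = pairs$target[i], mediator = m, gene_set = gs$name,
                 n_adjacent = n_adj, fraction = n_adj / length(gs$genes),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write path-analysis outputs
#'
#' @param paths path data frame.
#' @param summary mediator summary data frame.
#' @param dir output directory.
#' @return file paths, invisibly.
#' @export
write_paths <- function(paths, summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "paths.tsv")
  pm <- file.path(dir, "mediator_summary.tsv")
  write.table(paths, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pp, pm))
}
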