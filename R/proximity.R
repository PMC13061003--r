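#' Closest-distance network proximity of a target set to a disease module
#'
#' Computes the closest measure
#' \deqn{d(S,T) = \frac{1}{|T|} \sum_{t \in T} \min_{s \in S} d(s,t)}
#' the average over drug targets of the unweighted shortest-path distance to
#' the nearest disease gene. Targets unreachable from every disease gene
#' contribute `Inf`, making the result `Inf`, unless
#' `unreachable = "drop"`, in which case they are removed from the average.
#'
#' @param targets character vector of target genes (the set T).
#' @param disease_genes character vector of disease genes (the set S).
#' @param net `igraph` interactome.
#' @param unreachable `"infinity"` (default) or `"drop"`.
#' @return a single non-negative number, possibly `Inf`. Zero exactly when
#'   every in-network target is itself a disease gene.
#' @export
closest_proximity <- function(targets, disease_genes, net,
                              unreachable = c("infinity", "drop")) {
  unreachable <- match.arg(unreachable)
  nodes <- igraph::V(net)$name
  t_in <- unique(targets[targets %in% nodes])
  s_in <- unique(disease_genes[disease_genes %in% nodes])
  if (length(t_in) == 0L) {
    stop("no drug target is present in the interactome")
  }
  if (length(s_in) == 0L) {
    stop("no disease gene is present in the interactome")
  }
  dm <- igraph::distances(net, v = t_in, to = s_in)
  mins <- apply(dm, 1L, min)
  if (unreachable == "drop") {
    mins <- mins[is.finite(mins)]
    if (length(mins) == 0L) return(Inf)
  }
  mean(mins)
}

#' Proximity screen of a drug-target network against disease gene sets
#'
#' Fills a drugs-by-gene-sets matrix of closest proximities and a companion
#' matrix of per-column ranks (rank 1 = most proximal). Ranks are strict
#' permutations: ties in proximity are broken lexicographically by drug
#' identifier so downstream rank aggregation receives strict orders; drugs
#' with infinite proximity rank last. Drugs with no target in the interactome
#' are excluded (and listed in the metadata).
#'
#' @param dtn a `drug_target_network`.
#' @param gene_sets list of `gene_set` objects.
#' @param net `igraph` interactome.
#' @param unreachable passed to [closest_proximity()].
#' @return an object of class `proximity_matrix`: list with `drugs`,
#'   `gene_sets`, numeric matrix `d`, integer matrix `ranks`, and `meta`
#'   (tie rule, infinity policy, excluded drugs).
#' @export
proximity_screen <- function(dtn, gene_sets, net,
                             unreachable = c("infinity", "drop")) {
  unreachable <- match.arg(unreachable)
  gene_sets <- lapply(gene_sets, restrict_gene_set, net = net)
  if (length(gene_sets) == 0L) stop("no gene set survives restriction")
  nodes <- igraph::V(net)$name
  drugs_all <- sort(unique(dtn$drug_id))
  in_net <- vapply(drugs_all, function(d) any(drug_targets(dtn, d) %in% nodes),
                   logical(1L))
  excluded <- drugs_all[!in_net]
  if (length(excluded) > 0L) {
    message(sprintf("proximity_screen: excluded %d drug(s) with no in-network target: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  drugs <- drugs_all[in_net]
  if (length(drugs) == 0L) stop("no drug has a target in the interactome")
  set_names <- vapply(gene_sets, `[[`, character(1L), "name")

  # one distance computation per drug covering all gene sets
  all_disease <- sort(unique(unlist(lapply(gene_sets, `[[`, "genes"))))
  d <- matrix(NA_real_, length(drugs), length(gene_sets),
              dimnames = list(drugs, set_names))
  for (i in seq_along(drugs)) {
    t_in <- unique(intersect(drug_targets(dtn, drugs[i]), nodes))
    dm <- igraph::distances(net, v = t_in, to = all_disease)
    for (j in seq_along(gene_sets)) {
      mins <- apply(dm[, gene_sets[[j]]$genes, drop = FALSE], 1L, min)
      if (unreachable == "drop") {
        fin <- mins[is.finite(mins)]
        d[i, j] <- if (length(fin) == 0L) Inf else mean(fin)
      } else {
        d[i, j] <- mean(mins)
      }
    }
  }
  ranks <- vapply(seq_len(ncol(d)), function(j) {
    ord <- order(d[, j], drugs)  # Inf sorts last; ties by drug_id
    r <- integer(nrow(d))
    r[ord] <- seq_len(nrow(d))
    r
  }, integer(nrow(d)))
  ranks <- matrix(ranks, nrow = nrow(d), dimnames = dimnames(d))
  structure(list(drugs = drugs, gene_sets = set_names, d = d, ranks = ranks,
                 meta = list(tie_rule = "lexicographic by drug_id",
                             unreachable = unreachable,
                             excluded_drugs = excluded,
                             n_drugs = length(drugs),
                             n_gene_sets = length(gene_sets))),
            class = "proximity_matrix")
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf("proximity_matrix: %d drugs x %d gene sets (%d excluded; ties %s; unreachable=%s)\n",
              length(x$drugs), length(x$gene_sets),
              length(x$meta$excluded_drugs), x$meta$tie_rule, x$meta$unreachable))
  invisible(x)
}

#' Spearman correlation between gene-set proximity columns
#'
#' For each pair of gene-set columns, computes the Spearman rank correlation
#' of proximity values over the drugs finite in both columns. Pairs with
#' fewer than three common finite drugs are reported as `NA`.
#'
#' @param pm a `proximity_matrix`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
rank_correlation <- function(pm) {
  d <- pm$d
  k <- ncol(d)
  if (k < 2L) stop("rank_correlation requires at least two gene-set columns")
  out <- diag(1, k)
  dimnames(out) <- list(colnames(d), colnames(d))
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      ok <- is.finite(d[, a]) & is.finite(d[, b])
      out[a, b] <- out[b, a] <-
        if (sum(ok) < 3L) NA_real_ else cor(d[ok, a], d[ok, b], method = "spearman")
    }
  }
  out
}

#' Extract the per-gene-set ranked drug lists from a proximity matrix
#'
#' @param pm a `proximity_matrix`.
#' @return named list of character vectors of drug ids, best first — the
#'   `ranked_list` inputs for rank aggregation.
#' @export
ranked_lists <- function(pm) {
  out <- lapply(seq_along(pm$gene_sets), function(j) {
    pm$drugs[order(pm$ranks[, j])]
  })
  names(out) <- pm$gene_sets
  out
}

#' Write proximity-screen outputs
#'
#' Writes the proximity TSV (rows drugs, columns gene sets), the companion
#' rank TSV, and a JSON metadata file recording the tie rule, the infinity
#' policy, and counts.
#'
#' @param pm a `proximity_matrix`.
#' @param dir output directory (created if absent).
#' @return character vector of the three file paths, invisibly.
#' @export
write_proximity <- function(pm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- file.path(dir, "proximity.tsv")
  pr <- file.path(dir, "ranks.tsv")
  pj <- file.path(dir, "proximity_meta.json")
  write.table(data.frame(drug_id = pm$drugs, pm$d, check.names = FALSE),
              pd, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(drug_id = pm$drugs, pm$ranks, check.names = FALSE),
              pr, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(pm$meta, pj, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(pd, pr, pj))
}
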