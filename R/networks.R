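#' Load a gene-gene interactome from an edge list
#'
#' Reads a two-column edge list of gene symbols and returns a simple
#' undirected [igraph][igraph::igraph-package] graph. Self-loops and duplicate
#' edges (in either orientation) are dropped; the number removed is reported
#' with a message.
#'
#' @param source path to a tab-separated edge-list file (two columns, no
#'   header by default; SIF files with an interaction-type middle column are
#'   accepted), or a two-column character matrix / data frame of edges.
#' @param header logical; skip a header line when reading from file.
#' @return an undirected simple `igraph` graph whose vertex names are gene
#'   symbols.
#' @export
load_interactome <- function(source, header = FALSE) {
  if (is.character(source) && length(source) == 1L) {
    lines <- readLines(source)
    if (header && length(lines) > 0L) lines <- lines[-1L]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty edge list: no edges to load")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != 2L & nf != 3L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed edge-list line %d: expected 2 columns, found %d",
                   bad[1L] + as.integer(header), nf[bad[1L]]))
    }
    # SIF: source <interaction> target; plain TSV: source target
    em <- t(vapply(fields, function(f) {
      if (length(f) == 3L) c(f[1L], f[3L]) else f
    }, character(2L)))
  } else {
    em <- as.matrix(source)
    if (is.null(dim(em)) || ncol(em) != 2L) stop("edge input must have two columns")
    if (nrow(em) == 0L) stop("empty edge list: no edges to load")
    storage.mode(em) <- "character"
  }
  em <- trimws(em)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  n_raw <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- n_raw - igraph::ecount(g)
  if (dropped > 0L) {
    message(sprintf("load_interactome: dropped %d self-loop/duplicate edge(s)", dropped))
  }
  g
}

#' Write an interactome to a TSV edge list
#'
#' @param net an `igraph` interactome.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path) {
  em <- igraph::as_edgelist(net, names = TRUE)
  write.table(em, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a raw activity value to pActivity
#'
#' pActivity is the negative base-10 logarithm of a molar activity
#' concentration; a value of 5 corresponds to 10 uM.
#'
#' @param value positive activity values.
#' @param unit unit of `value`: `"nM"`, `"uM"` or `"M"`.
#' @return pActivity values (-log10 molar).
#' @export
pactivity <- function(value, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  offset <- switch(unit, nM = 9, uM = 6, M = 0)
  offset - log10(value)
}

#' Build the drug-target network from raw activity records
#'
#' Averages per-measurement pActivity (-log10 molar activity) within each
#' (drug, gene) pair and retains the pairs whose mean pActivity meets the
#' threshold. The default threshold of 5 corresponds to a mean activity of at
#' most 10 uM.
#'
#' @param records data frame with columns `drug_id`, `gene`, `standard_value`
#'   (positive activity concentrations); duplicate measurements for a pair all
#'   enter the mean.
#' @param threshold_pactivity minimum mean pActivity for a pair to be kept.
#' @param unit unit of `standard_value` (`"nM"` by default, the common
#'   activity-repository convention).
#' @return a data frame of class `drug_target_network` with columns
#'   `drug_id`, `gene`, `mean_pactivity`, one row per retained pair.
#' @export
filter_drug_targets <- function(records, threshold_pactivity = 5,
                                unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  req <- c("drug_id", "gene", "standard_value")
  if (length(records) == 0L || nrow(as.data.frame(records)) == 0L) {
    out <- data.frame(drug_id = character(), gene = character(),
                      mean_pactivity = numeric(), stringsAsFactors = FALSE)
    return(as_drug_target_network(out, threshold_pactivity))
  }
  records <- as.data.frame(records)
  if (!all(req %in% names(records))) {
    stop("records must have columns drug_id, gene, standard_value")
  }
  bad <- !is.finite(records$standard_value) | records$standard_value <= 0
  if (any(bad)) {
    warning(sprintf("filter_drug_targets: rejected %d record(s) with non-positive activity",
                    sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    out <- data.frame(drug_id = character(), gene = character(),
                      mean_pactivity = numeric(), stringsAsFactors = FALSE)
    return(as_drug_target_network(out, threshold_pactivity))
  }
  p <- pactivity(records$standard_value, unit)
  key <- interaction(records$drug_id, records$gene, drop = TRUE, sep = "\r")
  means <- tapply(p, key, mean)
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  out <- data.frame(
    drug_id = vapply(parts, `[`, character(1L), 1L),
    gene = vapply(parts, `[`, character(1L), 2L),
    mean_pactivity = as.numeric(means),
    stringsAsFactors = FALSE
  )
  out <- out[out$mean_pactivity >= threshold_pactivity, , drop = FALSE]
  out <- out[order(out$drug_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  as_drug_target_network(out, threshold_pactivity)
}

as_drug_target_network <- function(df, threshold = NA_real_) {
  stopifnot(all(c("drug_id", "gene", "mean_pactivity") %in% names(df)))
  if (anyDuplicated(df[c("drug_id", "gene")]) > 0L) {
    stop("duplicate (drug, gene) pairs in drug-target network")
  }
  attr(df, "threshold_pactivity") <- threshold
  class(df) <- c("drug_target_network", "data.frame")
  df
}

#' Read a drug-target network from TSV
#'
#' @param path TSV with header columns `drug_id`, `gene`, `mean_pactivity`.
#' @return a `drug_target_network` data frame.
#' @export
read_drug_target_network <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  as_drug_target_network(df)
}

#' Write a drug-target network to TSV
#' @param dtn a `drug_target_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_target_network <- function(dtn, path) {
  write.table(as.data.frame(dtn), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Target genes of one drug
#' @param dtn a `drug_target_network`.
#' @param drug drug identifier.
#' @return character vector of target gene symbols (possibly empty).
#' @export
drug_targets <- function(dtn, drug) {
  dtn$gene[dtn$drug_id == drug]
}

#' Construct a gene set
#'
#' @param name gene-set name.
#' @param genes character vector of gene symbols; deduplicated.
#' @param source_label free-text provenance label.
#' @return a `gene_set` list with fields `name`, `genes`, `source_label`.
#' @export
gene_set <- function(name, genes, source_label = "") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene set must be non-empty")
  structure(list(name = name, genes = genes, source_label = source_label),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (name, description, genes...).
#' @return list of `gene_set` objects, named by set name.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  out <- lapply(names(sets), function(nm) gene_set(nm, sets[[nm]], source_label = path))
  names(out) <- names(sets)
  out
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets list of `gene_set` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs) {
    paste(c(gs$name, gs$source_label, gs$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a gene set to the interactome
#'
#' Proximity is only defined for genes present in the network, so disease
#' genes absent from the interactome are dropped (with a message naming how
#' many). An empty intersection is an error.
#'
#' @param gs a `gene_set`.
#' @param net an `igraph` interactome.
#' @return a `gene_set` containing only in-network genes.
#' @export
restrict_gene_set <- function(gs, net) {
  nodes <- igraph::V(net)$name
  keep <- gs$genes[gs$genes %in% nodes]
  if (length(keep) == 0L) {
    stop(sprintf("gene set '%s' has no genes in the interactome; proximity undefined",
                 gs$name))
  }
  dropped <- setdiff(gs$genes, keep)
  if (length(dropped) > 0L) {
    message(sprintf("restrict_gene_set: dropped %d gene(s) absent from the interactome (%s)",
                    length(dropped), gs$name))
  }
  gene_set(gs$name, keep, gs$source_label)
}
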