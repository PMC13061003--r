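#!/usr/bin/env Rscript
# Stage 5: mechanistic path enumeration for the top-ranked drugs.
#
# Enumerates drug -> target -> mediator -> disease-gene paths (1 to 3
# edges) for the top 10 consensus drugs and summarises, for every
# (target, mediator) pair, how many disease genes each mediator touches.
# Outputs under results/paths/.

suppressMessages(library(netrepurpose))

consensus <- read.delim("results/screen/consensus.tsv",
                        stringsAsFactors = FALSE)$drug_id

res <- run_paths(list(
  edge_list = "results/data/interactome_edges.tsv",
  gene_sets = "results/data/disease_modules.gmt",
  drug_targets = "results/data/drug_targets.tsv",
  drugs = head(consensus, 10),
  outdir = "results/paths"))

tab <- table(res$paths$n_edges)
cat("paths by length (edges):\n")
print(tab)
if (nrow(res$summary) > 0) {
  top_med <- res$summary[order(-res$summary$fraction), ][1, ]
  cat(sprintf("most connected mediator: %s (touches %.0f%% of %s via target %s)\n",
              top_med$mediator, 100 * top_med$fraction, top_med$gene_set,
              top_med$target))
}
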