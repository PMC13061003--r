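#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the study conditions at desk scale: a 1,000-gene scale-free
# interactome, a planted 30-gene disease module plus an independent second
# module, 100 drugs (half placed proximal to the planted module), clinical
# phases strongly coupled to planted proximity, and six dose-response
# datasets (protective / neutral / adverse truth in both benefit
# directions). Everything is written in the pipeline's file formats under
# results/data/ together with a truth.json sidecar.

suppressMessages(library(netrepurpose))

sc <- synthetic_scenario(seed = 1, proximity_signal = 0.5, phase_signal = 0.8)
gen <- generate_scenario(sc)
paths <- write_scenario(gen, "results/data")

# a second disease module so that rank aggregation has two input rankings
sc_b <- synthetic_scenario(seed = 1001, n_disease_genes = 30)
module_b <- plant_disease_module(gen$net, sc_b)
module_b$name <- "module_b"
write_gene_sets(list(gen$disease, module_b), paths[["gmt"]])

cat(sprintf("interactome: %d genes, %d interactions\n",
            igraph::vcount(gen$net), igraph::ecount(gen$net)))
cat(sprintf("disease modules: %s (%d genes), %s (%d genes)\n",
            gen$disease$name, length(gen$disease$genes),
            module_b$name, length(module_b$genes)))
cat(sprintf("drugs: %d (%d planted proximal)\n",
            nrow(gen$drug_truth), sum(gen$drug_truth$proximal)))
cat(sprintf("dose-response datasets: %d\n",
            length(gen$dose_response$datasets)))
cat("inputs written under results/data/\n")
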