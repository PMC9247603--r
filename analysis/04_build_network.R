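#!/usr/bin/env Rscript
# From inferred MUL species tree to reticulate species network.
#
# Takes the allotetraploid assignment of script 03 (re-run here so the
# script is self-contained), folds the inferred MUL tree by joining the
# subgenome leaves, collapses weakly supported branches at PP < 0.7 (the
# undated MDC consensus carries no posteriors, so an annotated example tree
# demonstrates the collapse and the merged age interval), and writes the
# network edge list and extended newick.

suppressMessages(library(polycoal))
dir.create("results", showWarnings = FALSE)

gt <- simulate_gene_trees(
  simulate_history(preset_config("allotetraploid", rng_seed = 303)),
  n_trees = 100, plastid = NULL)
nuc <- paste0("L", 1:5)
fit <- hill_climb_assignment(gt$samples[nuc], truth_lineage_map(gt, nuc),
                             seed = 303)
poly <- split(paste0("P1.sg", 1:2), rep("P1", 2))
net <- join_subgenome_leaves(fit$species_tree, poly)
cat("inferred MUL tree:", ape::write.tree(fit$species_tree), "\n")
print(net)
cat("extended newick:", write_enewick(net), "\n")

el <- igraph::as_data_frame(net$graph)
write.table(el, "results/04_network_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(write_enewick(net), "results/04_network.enwk")

# dated example: a MUL tree annotated with posteriors and 95% HPD node ages
# (the dialect written by Bayesian dating tools); the polyploid's age is the
# covering interval of its subgenome divergence HPDs
txt <- paste0(
  "(((P1.sg1:1.2,spA:1.2)[&posterior=0.97,height_95%_HPD={0.59,1.8}]:2.3,",
  "spB:3.5)[&posterior=0.64]:0.89,",
  "((P1.sg2:1.7,spC:1.7)[&posterior=0.92,height_95%_HPD={1.2,2.87}]:1.5,",
  "spD:3.2)[&posterior=0.99]:1.19)[&posterior=1.0];")
mul <- read_annotated_tree(txt)
col <- collapse_low_support(mul, 0.7)
cat("\ndated MUL tree, PP<0.7 collapsed:", ape::write.tree(col), "\n")
age <- polyploid_age(mul, c("P1.sg1", "P1.sg2"))
cat(sprintf("merged 95%% HPD age interval of P1: %.2f-%.2f Ma\n",
            age[1], age[2]))
writeLines(sprintf("P1\t%.3f\t%.3f", age[1], age[2]),
           "results/04_polyploid_ages.tsv")
cat("wrote results/04_network_edges.tsv, results/04_network.enwk, results/04_polyploid_ages.tsv\n")
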