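#!/usr/bin/env Rscript
# Disease interactome (panel genes + first-degree neighbours), DEG overlap,
# reduction to the disease-DEG neighbourhood, and dual-centrality (degree +
# bottleneck) hub prioritization.
# Writes results/disease_subnetwork.tsv and results/centrality.tsv.

library(adipolink)

net <- read_network("results/data/network.tsv")
panel <- read_gene_list("results/data/disease_genes.txt")
degs <- read.delim("results/degs.tsv")
lipo <- read.delim("results/disease_degs.tsv")

subnet <- disease_neighborhood(net, panel)
ov <- overlap_stats(degs$gene, subnet)
seeds <- intersect(lipo$gene, igraph::V(subnet)$name)
reduced <- reduce_to_overlap_neighborhood(subnet, seeds)
prio <- prioritize_union(reduced, k = 100)

write_network(subnet, "results/disease_subnetwork.tsv")
write.table(prio$centrality, "results/centrality.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("interactome: %d nodes / %d edges (seed attrition %d)\n",
            igraph::vcount(subnet), igraph::ecount(subnet),
            attr(subnet, "seed_attrition")))
cat(sprintf("DEG overlap: %d of %d DEGs (%.1f%%) inside the interactome\n",
            ov$n_overlap, nrow(degs), ov$pct_of_degs))
cat(sprintf("reduced disease-DEG neighbourhood: %d nodes\n",
            igraph::vcount(reduced)))
cat(sprintf("prioritized hub union (top 100 by degree U top 100 by bottleneck): %d genes\n",
            length(prio$nodes)))
writeLines(prio$nodes, "results/prioritized_genes.txt")
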