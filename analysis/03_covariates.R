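#!/usr/bin/env Rscript
# Step 3: the three evolutionary-constraint proxies.
#
# PPI node degree (after identifier cleanup and simplification of the
# interaction graph), tissue-specificity tau over the 24 male-applicable
# tissues, and GO-slim biological-process multifunctionality with the
# immune-system-process flag.

suppressPackageStartupMessages(library(testevol))

fix <- function(f) file.path("results/fixtures", f)
rates <- load_ortholog_rates(fix("ortholog_rates.tsv"))

raw <- read_edge_list(fix("ppi_edges.tsv"), fix("id_mapping.tsv"))
net <- build_network(normalize_identifiers(raw))
degrees <- gene_degree_table(net, rates$gene_id)
cat("Network:", igraph::vcount(net$graph), "nodes,",
    igraph::ecount(net$graph), "edges\n")
cat("Genes not in network:", length(attr(degrees, "ledger")), "\n")

fpkm <- read_fpkm(fix("expression_fpkm.tsv"))
taus <- tau_table(fpkm)  # default: excludes ovary, placenta, uterus
cat("tau computed for", sum(!is.na(taus$tau)), "genes over",
    ncol(select_tissues(fpkm)), "tissues; median tau =",
    round(median(taus$tau, na.rm = TRUE), 3), "\n")

go_full <- read_obo(fix("go_toy.obo"))
go_slim <- read_obo(fix("go_slim_toy.obo"))
gof <- go_profile(read_gaf(fix("go_annotations.gaf")), go_full,
                  intersect(go_slim$terms, go_full$terms))
cat("Multifunctionality: median", median(gof$multifunctionality, na.rm = TRUE),
    "; immunity-flagged proteins:", sum(gof$immunity), "\n")

dir.create("results/covariates", recursive = TRUE, showWarnings = FALSE)
write.table(degrees, "results/covariates/node_degree.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(taus, "results/covariates/tau.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(gof, "results/covariates/go_multifunctionality.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
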