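# toy ontologies shared across tests, written once per session
toy_mp <- local({
  p <- tempfile(fileext = ".obo")
  write_toy_mp_obo(p)
  read_obo(p)
})

toy_go <- local({
  pf <- tempfile(fileext = ".obo")
  ps <- tempfile(fileext = ".obo")
  write_toy_go_obo(pf, ps)
  list(full = read_obo(pf), slim = read_obo(ps))
})
toy_slim_ids <- intersect(toy_go$slim$terms, toy_go$full$terms)

# brute-force reachability oracle over an obo_graph, independent of the
# BFS in the package: repeated relational closure on the parent matrix
closure_oracle <- function(g, term, direction = c("up", "down")) {
  direction <- match.arg(direction)
  n <- length(g$terms)
  adj <- matrix(FALSE, n, n, dimnames = list(g$terms, g$terms))
  for (t in g$terms) for (p in g$parents[[t]]) adj[t, p] <- TRUE
  if (direction == "down") adj <- t(adj)
  reach <- adj
  repeat {
    nxt <- (reach %*% adj) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  c(term, g$terms[reach[term, ]])
}

make_allele_row <- function(gene, allele = paste0(gene, "a1"),
                            type = "Targeted", attrs = "Null/knockout",
                            n_tg = 1L, zyg = "homozygous", sex = "both",
                            mp = "MP:0002000", flags = "") {
  data.frame(gene_id = gene, allele_id = allele, allele_type = type,
             allele_attributes = I(list(strsplit(attrs, ",")[[1]])),
             n_targeted_genes = n_tg, zygosity = zyg, sex = sex,
             mp_terms = I(list(strsplit(mp, ",")[[1]])),
             curation_flags = I(list(Filter(nzchar, strsplit(flags, ",")[[1]]))),
             stringsAsFactors = FALSE)
}

toy_alleles <- function(...) do.call(rbind, list(...))

# small simulation shared by several files (cheap, deterministic)
small_sim <- function(seed = 11L, excluded = TRUE) {
  simulation_config(
    n_genes = 60L,
    category_sizes = c(male_subinfertility = 10L, lethality = 30L,
                       nonessential = 20L),
    excluded_counts = if (excluded)
      c(double_essentiality = 3L, fertile_despite_abnormality = 1L,
        decreased_litter_size_only = 1L, requires_extra_manipulation = 1L,
        special_case_exclude = 1L) else integer(0),
    seed = seed)
}
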