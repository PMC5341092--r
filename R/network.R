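#' Read a raw PPI edge list and its identifier-mapping table
#'
#' @param edges_path 2-column TSV of protein accessions (`a`, `b`).
#' @param mapping_path TSV with columns `accession`, `status`
#'   (current/deleted/renamed), `replacement`, `gene_ids` (comma-separated),
#'   `biotype`, `reviewed` (TRUE/FALSE), and optional `hgnc_protein_coding`.
#' @return list `edges` (data.frame a, b), `mapping` (data.frame).
#' @export
read_edge_list <- function(edges_path, mapping_path) {
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  names(edges)[1:2] <- c("a", "b")
  mapping <- utils::read.delim(mapping_path, stringsAsFactors = FALSE)
  if (is.null(mapping$hgnc_protein_coding)) mapping$hgnc_protein_coding <- FALSE
  mapping$reviewed <- as.logical(mapping$reviewed)
  mapping$hgnc_protein_coding <- as.logical(mapping$hgnc_protein_coding)
  list(edges = edges, mapping = mapping)
}

#' Normalize protein identifiers in a raw edge list
#'
#' Cleanup mirrors the network-construction rules: accessions deleted from
#' the reference database are removed together with their edges; renamed
#' accessions are replaced by their replacement; products of
#' non-protein-coding genes are removed unless rescued by the
#' `hgnc_protein_coding` override; unmapped accessions are removed; an
#' unreviewed (TrEMBL-like) accession whose gene also maps to a reviewed
#' (Swiss-Prot-like) accession is merged into the reviewed one, its edges
#' inherited. Accessions mapping to several genes stay in the network but
#' are marked unusable for gene-level analysis.
#'
#' @param raw list as from [read_edge_list()].
#' @return list `edges`, `node_gene` (named character: accession -> gene id,
#'   `NA` for multi-gene or gene-less nodes), `multi_gene` (accessions with
#'   several gene ids), `removed` (data.frame accession, reason).
#' @export
normalize_identifiers <- function(raw) {
  edges <- raw$edges
  map <- raw$mapping
  if (anyDuplicated(map$accession)) {
    dup <- map$accession[duplicated(map$accession)]
    st <- split(map$status, map$accession)
    bad <- names(st)[vapply(st, function(s) length(unique(s)) > 1, TRUE)]
    if (length(bad))
      stop("conflicting mapping status for accession(s): ",
           paste(bad, collapse = ", "))
    map <- map[!duplicated(map$accession), , drop = FALSE]
  }
  rownames(map) <- map$accession
  removed <- data.frame(accession = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop_nodes <- function(edges, acc, reason) {
    if (length(acc)) {
      removed <<- rbind(removed, data.frame(accession = acc, reason = reason,
                                            stringsAsFactors = FALSE))
      edges <- edges[!(edges$a %in% acc | edges$b %in% acc), , drop = FALSE]
    }
    edges
  }
  # unmapped
  present <- unique(c(edges$a, edges$b))
  edges <- drop_nodes(edges, setdiff(present, map$accession), "unmapped")
  # deleted
  edges <- drop_nodes(edges, map$accession[map$status == "deleted"], "deleted")
  # renamed -> replacement (replacement must itself be mapped)
  ren <- map[map$status == "renamed", , drop = FALSE]
  if (nrow(ren)) {
    lut <- stats::setNames(ren$replacement, ren$accession)
    edges$a <- ifelse(edges$a %in% names(lut), lut[edges$a], edges$a)
    edges$b <- ifelse(edges$b %in% names(lut), lut[edges$b], edges$b)
    present <- unique(c(edges$a, edges$b))
    edges <- drop_nodes(edges, setdiff(present, map$accession),
                        "renamed_to_unmapped")
  }
  # non-protein-coding without override
  npc <- map$accession[map$biotype != "protein_coding" & !map$hgnc_protein_coding]
  edges <- drop_nodes(edges, npc, "non_protein_coding")
  # gene id sets
  gsets <- split_field(map$gene_ids)
  names(gsets) <- map$accession
  # merge unreviewed into a reviewed accession of the same gene
  present <- unique(c(edges$a, edges$b))
  gene_of <- function(acc) gsets[[acc]]
  reviewed_by_gene <- list()
  for (acc in present) {
    if (isTRUE(map[acc, "reviewed"])) {
      gs <- gene_of(acc)
      if (length(gs) == 1)
        reviewed_by_gene[[gs]] <- sort(c(reviewed_by_gene[[gs]], acc))
    }
  }
  merge_lut <- character()
  for (acc in present) {
    if (!isTRUE(map[acc, "reviewed"])) {
      gs <- gene_of(acc)
      if (length(gs) == 1 && !is.null(reviewed_by_gene[[gs]])) {
        merge_lut[acc] <- reviewed_by_gene[[gs]][1]
        removed <- rbind(removed, data.frame(
          accession = acc, reason = "merged_into_reviewed",
          stringsAsFactors = FALSE))
      }
    }
  }
  if (length(merge_lut)) {
    edges$a <- ifelse(edges$a %in% names(merge_lut), merge_lut[edges$a], edges$a)
    edges$b <- ifelse(edges$b %in% names(merge_lut), merge_lut[edges$b], edges$b)
  }
  present <- unique(c(edges$a, edges$b))
  multi <- present[vapply(present, function(a) length(gsets[[a]]) > 1, TRUE)]
  node_gene <- vapply(present, function(a) {
    gs <- gsets[[a]]
    if (length(gs) == 1) gs else NA_character_
  }, "")
  list(edges = edges, node_gene = node_gene, multi_gene = multi,
       removed = removed)
}

#' Build a simple undirected interaction network
#'
#' Duplicate edges (including merge-inherited parallel edges and reversed
#' orientations) are collapsed and self-interactions removed.
#'
#' @param norm list as returned by [normalize_identifiers()].
#' @return list of class `ppi_network`: `graph` (igraph), `node_gene`,
#'   `multi_gene`.
#' @export
build_network <- function(norm) {
  nodes <- unique(c(norm$edges$a, norm$edges$b, names(norm$node_gene)))
  g <- igraph::graph_from_data_frame(norm$edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, node_gene = norm$node_gene,
                 multi_gene = norm$multi_gene),
            class = "ppi_network")
}

#' Node degrees of an interaction network
#' @param net a `ppi_network`.
#' @return named integer vector (accession -> degree).
#' @export
node_degrees <- function(net) igraph::degree(net$graph)

#' Resolve a gene's representative accession and node degree
#'
#' When a gene maps to several accessions in the network, the one with
#' highest node degree is chosen; ties break to the lexicographically
#' smallest accession. Accessions carrying several gene ids are never
#' selectable. A gene with no accession in the network returns `NULL`
#' (it leaves the dataset; counted upstream as "not contained in the PPI
#' network").
#'
#' @param net a `ppi_network`.
#' @param gene_id gene identifier.
#' @return list `accession`, `degree`, or `NULL` if absent.
#' @export
resolve_gene_degree <- function(net, gene_id) {
  acc <- names(net$node_gene)[!is.na(net$node_gene) & net$node_gene == gene_id]
  acc <- setdiff(acc, net$multi_gene)
  acc <- intersect(acc, igraph::V(net$graph)$name)
  if (!length(acc)) return(NULL)
  degs <- igraph::degree(net$graph, v = acc)
  best <- max(degs)
  cand <- sort(acc[degs == best])
  list(accession = cand[1], degree = unname(best))
}

#' Per-gene degree table
#'
#' @param net a `ppi_network`.
#' @param genes gene ids to resolve.
#' @return data.frame `gene_id`, `accession`, `degree`; genes absent from
#'   the network are listed in attribute `ledger`.
#' @export
gene_degree_table <- function(net, genes) {
  res <- lapply(genes, function(g) resolve_gene_degree(net, g))
  found <- !vapply(res, is.null, TRUE)
  out <- data.frame(
    gene_id = genes[found],
    accession = vapply(res[found], `[[`, "", "accession"),
    degree = vapply(res[found], function(r) as.numeric(r$degree), 1),
    stringsAsFactors = FALSE)
  attr(out, "ledger") <- genes[!found]
  out
}
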