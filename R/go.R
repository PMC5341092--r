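#' Read a GAF 2.x annotation file
#'
#' Keeps the columns the pipeline uses: DB object id (column 2), GO id
#' (column 5), evidence code (column 7) and aspect (column 9). Comment lines
#' (`!`) are skipped.
#'
#' @param path GAF file path.
#' @return data.frame `protein`, `go_id`, `evidence`, `aspect`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(protein = character(), go_id = character(),
                      evidence = character(), aspect = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  grab <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else "", "")
  data.frame(protein = grab(2), go_id = grab(5), evidence = grab(7),
             aspect = grab(9), stringsAsFactors = FALSE)
}

#' Map a GO term to its minimal covering slim terms
#'
#' map2slim semantics: among the slim terms in the ancestor-or-self closure
#' of the query (via is_a and part_of), keep those with no other slim term
#' strictly between themselves and the query — i.e. the minimal elements of
#' the slim ancestors under the ancestor partial order. A term that is itself
#' in the slim maps to itself.
#'
#' @param term GO id; unknown terms are skipped with a warning.
#' @param graph full ontology as an `obo_graph`.
#' @param slim character vector of slim term ids.
#' @return character vector of slim ids (possibly empty).
#' @export
map_to_slim <- function(term, graph, slim) {
  if (!term %in% graph$terms) {
    warning("unknown GO term skipped: ", term)
    return(character())
  }
  if (term %in% slim) return(term)
  anc <- obo_ancestors(graph, term, include_self = TRUE)
  cand <- intersect(anc, slim)
  if (!length(cand)) return(character())
  keep <- vapply(cand, function(a) {
    others <- setdiff(cand, a)
    !any(vapply(others, function(s)
      a %in% obo_ancestors(graph, s, include_self = FALSE), TRUE))
  }, TRUE)
  cand[keep]
}

# usable biological-process annotations for one protein:
# aspect P, minus the uninformative root annotation GO:0008150 + ND
usable_bp <- function(ann) {
  bp <- ann[ann$aspect == "P", , drop = FALSE]
  bp[!(bp$go_id == "GO:0008150" & bp$evidence == "ND"), , drop = FALSE]
}

#' Multifunctionality: nonredundant GO-slim biological processes
#'
#' The size of the union of slim classes over all usable biological-process
#' annotations of a protein. The root term GO:0008150 annotated with evidence
#' code ND marks absence of information and is ignored; a protein left with
#' no usable BP annotation has no multifunctionality value (`NA`) and is
#' excluded upstream.
#'
#' @param ann annotation data.frame (as from [read_gaf()]) for one protein.
#' @param graph full GO as an `obo_graph`.
#' @param slim slim term ids.
#' @return integer count, or `NA_integer_` when no usable annotation exists.
#' @export
count_multifunctionality <- function(ann, graph, slim) {
  bp <- usable_bp(ann)
  if (nrow(bp) == 0) return(NA_integer_)
  slims <- unique(unlist(lapply(unique(bp$go_id), map_to_slim,
                                graph = graph, slim = slim)))
  length(slims)
}

#' Immunity involvement flag
#'
#' `TRUE` iff any usable biological-process annotation of the protein maps
#' into the slim class "immune system process" (GO:0002376).
#'
#' @inheritParams count_multifunctionality
#' @param immunity_term slim class id (default `"GO:0002376"`).
#' @return logical.
#' @export
flag_immunity <- function(ann, graph, slim, immunity_term = "GO:0002376") {
  bp <- usable_bp(ann)
  if (nrow(bp) == 0) return(FALSE)
  slims <- unique(unlist(lapply(unique(bp$go_id), map_to_slim,
                                graph = graph, slim = slim)))
  immunity_term %in% slims
}

#' Per-protein multifunctionality and immunity flags
#'
#' @param ann annotation data.frame covering many proteins.
#' @param graph full GO as an `obo_graph`.
#' @param slim slim term ids.
#' @return data.frame `gene_id`, `multifunctionality`, `immunity`, with
#'   attribute `ledger` naming proteins lacking usable BP annotation.
#' @export
go_profile <- function(ann, graph, slim) {
  prots <- unique(ann$protein)
  rows <- lapply(prots, function(p) {
    sub <- ann[ann$protein == p, , drop = FALSE]
    data.frame(gene_id = p,
               multifunctionality = count_multifunctionality(sub, graph, slim),
               immunity = flag_immunity(sub, graph, slim),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ledger") <- out$gene_id[is.na(out$multifunctionality)]
  out
}
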