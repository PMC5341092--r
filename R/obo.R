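#' Minimal OBO ontology reader
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 flat file, keeping `id`, `name`,
#' `namespace`, `is_a` parents and `relationship: part_of` parents; obsolete
#' terms are dropped. This covers the ontology structure the pipeline
#' traverses (the Mammalian Phenotype ontology uses is_a only; GO slim
#' mapping traverses is_a and part_of).
#'
#' @param path OBO file path.
#' @return object of class `obo_graph`: list with `terms` (character),
#'   `parents` (named list of parent id vectors), `name`, `namespace`
#'   (named character vectors).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character()
  parents <- list()
  names_v <- character()
  ns_v <- character()
  cur <- NULL
  cur_parents <- character()
  cur_name <- NA_character_
  cur_ns <- NA_character_
  obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms[length(terms) + 1L] <<- cur
      parents[[cur]] <<- unique(cur_parents)
      names_v[cur] <<- cur_name
      ns_v[cur] <<- cur_ns
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur_parents <- character()
      cur_name <- NA_character_; cur_ns <- NA_character_
      obsolete <- FALSE; in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur_name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur_ns <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_a:", ln))
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^relationship:\\s*part_of\\s", ln))
      cur_parents <- c(cur_parents,
                       trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
    else if (grepl("^is_obsolete:\\s*true", ln)) obsolete <- TRUE
  }
  flush()
  # drop dangling parent references
  parents <- lapply(parents, function(p) p[p %in% terms])
  structure(list(terms = terms, parents = parents,
                 name = names_v, namespace = ns_v),
            class = "obo_graph")
}

# children map (inverse of parents), built on demand
obo_children <- function(g) {
  ch <- lapply(stats::setNames(vector("list", length(g$terms)), g$terms),
               function(x) character())
  for (t in g$terms) for (p in g$parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  ch
}

#' Ancestors of a term (transitive is_a / part_of closure)
#'
#' @param g an `obo_graph`.
#' @param term term id.
#' @param include_self include the term itself (default `TRUE`).
#' @return character vector of term ids.
#' @export
obo_ancestors <- function(g, term, include_self = TRUE) {
  if (!term %in% g$terms) stop("unknown term: ", term)
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(g$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (include_self) unique(c(term, seen)) else setdiff(seen, term)
}

#' Descendant subtree of a term (root plus all transitive descendants)
#'
#' @param g an `obo_graph`.
#' @param root term id; unknown roots are an error.
#' @return character vector: root and every transitive descendant.
#' @export
obo_subtree <- function(g, root) {
  if (!root %in% g$terms) stop("unknown root term: ", root)
  ch <- obo_children(g)
  seen <- root
  frontier <- root
  while (length(frontier)) {
    nxt <- unique(unlist(ch[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}
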