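#' Load a table of pairwise substitution-rate estimates
#'
#' Keeps rows for 1-to-1 human-mouse orthologues whose dN/dS estimate is
#' present and not masked for synonymous-site saturation; everything else is
#' counted in the attached ledger. Rows with malformed numeric fields are
#' rejected with a warning.
#'
#' @param path TSV with columns `gene_id`, `homology_type`, `dn`, `ds`,
#'   `dnds`, `masked`, and optionally `chromosome`.
#' @return data.frame of surviving rows, attribute `ledger` (data.frame
#'   `reason`, `count`).
#' @export
load_ortholog_rates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("dn", "ds", "dnds")) {
    if (!is.numeric(df[[col]])) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$masked <- as.logical(df$masked)
  malformed <- is.na(df$masked) |
    (is.na(df$dn) & is.na(df$ds) & is.na(df$dnds) &
       df$homology_type == "malformed")
  bad_numeric <- rowSums(cbind(is.na(df$dn), is.na(df$ds))) > 0 &
    !is.na(df$dnds)
  malformed <- malformed | bad_numeric
  if (any(malformed)) {
    warning(sum(malformed), " malformed rate row(s) rejected")
    df <- df[!malformed, , drop = FALSE]
  }
  ledger <- data.frame(reason = character(), count = integer(),
                       stringsAsFactors = FALSE)
  note <- function(reason, n) {
    if (n > 0) ledger <<- rbind(ledger, data.frame(reason = reason, count = n,
                                                   stringsAsFactors = FALSE))
  }
  keep <- df$homology_type %in% c("ortholog_one2one", "1-to-1")
  note("not_one2one_orthologue", sum(!keep))
  df <- df[keep, , drop = FALSE]
  sat <- df$masked
  note("dS_saturation_masked", sum(sat))
  df <- df[!sat, , drop = FALSE]
  missing <- is.na(df$dnds)
  note("no_dnds_estimate", sum(missing))
  df <- df[!missing, , drop = FALSE]
  attr(df, "ledger") <- ledger
  df
}

new_ledger <- function() {
  data.frame(stage = character(), reason = character(), count = integer(),
             gene_ids = character(), stringsAsFactors = FALSE)
}

ledger_add <- function(ledger, stage, reason, ids) {
  if (length(ids) == 0) return(ledger)
  rbind(ledger, data.frame(stage = stage, reason = reason,
                           count = length(ids),
                           gene_ids = paste(ids, collapse = ","),
                           stringsAsFactors = FALSE))
}

#' Assemble the analysis table
#'
#' Inner-joins the covariate layers on the gene identifier and applies the
#' eligibility filters as staged exclusions: duplicate-identifier collapse,
#' missing dN/dS, absence from the PPI network, missing knockout phenotype
#' data, missing GO biological-process data, undefined tau, and finally the
#' category-level exclusions from the classifier. The ledger accounts for
#' every dropped gene, so that the record count plus the ledger counts equal
#' the size of the input universe.
#'
#' @param rates data.frame from [load_ortholog_rates()] (defines the gene
#'   universe; may carry `chromosome`).
#' @param degrees data.frame `gene_id`, `degree` (e.g. from
#'   [gene_degree_table()]).
#' @param tau data.frame `gene_id`, `tau` (e.g. from [tau_table()]).
#' @param go data.frame `gene_id`, `multifunctionality`, `immunity` (e.g.
#'   from [go_profile()]).
#' @param categories data.frame `gene_id`, `category`, `exclusion_reason`
#'   (from [categorize_dataset()]).
#' @return list: `records` data.frame (one row per included gene), `ledger`.
#' @export
assemble_dataset <- function(rates, degrees, tau, go, categories) {
  ledger <- new_ledger()
  # duplicate collapse: identical duplicates collapse to the first
  # occurrence; conflicting duplicates are an error
  if (anyDuplicated(rates$gene_id)) {
    dups <- unique(rates$gene_id[duplicated(rates$gene_id)])
    for (g in dups) {
      sub <- rates[rates$gene_id == g, c("dn", "ds", "dnds"), drop = FALSE]
      if (nrow(unique(sub)) > 1)
        stop("conflicting duplicate rate records for gene ", g)
    }
    ledger <- ledger_add(ledger, "duplicate_collapse", "duplicate_gene_id", dups)
    rates <- rates[!duplicated(rates$gene_id), , drop = FALSE]
  }
  universe <- rates$gene_id
  cur <- rates
  drop_stage <- function(cur, keep, stage, reason) {
    ledger <<- ledger_add(ledger, stage, reason, cur$gene_id[!keep])
    cur[keep, , drop = FALSE]
  }
  cur <- drop_stage(cur, !is.na(cur$dnds), "rates", "no_dnds_estimate")
  cur <- drop_stage(cur, cur$gene_id %in% degrees$gene_id,
                    "network", "not_in_ppi_network")
  has_ko <- cur$gene_id %in% categories$gene_id[categories$category != "no_data"]
  cur <- drop_stage(cur, has_ko, "phenotype", "no_ko_data")
  ok_go <- cur$gene_id %in% go$gene_id[!is.na(go$multifunctionality)]
  cur <- drop_stage(cur, ok_go, "go", "no_go_bp_data")
  ok_tau <- cur$gene_id %in% tau$gene_id[!is.na(tau$tau)]
  cur <- drop_stage(cur, ok_tau, "expression", "tau_undefined")
  # category exclusions, one ledger row per reason
  cat_map <- categories[match(cur$gene_id, categories$gene_id), ]
  excl <- cat_map$category == "excluded"
  if (any(excl)) {
    for (r in unique(cat_map$exclusion_reason[excl])) {
      ids <- cur$gene_id[excl & cat_map$exclusion_reason == r]
      ledger <- ledger_add(ledger, "category", r, ids)
    }
    cur <- cur[!excl, , drop = FALSE]
    cat_map <- cat_map[!excl, , drop = FALSE]
  }
  records <- data.frame(
    gene_id = cur$gene_id,
    category = cat_map$category,
    dn = cur$dn, ds = cur$ds, dnds = cur$dnds,
    degree = degrees$degree[match(cur$gene_id, degrees$gene_id)],
    tau = tau$tau[match(cur$gene_id, tau$gene_id)],
    multifunctionality =
      go$multifunctionality[match(cur$gene_id, go$gene_id)],
    immunity = go$immunity[match(cur$gene_id, go$gene_id)],
    x_linked = if (!is.null(cur$chromosome)) cur$chromosome == "X" else NA,
    stringsAsFactors = FALSE)
  stopifnot(nrow(records) + sum(ledger$count) == length(universe) +
              sum(ledger$count[ledger$stage == "duplicate_collapse"]))
  bad <- records$ds > 0 & abs(records$dnds - records$dn / records$ds) > 1e-6
  if (any(bad, na.rm = TRUE))
    warning("dN/dS inconsistent with dN and dS for ",
            sum(bad, na.rm = TRUE), " gene(s)")
  list(records = records, ledger = ledger)
}
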