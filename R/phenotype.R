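#' Classifier configuration
#'
#' MP term roots and single terms driving the essentiality classification.
#' Lethality evidence is any term inside the subtrees of "preweaning
#' lethality" (MP:0010770) or "lethality at weaning" (MP:0008569), or one of
#' four viability terms used as single ids (complete lethality MP:0011400,
#' partial lethality MP:0010831, decreased survivor rate MP:0008770,
#' abnormal survival MP:0010769) when literature curation confirmed
#' prepubertal death at sub-Mendelian ratios. Male sub-/infertility evidence
#' is male infertility (MP:0001925) or reduced male fertility (MP:0001922),
#' or a configured further male-reproductive term confirmed by curation.
#'
#' @param lethality_roots subtree roots giving lethality evidence.
#' @param lethality_singles single terms needing curation confirmation.
#' @param male_terms terms giving direct sub-/infertility evidence.
#' @param other_male_terms further male-reproductive terms, each requiring
#'   the `confirmed_male_subinfertility` curation flag; user-extensible.
#' @param litter_term the decreased-litter-size phenotype id.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(
    lethality_roots = c("MP:0010770", "MP:0008569"),
    lethality_singles = c("MP:0011400", "MP:0010831", "MP:0008770", "MP:0010769"),
    male_terms = c("MP:0001925", "MP:0001922"),
    other_male_terms = c("MP:0001924"),
    litter_term = "MP:0001935") {
  structure(list(lethality_roots = lethality_roots,
                 lethality_singles = lethality_singles,
                 male_terms = male_terms,
                 other_male_terms = other_male_terms,
                 litter_term = litter_term),
            class = "classifier_config")
}

split_field <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), "[,;|] *")
  lapply(out, function(v) v[nzchar(v)])
}

#' Read a knockout-allele phenotype table
#'
#' TSV with columns `gene_id`, `allele_id`, `allele_type`,
#' `allele_attributes`, `n_targeted_genes`, `zygosity`, `sex`, `mp_terms`,
#' `curation_flags`; the set-valued columns are comma-separated.
#'
#' @param path TSV path.
#' @return data.frame with list columns `mp_terms`, `curation_flags`,
#'   `allele_attributes`.
#' @export
read_allele_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$n_targeted_genes <- as.integer(df$n_targeted_genes)
  df$mp_terms <- split_field(df$mp_terms)
  df$curation_flags <- split_field(df$curation_flags)
  df$allele_attributes <- split_field(df$allele_attributes)
  df
}

#' Allele inclusion filter
#'
#' Keeps targeted null alleles affecting a single gene: `allele_type ==
#' "Targeted"`, attribute set containing `"Null/knockout"`, one targeted
#' gene, and zygosity homozygous — or hemizygous when the gene is X-linked
#' (male hemizygous knockouts).
#'
#' @param rows allele data.frame as from [read_allele_table()].
#' @param x_linked character vector of X-linked gene ids.
#' @return the surviving rows (possibly zero).
#' @export
filter_alleles <- function(rows, x_linked = character()) {
  if (nrow(rows) == 0) return(rows)
  has_null <- vapply(rows$allele_attributes,
                     function(a) "Null/knockout" %in% a, TRUE)
  keep <- rows$allele_type == "Targeted" &
    has_null &
    rows$n_targeted_genes == 1L &
    (rows$zygosity == "homozygous" |
       (rows$zygosity == "hemizygous" & rows$gene_id %in% x_linked))
  rows[keep, , drop = FALSE]
}

#' Descendant subtree of an MP term
#'
#' Root plus all transitive is_a descendants; thin wrapper over
#' [obo_subtree()] for the Mammalian Phenotype ontology.
#'
#' @param ont MP ontology as an `obo_graph`.
#' @param root MP id; unknown roots are an error.
#' @return character vector of MP ids.
#' @export
mp_subtree <- function(ont, root) obo_subtree(ont, root)

# evidence + exclusion assessment for the filtered alleles of one gene
assess_gene <- function(gene_id, rows, leth_set, cfg) {
  n <- nrow(rows)
  ev <- list()
  leth_any <- FALSE
  male_any <- FALSE
  male_assoc_any <- FALSE
  litter_flagged <- FALSE
  excl_flags <- character()
  male_related <- c(cfg$male_terms, cfg$other_male_terms, cfg$litter_term)
  for (i in seq_len(n)) {
    mp <- rows$mp_terms[[i]]
    fl <- rows$curation_flags[[i]]
    female <- "female_specific_phenotype" %in% fl
    if (any(mp %in% leth_set)) {
      leth_any <- TRUE
      ev[[length(ev) + 1L]] <- c(rows$allele_id[i], "lethality_subtree")
    }
    if (any(mp %in% cfg$lethality_singles) && "confirmed_prepubertal_death" %in% fl) {
      leth_any <- TRUE
      ev[[length(ev) + 1L]] <- c(rows$allele_id[i], "lethality_single_confirmed")
    }
    if (!female) {
      if (any(mp %in% cfg$male_terms)) {
        male_any <- TRUE
        ev[[length(ev) + 1L]] <- c(rows$allele_id[i], "male_subinfertility_term")
      }
      if (any(mp %in% cfg$other_male_terms) && "confirmed_male_subinfertility" %in% fl) {
        male_any <- TRUE
        ev[[length(ev) + 1L]] <- c(rows$allele_id[i], "male_repro_confirmed")
      }
      if (any(mp %in% male_related)) male_assoc_any <- TRUE
    }
    if (cfg$litter_term %in% mp &&
        "decreased_litter_size_only_homozygous_pairs" %in% fl)
      litter_flagged <- TRUE
    excl_flags <- c(excl_flags, intersect(
      fl, c("fertile_despite_abnormality", "fertility_increasing",
            "requires_extra_manipulation", "special_case_exclude")))
  }
  list(leth = leth_any, male = male_any, male_assoc = male_assoc_any,
       litter = litter_flagged, flags = unique(excl_flags), evidence = ev)
}

#' Classify one gene's essentiality from its filtered knockout alleles
#'
#' Exclusions take precedence over classification, in this fixed order:
#' double essentiality (lethality evidence together with any male
#' reproductive association, even via different alleles), unclear or fertile
#' status (curation flags `fertile_despite_abnormality`,
#' `fertility_increasing`), decreased litter size as the only fertility link,
#' phenotypes requiring manipulation of additional factors, and special-case
#' removals. Female-specific phenotype annotations never create
#' sub-/infertility evidence but do not by themselves exclude a gene.
#' A gene with phenotypic null alleles and no evidence is nonessential;
#' a gene with no surviving alleles has no data.
#'
#' @param gene_id gene identifier.
#' @param rows filtered allele rows for this gene.
#' @param ont MP ontology (`obo_graph`).
#' @param cfg a [classifier_config()].
#' @return list: `gene_id`, `category` (one of `"lethality"`,
#'   `"male_subinfertility"`, `"nonessential"`, `"excluded"`, `"no_data"`),
#'   `evidence` (list of allele id / rule pairs), `exclusion_reason`.
#' @export
classify_gene <- function(gene_id, rows, ont, cfg = classifier_config()) {
  if (nrow(rows) == 0)
    return(list(gene_id = gene_id, category = "no_data",
                evidence = list(), exclusion_reason = "no_phenotype_data"))
  leth_set <- unique(unlist(lapply(cfg$lethality_roots, mp_subtree, ont = ont)))
  a <- assess_gene(gene_id, rows, leth_set, cfg)
  reason <- NA_character_
  if (a$leth && a$male_assoc) reason <- "double_essentiality"
  else if (any(a$flags %in% c("fertile_despite_abnormality", "fertility_increasing")))
    reason <- "unclear_or_fertile"
  else if (!a$male && a$litter) reason <- "decreased_litter_size_only"
  else if ("requires_extra_manipulation" %in% a$flags)
    reason <- "requires_extra_manipulation"
  else if ("special_case_exclude" %in% a$flags) reason <- "special_case_exclude"
  if (!is.na(reason))
    return(list(gene_id = gene_id, category = "excluded",
                evidence = a$evidence, exclusion_reason = reason))
  category <- if (a$male) "male_subinfertility"
              else if (a$leth) "lethality"
              else "nonessential"
  list(gene_id = gene_id, category = category, evidence = a$evidence,
       exclusion_reason = NA_character_)
}

#' Classify a whole allele table
#'
#' Applies [filter_alleles()] then [classify_gene()] per gene and tallies
#' every exclusion reason into a ledger. Genes present in the input whose
#' alleles are all removed by the filter are reported as `no_data` in the
#' ledger (they leave the dataset, distinct from nonessential).
#'
#' @param rows allele data.frame as from [read_allele_table()].
#' @param ont MP ontology (`obo_graph`).
#' @param cfg a [classifier_config()].
#' @param x_linked X-linked gene ids (hemizygous acceptance).
#' @return list: `assignments` data.frame (`gene_id`, `category`,
#'   `exclusion_reason`), `ledger` data.frame (`reason`, `count`).
#' @export
categorize_dataset <- function(rows, ont, cfg = classifier_config(),
                               x_linked = character()) {
  genes <- unique(rows$gene_id)
  kept <- filter_alleles(rows, x_linked)
  res <- lapply(genes, function(g)
    classify_gene(g, kept[kept$gene_id == g, , drop = FALSE], ont, cfg))
  assignments <- data.frame(
    gene_id = vapply(res, `[[`, "", "gene_id"),
    category = vapply(res, `[[`, "", "category"),
    exclusion_reason = vapply(res, `[[`, "", "exclusion_reason"),
    stringsAsFactors = FALSE)
  reasons <- assignments$exclusion_reason[!is.na(assignments$exclusion_reason)]
  if (length(reasons)) {
    tab <- table(reasons)
    ledger <- data.frame(reason = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE)
  } else {
    ledger <- data.frame(reason = character(), count = integer(),
                         stringsAsFactors = FALSE)
  }
  list(assignments = assignments, ledger = ledger)
}
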