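#' Tissue selection for the specificity index
#'
#' The primary analysis computes tau over 24 tissues, excluding the three
#' female-specific tissues (ovary, placenta, uterus) from the full 27-tissue
#' expression panel; `mode = "all"` keeps every column (the supplementary
#' variant).
#'
#' @param m numeric matrix, genes in rows, tissues in named columns; FPKM.
#' @param mode `"exclude_female_specific"` (default) or `"all"`.
#' @param female_specific tissue names to exclude under the default mode.
#' @return the (sub)matrix.
#' @export
select_tissues <- function(m, mode = c("exclude_female_specific", "all"),
                           female_specific = c("ovary", "placenta", "uterus")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  if (anyDuplicated(colnames(m))) stop("tissue names must be unique")
  if (mode == "all") return(m)
  present <- female_specific %in% colnames(m)
  if (!any(present)) {
    warning("none of the female-specific tissues are present; matrix unchanged")
    return(m)
  }
  if (!all(present))
    stop("unknown tissue name(s) in exclusion set: ",
         paste(female_specific[!present], collapse = ", "))
  m[, setdiff(colnames(m), female_specific), drop = FALSE]
}

#' Tissue-specificity index tau for one expression profile
#'
#' \deqn{\tau = \frac{\sum_{i=1}^{N}(1 - x_i/x_{max})}{N - 1}}
#' over the N tissues of the profile: 0 for a gene expressed at the same
#' level everywhere, 1 for a gene expressed in a single tissue. An all-zero
#' profile has no defined tau and returns `NA` (such genes are excluded
#' upstream and counted in the exclusion ledger).
#'
#' @param x non-negative expression profile over >= 2 tissues (FPKM).
#' @return tau in `[0, 1]`, or `NA_real_` for an all-zero profile.
#' @export
compute_tau <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  if (any(x < 0)) stop("negative expression value")
  xmax <- max(x)
  if (xmax == 0) return(NA_real_)
  sum(1 - x / xmax) / (length(x) - 1)
}

#' Per-gene tau over an expression matrix
#'
#' Applies [select_tissues()] then [compute_tau()] row-wise. Genes with an
#' all-zero profile get `NA` and are listed in the attached ledger.
#'
#' @inheritParams select_tissues
#' @param log_transform if `TRUE`, tau is computed on `log2(FPKM + 1)` (the
#'   supplementary alternative); the primary analysis uses raw FPKM.
#' @return data.frame `gene_id`, `tau`, with attribute `ledger` naming the
#'   all-zero genes.
#' @export
tau_table <- function(m, mode = "exclude_female_specific",
                      female_specific = c("ovary", "placenta", "uterus"),
                      log_transform = FALSE) {
  sel <- select_tissues(m, mode, female_specific)
  if (log_transform) sel <- log2(sel + 1)
  taus <- apply(sel, 1, compute_tau)
  out <- data.frame(gene_id = rownames(m), tau = as.numeric(taus),
                    stringsAsFactors = FALSE)
  attr(out, "ledger") <- out$gene_id[is.na(out$tau)]
  out
}
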