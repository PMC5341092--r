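#' Simulation configuration
#'
#' Defaults reproduce the statistical structure of the study dataset: 965
#' classified genes split 57 male sub-/infertility, 502 lethality, 406
#' nonessential; a 4x4 target Spearman matrix over (dN/dS, degree,
#' multifunctionality, tau) with the observed off-diagonals; 24 tissues; and
#' 102 additional category-excluded genes (73 double essentiality, 26 with
#' unclear/litter/fertile-despite status, 3 special cases) so that the
#' dataset bookkeeping 1,067 - 102 = 965 can be replayed.
#'
#' Per-category location shifts are applied on the latent Gaussian scale
#' before the marginal transforms, ordering the medians as observed:
#' dN/dS highest in sub-/infertility and lowest in lethality genes; degree
#' and multifunctionality highest in lethality genes; tau highest in
#' sub-/infertility and lowest in lethality genes; dS highest in
#' nonessential genes. X-linkage and immunity flags default to the observed
#' per-category proportions (27/406, 5/57, 8/502 and 130/406, 11/57,
#' 140/502).
#'
#' @param n_genes number of classified genes.
#' @param category_sizes named counts for `male_subinfertility`, `lethality`,
#'   `nonessential`; must sum to `n_genes`.
#' @param target_spearman symmetric 4x4 Spearman matrix, unit diagonal, over
#'   variables (dnds, degree, multifunctionality, tau).
#' @param n_tissues number of male-applicable tissues.
#' @param shifts 3x5 matrix of latent shifts (rows: categories as above;
#'   columns: dnds, degree, multifunctionality, tau, ds).
#' @param x_linked_props,immunity_props named per-category flag proportions.
#' @param excluded_counts named counts of category-excluded genes to append
#'   (set to `c()` for none).
#' @param marginals list of quantile functions for the five covariates.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 965L,
    category_sizes = c(male_subinfertility = 57L, lethality = 502L,
                       nonessential = 406L),
    target_spearman = default_target_spearman(),
    n_tissues = 24L,
    shifts = default_latent_shifts(),
    x_linked_props = c(male_subinfertility = 5 / 57, lethality = 8 / 502,
                       nonessential = 27 / 406),
    immunity_props = c(male_subinfertility = 11 / 57, lethality = 140 / 502,
                       nonessential = 130 / 406),
    excluded_counts = c(double_essentiality = 73L,
                        fertile_despite_abnormality = 9L,
                        decreased_litter_size_only = 9L,
                        requires_extra_manipulation = 8L,
                        special_case_exclude = 3L),
    marginals = default_marginals(),
    seed = 1L) {
  stopifnot(sum(category_sizes) == n_genes,
            all(c("male_subinfertility", "lethality", "nonessential") %in%
                  names(category_sizes)),
            is.matrix(target_spearman), nrow(target_spearman) == 4,
            ncol(target_spearman) == 4,
            max(abs(target_spearman - t(target_spearman))) < 1e-12,
            all(abs(diag(target_spearman) - 1) < 1e-12),
            all(target_spearman >= -1 & target_spearman <= 1),
            n_tissues >= 2)
  structure(list(n_genes = as.integer(n_genes),
                 category_sizes = category_sizes,
                 target_spearman = target_spearman,
                 n_tissues = as.integer(n_tissues),
                 shifts = shifts,
                 x_linked_props = x_linked_props,
                 immunity_props = immunity_props,
                 excluded_counts = excluded_counts,
                 marginals = marginals,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

covariate_names <- c("dnds", "degree", "multifunctionality", "tau", "ds")

#' Observed zero-order Spearman targets
#' @return symmetric 4x4 matrix over (dnds, degree, multifunctionality, tau).
#' @export
default_target_spearman <- function() {
  v <- c("dnds", "degree", "multifunctionality", "tau")
  s <- diag(4)
  dimnames(s) <- list(v, v)
  s["dnds", "degree"] <- s["degree", "dnds"] <- -0.229
  s["dnds", "multifunctionality"] <- s["multifunctionality", "dnds"] <- -0.134
  s["dnds", "tau"] <- s["tau", "dnds"] <- 0.088
  s["degree", "multifunctionality"] <- s["multifunctionality", "degree"] <- 0.398
  s["degree", "tau"] <- s["tau", "degree"] <- -0.304
  s["tau", "multifunctionality"] <- s["multifunctionality", "tau"] <- -0.082
  s
}

#' Default per-category latent shifts
#' @return 3x5 matrix (categories x covariates).
#' @export
default_latent_shifts <- function() {
  m <- rbind(
    male_subinfertility = c(dnds = 0.6, degree = -0.3, multifunctionality = 0,
                            tau = 0.7, ds = 0),
    lethality = c(dnds = -0.35, degree = 0.4, multifunctionality = 0.3,
                  tau = -0.3, ds = 0),
    nonessential = c(dnds = 0, degree = 0, multifunctionality = 0,
                     tau = 0, ds = 0.35))
  colnames(m) <- covariate_names
  m
}

#' Default copula marginals
#'
#' dN/dS: Beta(1.5, 8) (purifying-selection-dominated, all values < 1);
#' degree: discretized lognormal(meanlog 2, sdlog 1), floor 1 (heavy-tailed
#' interactome degrees); multifunctionality: 1 + Poisson(3) (every gene has
#' at least one slim process); tau: Beta(2, 2); dS: Gamma(shape 8, rate 16)
#' (human-mouse synonymous divergence around 0.5).
#' @return named list of quantile functions over (0, 1).
#' @export
default_marginals <- function() {
  list(
    dnds = function(u) stats::qbeta(u, 1.5, 8),
    degree = function(u) pmax(1, round(stats::qlnorm(u, meanlog = 2, sdlog = 1))),
    multifunctionality = function(u) 1 + stats::qpois(u, 3),
    tau = function(u) stats::qbeta(u, 2, 2),
    ds = function(u) stats::qgamma(u, shape = 8, rate = 16))
}

#' Convert a Spearman correlation matrix to its Gaussian-copula Pearson matrix
#'
#' Elementwise \eqn{r = 2\sin(\pi\rho_s/6)}: the latent Pearson correlation
#' for which a Gaussian copula reproduces the given Spearman correlation of
#' continuous marginals. If the converted matrix is not positive definite it
#' is projected to the nearest positive-definite correlation matrix
#' (recorded in attribute `projected`).
#'
#' @param rho_s symmetric Spearman matrix, unit diagonal, entries in [-1, 1].
#' @return Pearson correlation matrix with attribute `projected`.
#' @export
spearman_to_pearson <- function(rho_s) {
  rho_s <- as.matrix(rho_s)
  if (max(abs(rho_s - t(rho_s))) > 1e-10) stop("Spearman matrix must be symmetric")
  if (any(rho_s < -1 | rho_s > 1)) stop("Spearman entries must lie in [-1, 1]")
  r <- 2 * sin(pi * rho_s / 6)
  diag(r) <- 1
  projected <- FALSE
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    r <- as.matrix(Matrix::nearPD(r, corr = TRUE)$mat)
    projected <- TRUE
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("matrix not positive definite after projection")
  }
  attr(r, "projected") <- projected
  r
}

#' Simulate the ground-truth gene table
#'
#' Draws a Gaussian copula with the converted correlation matrix (the dS
#' dimension is independent of the four target covariates), applies the
#' per-category latent shifts, maps through the marginal quantile functions,
#' derives dN as dN/dS times dS, assigns each gene a dominant tissue, and
#' flags X-linkage and immunity with per-category counts rounded from the
#' configured proportions. Category-excluded genes (if configured) are
#' appended with zero shifts and carry their exclusion reason. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return data.frame: `gene_id`, `category`, `exclusion_reason`, `dn`, `ds`,
#'   `dnds`, `degree`, `multifunctionality`, `tau`, `x_linked`, `immunity`,
#'   `top_tissue`, `chromosome`.
#' @export
simulate_gene_table <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  r4 <- spearman_to_pearson(cfg$target_spearman)
  r5 <- diag(5)
  r5[1:4, 1:4] <- r4
  dimnames(r5) <- list(covariate_names, covariate_names)
  # The category shifts are a between-group mixture component: they add
  # covariance Sigma_b and variance V_b on the latent scale. Compensate the
  # within-group correlation so the total latent correlation still matches
  # the copula target over the classified genes:
  #   R_w = r_t * sqrt((1 + V_b_i)(1 + V_b_j)) - Sigma_b.
  p_cat <- cfg$category_sizes / sum(cfg$category_sizes)
  s_mat <- cfg$shifts[names(p_cat), covariate_names, drop = FALSE]
  mbar <- colSums(p_cat * s_mat)
  sigma_b <- t(s_mat) %*% (p_cat * s_mat) - outer(mbar, mbar)
  v_tot <- sqrt(1 + diag(sigma_b))
  r_w <- r5 * outer(v_tot, v_tot) - sigma_b
  diag(r_w) <- 1
  ev <- eigen(r_w, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    r_w <- as.matrix(Matrix::nearPD(r_w, corr = TRUE)$mat)
  r5 <- r_w
  cats <- rep(c("male_subinfertility", "lethality", "nonessential"),
              times = cfg$category_sizes[c("male_subinfertility", "lethality",
                                           "nonessential")])
  excl <- rep(names(cfg$excluded_counts), times = cfg$excluded_counts)
  n_tot <- length(cats) + length(excl)
  z <- matrix(stats::rnorm(n_tot * 5), n_tot, 5) %*% chol(r5)
  shift <- matrix(0, n_tot, 5, dimnames = list(NULL, covariate_names))
  for (cat in rownames(cfg$shifts))
    shift[seq_along(cats)[cats == cat], ] <-
      matrix(cfg$shifts[cat, covariate_names],
             sum(cats == cat), 5, byrow = TRUE)
  u <- stats::pnorm(z + shift)
  # guard against exact 0/1 after shifting
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  vals <- lapply(seq_along(covariate_names), function(j)
    cfg$marginals[[covariate_names[j]]](u[, j]))
  names(vals) <- covariate_names
  # an integer degree sequence must be realizable as a simple graph over
  # these genes; continuous (override) degree marginals are left untouched
  integral_degree <- all(vals$degree == round(vals$degree))
  if (integral_degree) vals$degree <- make_graphical(vals$degree)
  category <- c(cats, rep("excluded", length(excl)))
  reason <- c(rep(NA_character_, length(cats)), excl)
  gt <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n_tot)),
    category = category,
    exclusion_reason = reason,
    dn = vals$dnds * vals$ds,
    ds = vals$ds,
    dnds = vals$dnds,
    degree = if (integral_degree) as.integer(vals$degree) else vals$degree,
    multifunctionality =
      if (all(vals$multifunctionality == round(vals$multifunctionality)))
        as.integer(vals$multifunctionality) else vals$multifunctionality,
    tau = vals$tau,
    x_linked = FALSE,
    immunity = FALSE,
    top_tissue = sample.int(cfg$n_tissues, n_tot, replace = TRUE),
    stringsAsFactors = FALSE)
  flag_exact <- function(props) {
    flags <- logical(n_tot)
    for (cat in names(props)) {
      ix <- which(gt$category == cat)
      k <- round(props[[cat]] * length(ix))
      if (k > 0) flags[sample(ix, k)] <- TRUE
    }
    # excluded genes: nonessential-like rates
    ix <- which(gt$category == "excluded")
    if (length(ix)) {
      k <- round(props[["nonessential"]] * length(ix))
      if (k > 0) flags[sample(ix, k)] <- TRUE
    }
    flags
  }
  gt$x_linked <- flag_exact(cfg$x_linked_props)
  gt$immunity <- flag_exact(cfg$immunity_props)
  gt$chromosome <- ifelse(gt$x_linked, "X",
                          as.character(1 + (seq_len(n_tot) %% 22)))
  attr(gt, "copula_projected") <- attr(r4, "projected")
  attr(gt, "degree_adjustments") <- attr(vals$degree, "adjustments")
  gt
}

#' Repair a degree sequence until it is graphical
#'
#' Caps degrees at n - 1, floors them at 1, fixes odd parity by a +1 on a
#' minimum-degree node, and then, while the Erdos-Gallai condition fails,
#' moves one unit of degree from the largest to the smallest node. All
#' adjustments are counted in attribute `adjustments`. Deterministic.
#'
#' @param deg positive integer degree sequence.
#' @return graphical integer sequence, attribute `adjustments`.
#' @export
make_graphical <- function(deg) {
  n <- length(deg)
  adj <- 0L
  d <- pmin(pmax(as.integer(round(deg)), 1L), n - 1L)
  adj <- adj + sum(d != deg)
  if (sum(d) %% 2 == 1) {
    i <- which.min(d)
    d[i] <- d[i] + 1L
    adj <- adj + 1L
  }
  erdos_gallai_ok <- function(d) {
    s <- sort(d, decreasing = TRUE)
    csum <- cumsum(s)
    for (k in seq_len(n)) {
      rhs <- k * (k - 1) + sum(pmin(s[-seq_len(k)], k))
      if (csum[k] > rhs) return(FALSE)
    }
    TRUE
  }
  guard <- 0L
  while (!erdos_gallai_ok(d)) {
    i_max <- which.max(d)
    i_min <- which.min(d)
    if (i_max == i_min) break
    d[i_max] <- d[i_max] - 1L
    d[i_min] <- d[i_min] + 1L
    adj <- adj + 2L
    guard <- guard + 1L
    if (guard > 10L * n) stop("degree sequence could not be made graphical")
  }
  attr(d, "adjustments") <- adj
  d
}

#' Realize a degree sequence as a simple graph (Havel-Hakimi)
#'
#' Deterministic greedy construction: repeatedly connect the node of largest
#' residual degree to the next-largest residual nodes. Even-sum violations
#' and locally infeasible demands are repaired by +-1 adjustments, counted
#' in attribute `repairs`.
#'
#' @param deg positive integer degree sequence.
#' @return 2-column integer matrix of node-index edges, attribute `repairs`.
#' @export
havel_hakimi_edges <- function(deg) {
  stopifnot(all(deg >= 0), all(deg == round(deg)))
  n <- length(deg)
  if (any(deg > n - 1)) stop("degree exceeds n - 1; sequence unrealizable")
  repairs <- 0L
  if (sum(deg) %% 2 == 1) {
    i <- which.min(deg)
    deg[i] <- deg[i] + 1L
    repairs <- repairs + 1L
  }
  residual <- as.integer(deg)
  edges <- matrix(0L, nrow = sum(residual) %/% 2, ncol = 2)
  m <- 0L
  while (any(residual > 0)) {
    v <- which.max(residual)
    d <- residual[v]
    residual[v] <- 0L
    cand <- setdiff(order(-residual, seq_len(n)), v)
    cand <- cand[residual[cand] > 0]
    take <- cand[seq_len(min(d, length(cand)))]
    if (length(take) < d) repairs <- repairs + (d - length(take))
    for (w in take) {
      m <- m + 1L
      edges[m, ] <- c(v, w)
      residual[w] <- residual[w] - 1L
    }
  }
  out <- edges[seq_len(m), , drop = FALSE]
  attr(out, "repairs") <- repairs
  out
}

#' Write the toy Mammalian Phenotype ontology
#'
#' A small is_a tree containing the classification terms: the preweaning
#' lethality (MP:0010770) and lethality-at-weaning (MP:0008569) subtrees
#' with toy children, the four single viability terms, and the male
#' reproduction branch (MP:0001924/25/22, MP:0001935, MP:0002210), plus a
#' benign toy phenotype for nonessential genes.
#'
#' @param path output OBO path.
#' @return `path`, invisibly.
#' @export
write_toy_mp_obo <- function(path) {
  term <- function(id, name, parents = character()) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      paste0("is_a: ", parents), "")
  }
  lines <- c(
    "format-version: 1.2", "ontology: mp-toy", "",
    term("MP:0000001", "mammalian phenotype"),
    term("MP:0010768", "mortality/aging", "MP:0000001"),
    term("MP:0010770", "preweaning lethality", "MP:0010768"),
    term("MP:0011100", "preweaning lethality, complete penetrance", "MP:0010770"),
    term("MP:0011110", "preweaning lethality, incomplete penetrance", "MP:0010770"),
    term("MP:0008569", "lethality at weaning", "MP:0010768"),
    term("MP:0008571", "lethality at weaning, complete penetrance", "MP:0008569"),
    term("MP:0011400", "complete lethality", "MP:0010768"),
    term("MP:0010831", "partial lethality", "MP:0010768"),
    term("MP:0008770", "decreased survivor rate", "MP:0010768"),
    term("MP:0010769", "abnormal survival", "MP:0010768"),
    term("MP:0005389", "reproductive system phenotype", "MP:0000001"),
    term("MP:0001924", "infertility", "MP:0005389"),
    term("MP:0001925", "male infertility", "MP:0001924"),
    term("MP:0001926", "female infertility", "MP:0001924"),
    term("MP:0001922", "reduced male fertility", "MP:0005389"),
    term("MP:0001935", "decreased litter size", "MP:0005389"),
    term("MP:0002210", "abnormal sex determination", "MP:0005389"),
    term("MP:0002000", "toy benign phenotype", "MP:0000001"))
  writeLines(lines, path)
  invisible(path)
}

toy_go_n_slim <- 30L

#' Write the toy GO / GO-slim ontology pair
#'
#' The full ontology has the biological_process root, `n_slim` generic slim
#' classes (GO:0090001...) each with one child term (GO:0091001...), and the
#' immune system process class GO:0002376 with a toy child; the slim file
#' lists the slim classes only.
#'
#' @param full_path,slim_path output OBO paths.
#' @param n_slim number of generic slim classes.
#' @return named character vector of the two paths, invisibly.
#' @export
write_toy_go_obo <- function(full_path, slim_path, n_slim = toy_go_n_slim) {
  term <- function(id, name, parents = character()) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      paste0("is_a: ", parents), "")
  }
  slim_ids <- sprintf("GO:00900%02d", seq_len(n_slim))
  child_ids <- sprintf("GO:00910%02d", seq_len(n_slim))
  lines <- c("format-version: 1.2", "ontology: go-toy", "",
             term("GO:0008150", "biological_process"),
             term("GO:0002376", "immune system process", "GO:0008150"),
             term("GO:0002200", "toy immune subprocess", "GO:0002376"))
  for (i in seq_len(n_slim)) {
    lines <- c(lines,
               term(slim_ids[i], sprintf("toy process %02d", i), "GO:0008150"),
               term(child_ids[i], sprintf("toy subprocess %02d", i), slim_ids[i]))
  }
  writeLines(lines, full_path)
  slim_lines <- c("format-version: 1.2", "ontology: go-toy-slim", "",
                  term("GO:0002376", "immune system process"))
  for (i in seq_len(n_slim))
    slim_lines <- c(slim_lines, term(slim_ids[i], sprintf("toy process %02d", i)))
  writeLines(slim_lines, slim_path)
  invisible(c(full = full_path, slim = slim_path))
}

#' Emit the five pipeline input files from a ground-truth table
#'
#' Writes, under `out_dir`: an FPKM matrix over 27 tissues (24 generic plus
#' ovary/placenta/uterus) constructed by inverting the tau formula for a
#' one-dominant-tissue profile, so that recomputed tau equals ground truth
#' to numerical precision; a GAF annotation file whose slim-mapped
#' biological-process count equals ground-truth multifunctionality (with the
#' immunity class included iff flagged); a PPI edge list plus identifier
#' mapping realizing the ground-truth degree sequence via Havel-Hakimi;
#' a knockout-allele phenotype table the classifier maps back to the
#' ground-truth categories and exclusion reasons; an ortholog-rates TSV
#' (1-to-1 orthologues, unmasked, with the chromosome column); and the toy
#' MP and GO/GO-slim ontologies.
#'
#' @param gt ground truth from [simulate_gene_table()].
#' @param out_dir output directory (created if missing).
#' @param n_tissues number of male-applicable tissues (must match the
#'   simulation).
#' @return named character vector of file paths (the manifest), with
#'   attribute `degree_repairs` from the graph construction.
#' @export
emit_fixture_files <- function(gt, out_dir, n_tissues = 24L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(gt)
  paths <- c(
    fpkm = file.path(out_dir, "expression_fpkm.tsv"),
    gaf = file.path(out_dir, "go_annotations.gaf"),
    edges = file.path(out_dir, "ppi_edges.tsv"),
    mapping = file.path(out_dir, "id_mapping.tsv"),
    alleles = file.path(out_dir, "phenotype_alleles.tsv"),
    rates = file.path(out_dir, "ortholog_rates.tsv"),
    mp_obo = file.path(out_dir, "mp_toy.obo"),
    go_obo = file.path(out_dir, "go_toy.obo"),
    go_slim_obo = file.path(out_dir, "go_slim_toy.obo"),
    ground_truth = file.path(out_dir, "ground_truth.tsv"))

  # expression matrix: dominant tissue at 100, background (1 - tau) * 100
  tissues <- c(sprintf("tissue%02d", seq_len(n_tissues)),
               "ovary", "placenta", "uterus")
  xmax <- 100
  bg <- (1 - gt$tau) * xmax
  fpkm <- matrix(rep(bg, length(tissues)), nrow = n)
  colnames(fpkm) <- tissues
  fpkm[cbind(seq_len(n), gt$top_tissue)] <- xmax
  fpkm_df <- data.frame(gene_id = gt$gene_id, fpkm, check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.table(fpkm_df, paths["fpkm"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # GAF: multifunctionality distinct slim classes per gene, via child terms
  n_slim <- toy_go_n_slim
  gaf_rows <- character()
  for (i in seq_len(n)) {
    k <- gt$multifunctionality[i]
    k_generic <- k - as.integer(gt$immunity[i])
    terms <- character()
    if (gt$immunity[i]) terms <- "GO:0002200"
    if (k_generic > 0) {
      idx <- ((i - 1 + seq_len(k_generic) - 1) %% n_slim) + 1
      terms <- c(terms, sprintf("GO:00910%02d", idx))
    }
    gaf_rows <- c(gaf_rows, vapply(terms, function(tm)
      paste("TOY", gt$gene_id[i], gt$gene_id[i], "", tm, "TOY:0001", "IDA",
            "", "P", "", "", "protein", "taxon:9606", "20260101", "TOY", "",
            "", sep = "\t"), ""))
  }
  writeLines(c("!gaf-version: 2.1", gaf_rows), paths["gaf"])

  # PPI network realizing the degree sequence
  acc <- sprintf("P%05d", seq_len(n))
  e <- havel_hakimi_edges(gt$degree)
  utils::write.table(data.frame(a = acc[e[, 1]], b = acc[e[, 2]]),
                     paths["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(
    accession = acc, status = "current", replacement = "",
    gene_ids = gt$gene_id, biotype = "protein_coding", reviewed = TRUE,
    hgnc_protein_coding = FALSE, stringsAsFactors = FALSE),
    paths["mapping"], sep = "\t", quote = FALSE, row.names = FALSE)

  # phenotype-allele table
  allele_for <- function(i) {
    g <- gt$gene_id[i]
    zyg <- if (gt$x_linked[i]) "hemizygous" else "homozygous"
    mk <- function(suffix, mp, flags = "", zy = zyg)
      data.frame(gene_id = g, allele_id = paste0(g, suffix),
                 allele_type = "Targeted", allele_attributes = "Null/knockout",
                 n_targeted_genes = 1L, zygosity = zy, sex = "both",
                 mp_terms = mp, curation_flags = flags,
                 stringsAsFactors = FALSE)
    cat <- gt$category[i]
    if (cat == "lethality") return(mk("a1", "MP:0011100"))
    if (cat == "male_subinfertility") return(mk("a1", "MP:0001925"))
    if (cat == "nonessential") return(mk("a1", "MP:0002000"))
    switch(gt$exclusion_reason[i],
      double_essentiality = rbind(mk("a1", "MP:0011100"),
                                  mk("a2", "MP:0001925")),
      fertile_despite_abnormality = mk("a1", "MP:0001922",
                                       "fertile_despite_abnormality"),
      decreased_litter_size_only = mk("a1", "MP:0001935",
                                      "decreased_litter_size_only_homozygous_pairs"),
      requires_extra_manipulation = mk("a1", "MP:0011100",
                                       "requires_extra_manipulation"),
      special_case_exclude = mk("a1", "MP:0001925", "special_case_exclude"))
  }
  alleles <- do.call(rbind, lapply(seq_len(n), allele_for))
  utils::write.table(alleles, paths["alleles"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # ortholog rates
  utils::write.table(data.frame(
    gene_id = gt$gene_id, homology_type = "ortholog_one2one",
    dn = gt$dn, ds = gt$ds, dnds = gt$dnds, masked = FALSE,
    chromosome = gt$chromosome, stringsAsFactors = FALSE),
    paths["rates"], sep = "\t", quote = FALSE, row.names = FALSE)

  write_toy_mp_obo(paths["mp_obo"])
  write_toy_go_obo(paths["go_obo"], paths["go_slim_obo"])

  gt_flat <- gt
  utils::write.table(gt_flat, paths["ground_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(paths, "degree_repairs") <- attr(e, "repairs")
  paths
}
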