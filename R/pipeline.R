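#' Pipeline configuration
#'
#' Either a simulation block (the default: fixtures are generated and then
#' consumed like real inputs) or a named list of paths to the five input
#' files plus the three ontologies.
#'
#' @param simulate a [simulation_config()], or `NULL` when `paths` is given.
#' @param paths named list/vector with entries `rates`, `edges`, `mapping`,
#'   `fpkm`, `gaf`, `alleles`, `mp_obo`, `go_obo`, `go_slim_obo`.
#' @param fixture_dir where simulated fixtures are written.
#' @param tissue_mode `"exclude_female_specific"` (24-tissue primary
#'   analysis) or `"all"`.
#' @param mwu_mode Mann-Whitney p-value mode for the post-hoc tests;
#'   `"normal"` (tie-corrected approximation with continuity correction,
#'   the large-sample convention of the original analysis tool), `"auto"`
#'   or `"exact"`.
#' @param bootstrap_B bootstrap pseudo-replicates for median confidence
#'   intervals (analysis-wide setting: 100,000).
#' @param bootstrap_level confidence level.
#' @param holm_m_dnds family size for correlations involving dN/dS
#'   (3 zero-order + 3 partial = 6).
#' @param holm_m_other family size for the remaining zero-order pairs.
#' @param kw_variant_m named family sizes for Kruskal-Wallis p adjustment
#'   of variables analysed in method variants (node degree and tau each have
#'   three variants in the full study design).
#' @param posthoc_m family size for the three pairwise post-hoc tests per
#'   variable.
#' @param seed integer master seed (drives simulation and bootstraps).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            paths = NULL,
                            fixture_dir = file.path(tempdir(), "testevol_fixtures"),
                            tissue_mode = "exclude_female_specific",
                            mwu_mode = "normal",
                            bootstrap_B = 100000L,
                            bootstrap_level = 0.95,
                            holm_m_dnds = 6L,
                            holm_m_other = 3L,
                            kw_variant_m = c(degree = 3L, tau = 3L),
                            posthoc_m = 3L,
                            seed = 1L) {
  if (is.null(simulate) && is.null(paths))
    stop("either a simulate block or input paths must be given")
  structure(list(simulate = simulate, paths = paths,
                 fixture_dir = fixture_dir, tissue_mode = tissue_mode,
                 mwu_mode = mwu_mode, bootstrap_B = as.integer(bootstrap_B),
                 bootstrap_level = bootstrap_level,
                 holm_m_dnds = as.integer(holm_m_dnds),
                 holm_m_other = as.integer(holm_m_other),
                 kw_variant_m = kw_variant_m,
                 posthoc_m = as.integer(posthoc_m),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

category_levels <- c("nonessential", "male_subinfertility", "lethality")

#' Read an FPKM matrix from TSV
#' @param path TSV, first column `gene_id`, remaining columns tissues.
#' @return numeric matrix with gene rownames and tissue colnames.
#' @export
read_fpkm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Per-category medians, bootstrap CIs, and pairwise post-hoc tests
#'
#' For one variable: the per-category median with its percentile-bootstrap
#' confidence interval, and the three pairwise two-tailed Mann-Whitney tests
#' Holm-adjusted within the variable's family. Empty categories are dropped
#' and the pairwise tests restricted to the remaining pairs.
#'
#' @param values numeric vector.
#' @param categories character/factor vector aligned with `values`.
#' @param B,level bootstrap settings.
#' @param seed integer seed for the bootstrap streams.
#' @param m Holm family size for the pairwise tests.
#' @param mwu_mode see [mann_whitney_u()].
#' @return list: `medians` data.frame (`category`, `n`, `median`, `ci_lo`,
#'   `ci_hi`), `pairwise` data.frame (`a`, `b`, `u`, `p_raw`, `p_holm`).
#' @export
summarize_groups <- function(values, categories, B = 10000L, level = 0.95,
                             seed = 1L, m = 3L, mwu_mode = "normal") {
  cats <- intersect(category_levels, unique(as.character(categories)))
  if (length(cats) < 2) stop("need at least two nonempty categories")
  med <- do.call(rbind, lapply(seq_along(cats), function(i) {
    v <- values[categories == cats[i]]
    ci <- bootstrap_median_ci(v, B = B, level = level, seed = seed + i)
    data.frame(category = cats[i], n = length(v),
               median = stats::median(v), ci_lo = ci[1], ci_hi = ci[2],
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(cats, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- mann_whitney_u(values[categories == a], values[categories == b],
                          mode = mwu_mode)
    data.frame(a = a, b = b, u = res$statistic, p_raw = res$p_raw,
               stringsAsFactors = FALSE)
  }))
  pw$p_holm <- holm_adjust(pw$p_raw, m = max(m, nrow(pw)))
  list(medians = med, pairwise = pw)
}

count_table <- function(flag, categories) {
  tab <- sapply(category_levels, function(cat)
    c(sum(flag[categories == cat]), sum(!flag[categories == cat])))
  rownames(tab) <- c("yes", "no")
  tab
}

#' Run the full pipeline
#'
#' Simulates (or reads) the five input files, classifies essentiality from
#' the knockout-allele table, computes node degree, tau and GO-slim
#' multifunctionality, assembles the analysis table with its exclusion
#' ledger, and produces the report bundle: zero-order correlations
#' (`table1`), partial correlations of dN/dS with the constraint proxies
#' (`table2`), Kruskal-Wallis tests over the three categories for six
#' variables (`table3`), the category-composition tests for immunity and
#' X-linkage (`table4`), and per-category median summaries with bootstrap
#' CIs and post-hoc tests for the rate variables (`fig1`) and constraint
#' variables (`fig2`). Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `report_bundle` with elements `table1`, `table2`,
#'   `table3`, `table4`, `fig1`, `fig2`, `records`, `ledger`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    gt <- simulate_gene_table(sim_cfg)
    paths <- emit_fixture_files(gt, config$fixture_dir,
                                n_tissues = sim_cfg$n_tissues)
  } else {
    paths <- config$paths
  }
  rates <- load_ortholog_rates(paths[["rates"]])
  x_linked <- rates$gene_id[rates$chromosome == "X"]

  mp <- read_obo(paths[["mp_obo"]])
  alleles <- read_allele_table(paths[["alleles"]])
  cat_res <- categorize_dataset(alleles, mp, x_linked = x_linked)

  raw <- read_edge_list(paths[["edges"]], paths[["mapping"]])
  net <- build_network(normalize_identifiers(raw))
  degrees <- gene_degree_table(net, rates$gene_id)

  fpkm <- read_fpkm(paths[["fpkm"]])
  taus <- tau_table(fpkm, mode = config$tissue_mode)

  go_full <- read_obo(paths[["go_obo"]])
  go_slim <- read_obo(paths[["go_slim_obo"]])
  slim_ids <- intersect(go_slim$terms, go_full$terms)
  ann <- read_gaf(paths[["gaf"]])
  gof <- go_profile(ann, go_full, slim_ids)

  asm <- assemble_dataset(rates, degrees, taus, gof, cat_res$assignments)
  rec <- asm$records

  # Table 1: zero-order Spearman correlations; the three pairs involving
  # dN/dS share a Holm family with the three partial correlations
  vars4 <- c("dnds", "degree", "multifunctionality", "tau")
  pairs <- utils::combn(vars4, 2)
  t1 <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- spearman(rec[[a]], rec[[b]])
    data.frame(var_a = a, var_b = b, rho = res$statistic, n = res$n,
               p_raw = res$p_raw, stringsAsFactors = FALSE)
  }))
  # Table 2: partial Spearman of dN/dS vs each proxy given the other two
  others <- c("degree", "multifunctionality", "tau")
  t2 <- do.call(rbind, lapply(others, function(v) {
    ctrl <- setdiff(others, v)
    res <- partial_spearman(rec$dnds, rec[[v]],
                            controls = rec[, ctrl, drop = FALSE])
    data.frame(var = v, controlling_for = paste(ctrl, collapse = "+"),
               rho = res$statistic, n = res$n, p_raw = res$p_raw,
               stringsAsFactors = FALSE)
  }))
  dnds_pair <- t1$var_a == "dnds" | t1$var_b == "dnds"
  fam_dnds <- holm_adjust(c(t1$p_raw[dnds_pair], t2$p_raw),
                          m = max(config$holm_m_dnds,
                                  sum(dnds_pair) + nrow(t2)))
  t1$p_holm <- NA_real_
  t1$p_holm[dnds_pair] <- fam_dnds[seq_len(sum(dnds_pair))]
  t1$p_holm[!dnds_pair] <- holm_adjust(t1$p_raw[!dnds_pair],
                                       m = max(config$holm_m_other,
                                               sum(!dnds_pair)))
  t1$family <- ifelse(dnds_pair, "dnds_correlations", "other_correlations")
  t2$p_holm <- fam_dnds[-seq_len(sum(dnds_pair))]
  t2$family <- "dnds_correlations"

  # Table 3: Kruskal-Wallis among the three categories for six variables
  vars6 <- c("dnds", "dn", "ds", "degree", "tau", "multifunctionality")
  t3 <- do.call(rbind, lapply(vars6, function(v) {
    groups <- split(rec[[v]], factor(rec$category, levels = category_levels))
    res <- kruskal_wallis(groups)
    m <- if (v %in% names(config$kw_variant_m)) config$kw_variant_m[[v]] else 1L
    data.frame(variable = v, H = res$statistic, df = res$df,
               p_raw = res$p_raw,
               p_adjusted = holm_adjust(res$p_raw, m = m),
               stringsAsFactors = FALSE)
  }))

  # Table 4: category composition, immunity and X-linkage
  tabs <- list(immunity = count_table(rec$immunity, rec$category),
               x_chromosome = count_table(rec$x_linked, rec$category))
  t4 <- do.call(rbind, lapply(names(tabs), function(nm) {
    tab <- tabs[[nm]]
    res <- contingency_test(tab, name = nm)
    props <- tab["yes", ] / colSums(tab)
    data.frame(variable = nm,
               test = choose_test(tab),
               statistic = res$statistic,
               p_raw = res$p_raw,
               t(stats::setNames(sprintf("%d/%d", tab["yes", ], colSums(tab)),
                                 paste0("counts_", colnames(tab)))),
               t(stats::setNames(round(100 * props, 1),
                                 paste0("pct_", colnames(tab)))),
               stringsAsFactors = FALSE)
  }))

  boot_seed <- config$seed + 1000L
  sum_for <- function(vars) {
    out <- lapply(seq_along(vars), function(i)
      summarize_groups(rec[[vars[i]]], rec$category,
                       B = config$bootstrap_B, level = config$bootstrap_level,
                       seed = boot_seed + 10L * i, m = config$posthoc_m,
                       mwu_mode = config$mwu_mode))
    names(out) <- vars
    out
  }
  fig1 <- sum_for(c("dnds", "dn", "ds"))
  fig2 <- sum_for(c("degree", "multifunctionality", "tau"))

  ledger <- asm$ledger
  manifest <- data.frame(
    key = c("seed", "n_records", "tissue_mode", "bootstrap_B", "mwu_mode",
            "simulated"),
    value = c(config$seed, nrow(rec), config$tissue_mode, config$bootstrap_B,
              config$mwu_mode, !is.null(config$simulate)),
    stringsAsFactors = FALSE)
  structure(list(table1 = t1, table2 = t2, table3 = t3, table4 = t4,
                 fig1 = fig1, fig2 = fig2, records = rec, ledger = ledger,
                 category_counts = table(rec$category), manifest = manifest),
            class = "report_bundle")
}

#' Write a report bundle as TSV files
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return invisible character vector of the files written.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out <<- c(out, p)
  }
  wr(bundle$table1, "table1_zero_order_correlations")
  wr(bundle$table2, "table2_partial_correlations")
  wr(bundle$table3, "table3_kruskal_wallis")
  wr(bundle$table4, "table4_composition")
  for (fig in c("fig1", "fig2")) {
    for (v in names(bundle[[fig]])) {
      wr(bundle[[fig]][[v]]$medians, paste0(fig, "_", v, "_medians"))
      wr(bundle[[fig]][[v]]$pairwise, paste0(fig, "_", v, "_pairwise"))
    }
  }
  wr(bundle$ledger, "exclusion_ledger")
  wr(bundle$manifest, "run_manifest")
  invisible(out)
}
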