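test_that("spearman-to-pearson conversion follows the sine formula", {
  s <- diag(2)
  expect_equal(spearman_to_pearson(s), diag(2), ignore_attr = TRUE)
  s[1, 2] <- s[2, 1] <- 0.5
  r <- spearman_to_pearson(s)
  expect_equal(r[1, 2], 2 * sin(pi * 0.5 / 6), tolerance = 1e-12)
  expect_equal(r[1, 2], 0.5176381, tolerance = 1e-6)
  # perfect rank correlation: the sine formula gives exactly 1; the
  # resulting singular matrix is then projected to the nearest PD matrix
  expect_equal(2 * sin(pi * 1 / 6), 1)
  s[1, 2] <- s[2, 1] <- 1
  r1 <- spearman_to_pearson(s)
  expect_equal(r1[1, 2], 1, tolerance = 1e-6)
  expect_true(attr(r1, "projected"))
  expect_false(attr(spearman_to_pearson(default_target_spearman()), "projected"))
  bad <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(spearman_to_pearson(bad), "symmetric")
  # a rank-degenerate matrix triggers the positive-definite projection
  s3 <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  r3 <- spearman_to_pearson(s3)
  expect_true(attr(r3, "projected"))
  expect_gt(min(eigen(r3, symmetric = TRUE)$values), 0)
})

test_that("simulated covariates reproduce the target correlation structure", {
  cfg <- simulation_config(seed = 101)
  gt <- simulate_gene_table(cfg)
  inc <- gt[gt$category != "excluded", ]
  expect_equal(nrow(inc), 965)
  expect_equal(sum(inc$category == "male_subinfertility"), 57)
  expect_equal(sum(inc$category == "lethality"), 502)
  expect_equal(sum(inc$category == "nonessential"), 406)
  # purifying selection throughout: all dN/dS below one
  expect_true(all(inc$dnds >= 0 & inc$dnds < 1))
  expect_true(all(is.finite(as.matrix(inc[, c("dn", "ds", "dnds", "tau")]))))
  expect_true(all(inc$degree >= 1))
  # sampled Spearman near targets despite the category shifts
  tgt <- default_target_spearman()
  vars <- rownames(tgt)
  for (i in 1:3) for (j in (i + 1):4) {
    obs <- spearman(inc[[vars[i]]], inc[[vars[j]]])$statistic
    expect_lt(abs(obs - tgt[i, j]), 0.08)
  }
})

test_that("copula converges to the target Spearman matrix without shifts", {
  # continuous marginals isolate the copula itself: Spearman correlation is
  # invariant under the strictly monotone marginal transforms, so the sample
  # matrix must converge to the target. (The default discretized count
  # marginals introduce rank ties that attenuate Spearman by roughly a
  # percent; that attenuation is a property of discretization, not of the
  # copula calibration.)
  cont <- default_marginals()
  cont$degree <- function(u) stats::qlnorm(u, 2, 1)
  cont$multifunctionality <- function(u) stats::qgamma(u, 3)
  cfg <- simulation_config(
    n_genes = 10000L,
    category_sizes = c(male_subinfertility = 1000L, lethality = 5000L,
                       nonessential = 4000L),
    shifts = default_latent_shifts() * 0,
    excluded_counts = integer(0),
    marginals = cont,
    seed = 202)
  gt <- simulate_gene_table(cfg)
  tgt <- default_target_spearman()
  vars <- rownames(tgt)
  for (i in 1:3) for (j in (i + 1):4) {
    obs <- spearman(gt[[vars[i]]], gt[[vars[j]]])$statistic
    expect_lt(abs(obs - tgt[i, j]), 0.03)
  }
})

test_that("null configuration rejects at the nominal rate", {
  # zero shifts and zero correlations: Kruskal-Wallis on dN/dS across
  # categories is a true null; rejection rate over seeds stays near 5%
  rej <- vapply(1:200, function(s) {
    cfg <- simulation_config(
      n_genes = 120L,
      category_sizes = c(male_subinfertility = 20L, lethality = 50L,
                         nonessential = 50L),
      target_spearman = diag(4),
      shifts = default_latent_shifts() * 0,
      excluded_counts = integer(0), seed = 5000 + s)
    gt <- simulate_gene_table(cfg)
    kruskal_wallis(split(gt$dnds, gt$category))$p_raw < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("category flags hit the configured per-category counts", {
  gt <- simulate_gene_table(simulation_config(seed = 303))
  inc <- gt[gt$category != "excluded", ]
  expect_equal(sum(inc$x_linked[inc$category == "lethality"]), 8)
  expect_equal(sum(inc$x_linked[inc$category == "male_subinfertility"]), 5)
  expect_equal(sum(inc$x_linked[inc$category == "nonessential"]), 27)
  expect_equal(sum(inc$immunity[inc$category == "lethality"]), 140)
  expect_equal(sum(inc$immunity[inc$category == "male_subinfertility"]), 11)
  expect_equal(sum(inc$immunity[inc$category == "nonessential"]), 130)
  expect_true(all(inc$chromosome[inc$x_linked] == "X"))
})

test_that("median shifts order the categories as configured", {
  gt <- simulate_gene_table(simulation_config(seed = 404))
  inc <- gt[gt$category != "excluded", ]
  med <- function(v) tapply(inc[[v]], inc$category, median)
  m <- med("dnds")
  expect_gt(m["male_subinfertility"], m["nonessential"])
  expect_gt(m["nonessential"], m["lethality"])
  m <- med("tau")
  expect_gt(m["male_subinfertility"], m["nonessential"])
  expect_gt(m["nonessential"], m["lethality"])
  m <- med("degree")
  expect_gt(m["lethality"], m["nonessential"])
  expect_gt(m["nonessential"], m["male_subinfertility"])
  # multifunctionality is a small discrete count: medians can tie, so the
  # ordering is checked on mean ranks
  r <- rank(inc$multifunctionality)
  mr <- tapply(r, inc$category, mean)
  expect_gt(mr["lethality"], mr["nonessential"])
  expect_gt(mr["lethality"], mr["male_subinfertility"])
  m <- med("ds")
  expect_gt(m["nonessential"], m["lethality"])
})

test_that("same seed gives byte-identical fixtures", {
  cfg <- small_sim(seed = 55)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- emit_fixture_files(simulate_gene_table(cfg), d1)
  p2 <- emit_fixture_files(simulate_gene_table(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  # a different seed changes the data
  cfg2 <- small_sim(seed = 56)
  d3 <- file.path(tempdir(), "fx3")
  p3 <- emit_fixture_files(simulate_gene_table(cfg2), d3)
  expect_false(identical(readLines(p1[["rates"]]), readLines(p3[["rates"]])))
})

test_that("havel-hakimi realizes graphical degree sequences exactly", {
  # hand case: star plus edge
  e <- havel_hakimi_edges(c(3, 1, 1, 1))
  expect_equal(attr(e, "repairs"), 0L)
  d <- tabulate(c(e[, 1], e[, 2]), nbins = 4)
  expect_equal(d, c(3, 1, 1, 1))
  # random graphical sequences (generated from actual graphs)
  set.seed(61)
  for (i in 1:5) {
    g <- igraph::sample_gnp(30, 0.2)
    target <- igraph::degree(g)
    e <- havel_hakimi_edges(target)
    expect_equal(attr(e, "repairs"), 0L)
    d <- tabulate(c(e[, 1], e[, 2]), nbins = 30)
    expect_equal(as.numeric(d), as.numeric(target))
    # simple graph: no duplicate edges, no loops
    expect_false(any(e[, 1] == e[, 2]))
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_equal(anyDuplicated(key), 0L)
  }
  # odd-sum sequence gets repaired with a recorded +-1 adjustment
  e_odd <- havel_hakimi_edges(c(2, 1, 1, 1))
  expect_gt(attr(e_odd, "repairs"), 0L)
})

test_that("emitted fixtures invert to the ground truth covariates", {
  cfg <- small_sim(seed = 77)
  gt <- simulate_gene_table(cfg)
  dir <- file.path(tempdir(), "fx_roundtrip")
  paths <- emit_fixture_files(gt, dir)
  # tau round trip at numerical precision
  fpkm <- read_fpkm(paths[["fpkm"]])
  tt <- tau_table(fpkm)
  expect_equal(tt$tau[match(gt$gene_id, tt$gene_id)], gt$tau,
               tolerance = 1e-6)
  # constant-expression gene emits a uniform row with tau 0
  flat <- which.min(gt$tau)
  expect_equal(compute_tau(fpkm[gt$gene_id[flat], ]),
               gt$tau[flat], tolerance = 1e-9)
  # degrees round trip through the network layer
  raw <- read_edge_list(paths[["edges"]], paths[["mapping"]])
  net <- build_network(normalize_identifiers(raw))
  deg <- gene_degree_table(net, gt$gene_id)
  expect_equal(deg$degree[match(gt$gene_id, deg$gene_id)],
               as.numeric(gt$degree))
  # multifunctionality and immunity round trip through GO
  go_full <- read_obo(paths[["go_obo"]])
  go_slim <- read_obo(paths[["go_slim_obo"]])
  slim <- intersect(go_slim$terms, go_full$terms)
  gof <- go_profile(read_gaf(paths[["gaf"]]), go_full, slim)
  ix <- match(gt$gene_id, gof$gene_id)
  expect_equal(gof$multifunctionality[ix], gt$multifunctionality)
  expect_equal(gof$immunity[ix], gt$immunity)
  # lethality genes carry an MP term inside the preweaning subtree
  alleles <- read_allele_table(paths[["alleles"]])
  sub <- mp_subtree(read_obo(paths[["mp_obo"]]), "MP:0010770")
  leth <- gt$gene_id[gt$category == "lethality"]
  for (g in leth[1:5]) {
    mp <- unlist(alleles$mp_terms[alleles$gene_id == g])
    expect_true(any(mp %in% sub))
  }
})
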