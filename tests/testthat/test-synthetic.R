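test_that("fixture specs validate their feasibility constraints", {
  expect_error(synthetic_spec(n_genes = 50, n_modules = 3, module_size = 20),
               "exceeds n_genes")
  expect_error(synthetic_spec(list_length = 60), "50")
  expect_error(synthetic_spec(coreg_within_module_fraction = 1.2), "0, 1")
  expect_error(synthetic_spec(module_size = 10, list_length = 20,
                              coreg_within_module_fraction = 1),
               "module_size - 1")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
})

test_that("fixtures are reproducible and structured as specified", {
  spec <- synthetic_spec(n_genes = 120, n_modules = 2, module_size = 12,
                         list_length = 6, coreg_within_module_fraction = 0.5,
                         seed = 13)
  f1 <- generate_fixture(spec)
  f2 <- generate_fixture(spec)
  expect_identical(f1$coreg$entries, f2$coreg$entries)
  expect_identical(f1$expression$values, f2$expression$values)

  # module genes lead their lists with same-module partners
  truth <- f1$truth$module_of_gene
  n_within <- round(0.5 * 6)
  for (g in names(truth)[!is.na(truth)][c(1, 5, 20)]) {
    lst <- f1$coreg$entries[[g]]
    expect_length(lst, 6L)
    expect_true(all(truth[lst[seq_len(n_within)]] == truth[g]))
  }
  # background genes have full-length lists too
  bg <- names(truth)[is.na(truth)][1]
  expect_length(f1$coreg$entries[[bg]], 6L)
  # no list contains its own query gene (coreg_table invariant)
  expect_false(any(mapply(function(g, l) g %in% l,
                          names(f1$coreg$entries), f1$coreg$entries)))
})

test_that("noiseless fixtures yield exactly the planted log2 effects", {
  spec <- synthetic_spec(n_genes = 80, n_modules = 1, module_size = 10,
                         list_length = 5, effect_size = 2, noise_sd = 0,
                         seed = 17)
  fix <- generate_fixture(spec)
  d <- compute_differences(fix$expression, "A", "B")
  truth <- fix$truth$module_of_gene
  expect_equal(unname(d[!is.na(truth)]), rep(2, 10), tolerance = 1e-9)
  expect_equal(unname(d[is.na(truth)]), rep(0, 70), tolerance = 1e-9)
})

test_that("a fully within-module list yields a complete weighted graph", {
  # 21-gene module with 20-long all-module lists: every per-hit set is the
  # whole module, so all 21 sets contain every pair -> K21 with weight 42
  spec <- synthetic_spec(n_genes = 100, n_modules = 1, module_size = 21,
                         list_length = 20, coreg_within_module_fraction = 1,
                         seed = 19)
  fix <- generate_fixture(spec)
  module_genes <- names(fix$truth$module_of_gene)[
    !is.na(fix$truth$module_of_gene)]
  hits <- hit_list(module_genes)
  m <- build_pair_matrix(hits, fix$coreg, k = 20)
  net <- assemble_network(m, hits)
  expect_identical(nrow(net$edges), 210L)  # all 21 choose 2 pairs
  expect_true(all(net$edges$weight == 2L * 21L))
  met <- connectivity_metrics(net)
  expect_identical(met$percent_included, 100)
})

test_that("zero within-module co-regulation is indistinguishable from random lists", {
  zs <- sapply(1:10, function(s) {
    fix <- generate_fixture(synthetic_spec(
      n_genes = 400, n_modules = 2, module_size = 15, list_length = 8,
      coreg_within_module_fraction = 0, seed = s))
    ds <- apply_noise_floor(fix$expression, 15)
    rk <- rank_genes(compute_differences(ds, "A", "B"), "up")
    hl <- top_hits(rk, 30)
    met <- connectivity_metrics(assemble_network(
      suppressMessages(build_pair_matrix(hl, fix$coreg, k = 8)), hl))
    nc <- null_connectivity(fix$universe, fix$coreg, size = 30, k = 8,
                            n_sets = 30, seed = s + 500)
    c(z_test(met$percent_included, nc$percent_included)$Z,
      z_test(met$connections_per_hit, nc$connections_per_hit)$Z)
  })
  expect_lt(abs(mean(zs[1, ])), 1)
  expect_lt(abs(mean(zs[2, ])), 1)
})

test_that("selected connectors are strongly enriched for planted modules", {
  fix <- generate_fixture(synthetic_spec(seed = 2))
  ds <- apply_noise_floor(fix$expression, 15)
  rk <- rank_genes(compute_differences(ds, "A", "B"), "up")
  hl <- top_hits(rk, 90)
  m <- suppressMessages(build_pair_matrix(hl, fix$coreg, k = 20))
  sel <- suppressMessages(select_connectors(rank_candidates(m), 30))
  expect_gt(length(sel), 0L)
  precision <- mean(!is.na(fix$truth$module_of_gene[sel]))
  background_share <- 90 / 2000
  expect_gt(precision, 10 * background_share)
})

test_that("written fixtures round-trip through every reader dialect", {
  fix <- generate_fixture(synthetic_spec(n_genes = 60, n_modules = 1,
                                         module_size = 8, list_length = 4,
                                         seed = 29))
  dir <- withr::local_tempdir()
  paths <- write_fixture(fix, dir)
  expect_true(all(file.exists(paths)))
  back <- read_coreg_sheets(paths[["coreg"]], format = "wide")
  expect_identical(back$entries, fix$coreg$entries)
  u <- read_gene_universe(paths[["universe"]])
  expect_identical(u$genes, fix$universe$genes)
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_identical(
    vapply(truth$module_of_gene, function(m) !identical(m, "none"),
           logical(1)),
    stats::setNames(!is.na(fix$truth$module_of_gene),
                    names(fix$truth$module_of_gene)))
})
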