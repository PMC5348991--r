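test_that("TSV and PCL expression tables parse and round-trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "e.tsv")
  writeLines(c("GENE\ts1\ts2", "g1\t1.5\t2", "g2\t3\t4"), p)
  ds <- read_expression_table(p, "tsv",
                              conditions = c(s1 = "A", s2 = "B"))
  expect_identical(dim(ds), c(2L, 2L))
  expect_equal(ds$values["g1", "s2"], 2)

  # PCL: annotation columns and EWEIGHT row are parsed and discarded
  p2 <- file.path(dir, "e.pcl")
  writeLines(c("YORF\tNAME\tGWEIGHT\ts1\ts2",
               "EWEIGHT\t\t\t1\t1",
               "g1\tgene one\t1\t10\t20",
               "g2\tgene two\t1\t30\t40"), p2)
  expect_message(
    ds2 <- read_expression_table(p2, "pcl",
                                 conditions = c(s1 = "A", s2 = "B")),
    "EWEIGHT")
  expect_identical(rownames(ds2$values), c("g1", "g2"))
  expect_identical(colnames(ds2$values), c("s1", "s2"))
  expect_equal(unname(ds2$values["g2", ]), c(30, 40))
  expect_identical(ds2$normalization, "PCL")

  # duplicate gene and non-numeric cell errors name the offender
  p3 <- file.path(dir, "dup.tsv")
  writeLines(c("GENE\ts1", "g1\t1", "g1\t2"), p3)
  expect_error(read_expression_table(p3, "tsv"), "g1")
  p4 <- file.path(dir, "nonnum.tsv")
  writeLines(c("GENE\ts1", "g1\tabc"), p4)
  expect_error(read_expression_table(p4, "tsv"), "s1")

  # synthetic fixture round-trips through both writers/readers, with the
  # condition map carried by a YAML sidecar
  fix <- generate_fixture(synthetic_spec(n_genes = 40, n_modules = 1,
                                         module_size = 10, list_length = 5,
                                         seed = 5))
  paths <- write_fixture(fix, file.path(dir, "fix"))
  back_tsv <- read_expression_table(paths[["expression_tsv"]], "tsv",
                                    conditions_file = paths[["conditions"]])
  expect_equal(back_tsv$values, fix$expression$values, tolerance = 1e-12)
  expect_identical(back_tsv$conditions, fix$expression$conditions)
  back_pcl <- suppressMessages(
    read_expression_table(paths[["expression_pcl"]], "pcl",
                          conditions_file = paths[["conditions"]]))
  expect_equal(back_pcl$values, fix$expression$values, tolerance = 1e-12)
})

test_that("noise floor clamps values and is idempotent", {
  v <- matrix(c(3, 15, 40, 7), nrow = 4,
              dimnames = list(paste0("g", 1:4), "s1"))
  ds <- expression_dataset(v, c(s1 = "A"))
  expect_identical(unname(apply_noise_floor(ds, 0)$values[, 1]),
                   c(3, 15, 40, 7))
  floored <- apply_noise_floor(ds, 15)
  expect_identical(unname(floored$values[, 1]), c(15, 15, 40, 15))
  expect_identical(apply_noise_floor(floored, 15)$values, floored$values)
  expect_error(apply_noise_floor(ds, -1), "non-negative")

  # all-noise genes collapse to zero difference downstream
  v2 <- matrix(c(2, 9, 4, 1), nrow = 1,
               dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  ds2 <- expression_dataset(v2, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  d <- compute_differences(apply_noise_floor(ds2, 15), "A", "B")
  expect_identical(unname(d), 0)
})

test_that("expression differences are mean log2 ratios", {
  v <- matrix(c(8, 2), nrow = 1, dimnames = list("g1", c("a1", "b1")))
  ds <- expression_dataset(v, c(a1 = "A", b1 = "B"))
  expect_equal(unname(compute_differences(ds, "A", "B")), 2)
  expect_equal(unname(compute_differences(ds, "A", "A")), 0)

  # replicates: a=(4,16), b=(2,2) -> mean log2 3 - 1 = +2
  v2 <- matrix(c(4, 16, 2, 2), nrow = 1,
               dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  ds2 <- expression_dataset(v2, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(unname(compute_differences(ds2, "A", "B")), 2)

  # antisymmetry on a random dataset
  set.seed(11)
  v3 <- matrix(stats::rlnorm(60, 4, 1), nrow = 10,
               dimnames = list(sprintf("g%02d", 1:10),
                               c(sprintf("a%d", 1:3), sprintf("b%d", 1:3))))
  ds3 <- expression_dataset(v3, stats::setNames(rep(c("A", "B"), each = 3),
                                                colnames(v3)))
  expect_equal(compute_differences(ds3, "A", "B"),
               -compute_differences(ds3, "B", "A"))

  expect_error(compute_differences(ds, "A", "Z"), "unknown condition")
  v0 <- matrix(c(0, 2), nrow = 1, dimnames = list("g1", c("a1", "b1")))
  ds0 <- expression_dataset(v0, c(a1 = "A", b1 = "B"))
  expect_error(compute_differences(ds0, "A", "B"), "noise floor")
})

test_that("rankings sort per direction with deterministic ties", {
  d <- c(A = 2, B = -1, C = 0)
  up <- rank_genes(d, "up")
  expect_identical(up$gene, c("A", "C", "B"))
  down <- rank_genes(d, "down")
  expect_identical(down$gene, c("B", "C", "A"))

  # ties broken lexicographically
  tied <- rank_genes(c(Z = 1, A = 1, M = 1), "up")
  expect_identical(tied$gene, c("A", "M", "Z"))

  # full agreement with an independent sort on 1000 random deltas
  set.seed(23)
  d2 <- stats::setNames(stats::rnorm(1000), sprintf("g%04d", sample(1000)))
  up2 <- rank_genes(d2, "up")
  oracle <- names(sort(d2, decreasing = TRUE))
  expect_identical(up2$gene, oracle)
  expect_identical(up2$rank, 1:1000)

  # antisymmetry of rank positions when all deltas are distinct
  down2 <- rank_genes(d2, "down")
  expect_identical(down2$rank[match(up2$gene, down2$gene)],
                   1000L + 1L - up2$rank)
})

test_that("hit lists are ranking prefixes with strict bounds", {
  r <- make_ranking(50)
  expect_identical(top_hits(r, 1)$genes, genes_at_ranks(1))
  expect_identical(top_hits(r, 50)$genes, genes_at_ranks(1:50))
  h10 <- top_hits(r, 10)
  expect_identical(h10$genes, r$gene[1:10])
  expect_identical(h10$source, "ranking")
  expect_error(top_hits(r, 51), "exceeds")
  expect_error(hit_list(c("a", "a")), "duplicate")

  # external hit lists read from disk
  dir <- withr::local_tempdir()
  p <- file.path(dir, "hits.txt")
  writeLines(c("# top hits", "g1\t1.2", "g2"), p)
  hl <- read_hit_list(p, "down")
  expect_identical(hl$genes, c("g1", "g2"))
  expect_identical(hl$source, "external")
})
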