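test_that("raw pair records follow the (1+k)^2 enumeration identity", {
  set.seed(31)
  pool <- sprintf("P%03d", 1:200)
  entries <- stats::setNames(
    lapply(pool[1:30], function(g) sample(setdiff(pool, g), 20L)),
    pool[1:30])
  tab <- coreg_table(entries)

  # one hit with a full 20-list enumerates 21^2 = 441 records
  m1 <- build_pair_matrix(hit_list(pool[1]), tab, k = 20)
  expect_identical(m1$raw_pair_records, 441L)

  # h hits with full lists enumerate h * (1+k)^2
  for (case in list(c(h = 5, k = 3), c(h = 10, k = 20), c(h = 30, k = 7))) {
    m <- build_pair_matrix(hit_list(pool[seq_len(case[["h"]])]), tab,
                           k = case[["k"]])
    expect_identical(m$raw_pair_records,
                     as.integer(case[["h"]] * (1 + case[["k"]])^2))
  }

  # a hit without a table entry contributes exactly its self-record
  expect_message(
    m2 <- build_pair_matrix(hit_list(c(pool[1], "ORPHAN")), tab, k = 20),
    "without a co-regulator entry")
  expect_identical(m2$raw_pair_records, 441L + 1L)
})

test_that("pair counts match brute-force enumeration", {
  # the 2-gene instance: mutual co-regulators give occurrence count 4
  tab <- coreg_table(list(A = "B", B = "A"))
  m <- build_pair_matrix(hit_list(c("A", "B")), tab, k = 1)
  expect_identical(m$pairs$gene_a, "A")
  expect_identical(m$pairs$gene_b, "B")
  expect_identical(m$pairs$count, 4L)

  # random instances with <= 6 hits and k <= 3 against the loop oracle
  set.seed(37)
  for (rep in 1:25) {
    genes <- sprintf("g%02d", 1:12)
    entries <- random_entries(genes, 4L)
    tab <- coreg_table(entries)
    k <- sample.int(3L, 1L)
    hits <- hit_list(sample(genes, sample.int(6L, 1L)))
    m <- build_pair_matrix(hits, tab, k = k)
    oracle <- brute_force_pairs(hits$genes, entries, k)
    got <- stats::setNames(m$pairs$count,
                           paste(m$pairs$gene_a, m$pairs$gene_b, sep = "|"))
    expect_identical(got[order(names(got))],
                     oracle$counts[order(names(oracle$counts))])
    expect_identical(m$raw_pair_records, oracle$raw)
    # no self-pairs, counts >= 1, lexicographic canonical order
    expect_true(all(m$pairs$gene_a < m$pairs$gene_b))
    expect_true(all(m$pairs$count >= 1L))
    # dedup conservation: unordered counts + self-records = raw records
    k_g <- vapply(hits$genes, function(g)
      length(top_coregulators(tab, g, k)), integer(1L))
    expect_identical(sum(m$pairs$count) + sum(1L + k_g),
                     m$raw_pair_records)
  }
})

test_that("pair matrix dumps round-trip through TSV", {
  tab <- coreg_table(tiny_entries())
  m <- build_pair_matrix(hit_list(c("A", "C", "E")), tab, k = 3)
  p <- file.path(withr::local_tempdir(), "matrix.tsv")
  write_pair_matrix(m, p)
  back <- read_pair_matrix(p)
  expect_identical(back$pairs, m$pairs)
  expect_identical(back$raw_pair_records, m$raw_pair_records)
  expect_identical(back$hit_genes, m$hit_genes)
  expect_identical(back$k, m$k)
})

test_that("network assembly keeps only member-member edges", {
  tab <- coreg_table(tiny_entries())
  hits <- hit_list(c("A", "B", "C"))
  m <- build_pair_matrix(hits, tab, k = 3)

  net <- assemble_network(m, hits)
  # brute-force filter: pairs with both endpoints among the nodes
  keep <- m$pairs$gene_a %in% hits$genes & m$pairs$gene_b %in% hits$genes
  expect_identical(net$edges$gene_a, m$pairs$gene_a[keep])
  expect_identical(net$edges$weight, m$pairs$count[keep])
  expect_true(all(net$nodes$role == "hit"))

  # pairs touching non-members are excluded; adding the connector admits them
  expect_false("E" %in% c(net$edges$gene_a, net$edges$gene_b))
  net2 <- assemble_network(m, hits, connectors = "E")
  expect_true("E" %in% c(net2$edges$gene_a, net2$edges$gene_b))
  expect_identical(net2$nodes$role[net2$nodes$gene == "E"], "connector")

  # edge weights always equal the matrix counts they came from
  key <- function(df) paste(df$gene_a, df$gene_b)
  expect_identical(net2$edges$weight,
                   m$pairs$count[match(key(net2$edges), key(m$pairs))])

  expect_error(assemble_network(m, hits, connectors = "A"),
               "also present in the hit list")

  # deltas are attached to nodes when supplied
  net3 <- assemble_network(m, hits, deltas = c(A = 1.5, B = -2, C = 0))
  expect_equal(net3$nodes$delta[net3$nodes$gene == "B"], -2)
})

test_that("connectivity metrics count weighted hit degrees", {
  # edgeless network of 10 hits
  tab0 <- coreg_table(stats::setNames(
    lapply(sprintf("h%02d", 1:10), function(g) "FARAWAY"),
    sprintf("h%02d", 1:10)))
  hits0 <- hit_list(sprintf("h%02d", 1:10))
  net0 <- assemble_network(build_pair_matrix(hits0, tab0, k = 1), hits0)
  met0 <- connectivity_metrics(net0)
  expect_identical(met0$percent_included, 0)
  expect_identical(met0$connections_per_hit, 0)

  # two hits joined by one weight-4 edge: 100% included, (4+4)/2 = 4
  tab <- coreg_table(list(A = "B", B = "A"))
  hits <- hit_list(c("A", "B"))
  met <- connectivity_metrics(
    assemble_network(build_pair_matrix(hits, tab, k = 1), hits))
  expect_identical(met$percent_included, 100)
  expect_identical(met$connections_per_hit, 4)

  # a connector adjacent to a previously isolated hit raises inclusion
  tab2 <- coreg_table(list(A = "B", B = "A", C = "X", X = "C"))
  hits2 <- hit_list(c("A", "B", "C"))
  m2 <- build_pair_matrix(hits2, tab2, k = 1)
  base <- connectivity_metrics(assemble_network(m2, hits2))
  expanded <- connectivity_metrics(
    assemble_network(m2, hits2, connectors = "X"))
  expect_lt(base$percent_included, expanded$percent_included)

  expect_error(connectivity_metrics(
    structure(list(nodes = data.frame(gene = "c", role = "connector",
                                      delta = NA_real_),
                   edges = net0$edges, direction = "up"),
              class = "coreg_network")), "no hit nodes")
})

test_that("weighted hit degree agrees with igraph strength", {
  set.seed(43)
  genes <- sprintf("g%02d", 1:25)
  tab <- coreg_table(random_entries(genes, 6L))
  hits <- hit_list(sample(genes, 10L))
  m <- build_pair_matrix(hits, tab, k = 5)
  cand <- rank_candidates(m)
  sel <- suppressMessages(select_connectors(cand, 5))
  net <- assemble_network(m, hits, connectors = sel)
  met <- connectivity_metrics(net)
  g <- as_igraph(net)
  s <- igraph::strength(g, weights = igraph::E(g)$weight)
  hit_s <- s[igraph::V(g)$role == "hit"]
  expect_equal(met$connections_per_hit, sum(hit_s) / length(hit_s))
  expect_equal(met$percent_included, 100 * mean(hit_s > 0))
})

test_that("both connectivity metrics are monotone in k", {
  set.seed(47)
  genes <- sprintf("g%03d", 1:60)
  tab <- coreg_table(random_entries(genes, 10L))
  hits <- hit_list(sample(genes, 15L))
  pct <- cph <- numeric(0)
  for (k in 1:8) {
    met <- connectivity_metrics(
      assemble_network(build_pair_matrix(hits, tab, k = k), hits))
    pct <- c(pct, met$percent_included)
    cph <- c(cph, met$connections_per_hit)
  }
  expect_true(all(diff(pct) >= 0))
  expect_true(all(diff(cph) >= 0))
})
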