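# Shared fixtures and independent oracles. The oracles deliberately use only
# plain loops over the definitions, never the package's own code paths.

# A small fully-specified co-regulator table used across tests.
tiny_entries <- function() {
  list(
    A = c("B", "C", "D"),
    B = c("A", "D"),
    C = c("A", "B", "E"),
    D = c("E"),
    E = c("A", "B", "C", "D")
  )
}

# Random co-regulator entries over `genes`, list lengths 1..max_len.
random_entries <- function(genes, max_len) {
  entries <- lapply(genes, function(g) {
    sample(setdiff(genes, g), sample.int(max_len, 1L))
  })
  names(entries) <- genes
  entries
}

# Independent pair-count oracle: enumerate every ordered pair (self-pairs
# included) of each per-hit set with a double loop, then merge.
brute_force_pairs <- function(hit_genes, entries, k) {
  counts <- list()
  raw <- 0L
  for (g in hit_genes) {
    lst <- entries[[g]]
    if (!is.null(lst)) lst <- lst[seq_len(min(k, length(lst)))]
    s <- c(g, lst)
    raw <- raw + as.integer(length(s)^2)
    for (x in s) {
      for (y in s) {
        if (x != y) {
          key <- paste(sort(c(x, y)), collapse = "|")
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  list(counts = unlist(counts), raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent threshold-scan oracle for connector selection: try every
# threshold t from 0 upward and take the first obeying the cap.
brute_force_selection <- function(genes, counts, max_c) {
  for (t in 0:max(counts)) {
    above <- counts > t
    if (sum(above) <= max_c) {
      return(list(threshold = t, genes = genes[above]))
    }
  }
}

# Build a connector_candidates data frame directly from counts (sorted the
# way rank_candidates sorts).
make_candidates <- function(genes, counts) {
  df <- data.frame(gene = genes, connections_to_hits = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$connections_to_hits, df$gene, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("connector_candidates", "data.frame")
  df
}

# A ranking of N genes in which gene i has rank i (delta descending).
make_ranking <- function(N, direction = "up") {
  genes <- sprintf("R%05d", seq_len(N))
  deltas <- stats::setNames(as.numeric(N:1), genes)
  if (direction == "down") deltas <- -deltas
  rank_genes(deltas, direction = direction)
}

# Gene identifiers occupying the given ranks of make_ranking(N).
genes_at_ranks <- function(ranks) sprintf("R%05d", ranks)

# A small expression dataset with two conditions and given replicate count.
tiny_expression <- function(values, reps = 1L) {
  genes <- rownames(values)
  samples <- colnames(values)
  conds <- stats::setNames(rep(c("A", "B"), each = ncol(values) / 2),
                           samples)
  expression_dataset(values, conds)
}
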