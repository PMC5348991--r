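#' Build the pairwise co-occurrence connection matrix
#'
#' For each hit gene g with co-regulator prefix of length `k_g` (at most `k`),
#' the per-hit set `S_g = {g} U prefix` is enumerated as the full
#' `(1 + k_g) x (1 + k_g)` grid of ordered gene pairs, self-pairs included —
#' so one hit with 20 co-regulators contributes 441 raw pair records, 100
#' such hits contribute 44,100 and 40 co-regulators per hit give 168,100.
#' All records are then canonicalized to unordered pairs of distinct genes:
#' self-pairs are dropped and the remaining multiplicity becomes the pair's
#' occurrence count X, so each pair is listed once with its count.
#'
#' Hits absent from the co-regulator table contribute only their single
#' self-record (which is then dropped) and are logged; they can still gain
#' edges through other hits' lists.
#'
#' @param hits A [hit_list()].
#' @param table A [coreg_table()].
#' @param k Number of co-regulators per hit (`>= 1`).
#' @return An object of class `pair_matrix`: list with `pairs` (data frame
#'   `gene_a` < `gene_b` lexicographically, `count`), `raw_pair_records`,
#'   `hit_genes`, `k`.
#' @export
build_pair_matrix <- function(hits, table, k) {
  stopifnot(inherits(hits, "hit_list"), inherits(table, "coreg_table"))
  k <- .sn_assert_scalar_count(k, "k")
  hit_genes <- hits$genes
  sets <- lapply(hit_genes, function(g) c(g, top_coregulators(table, g, k)))
  k_g <- lengths(sets) - 1L
  no_entry <- hit_genes[k_g == 0L & !(hit_genes %in% names(table$entries))]
  if (length(no_entry)) {
    .sn_log(length(no_entry),
            " hit(s) without a co-regulator entry contribute only their ",
            "self-record: ", paste(utils::head(no_entry, 5L), collapse = ", "),
            if (length(no_entry) > 5L) ", ..." else "")
  }
  raw <- as.integer(sum((1L + k_g)^2))
  # Each unordered pair {a, b} within one hit's set appears as the two ordered
  # records (a,b) and (b,a); accumulate multiplicity 2 per within-set pair.
  # Genes are coded as integers in lexicographic order so pairs can be keyed
  # numerically; this path runs thousands of times inside the null loops.
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  n_codes <- length(all_genes)
  combn_cache <- list()
  keys <- unlist(lapply(sets, function(s) {
    m <- length(s)
    if (m < 2L) return(double(0L))
    code <- sort.int(match(s, all_genes))
    len <- as.character(m)
    tpl <- combn_cache[[len]]
    if (is.null(tpl)) {
      tpl <- utils::combn(m, 2L)
      combn_cache[[len]] <<- tpl
    }
    # code[i] < code[j] for i < j, so key = a * n + b is canonical
    as.double(code[tpl[1L, ]]) * n_codes + code[tpl[2L, ]]
  }), use.names = FALSE)
  if (length(keys)) {
    keys <- sort.int(keys, method = "radix")
    ends <- c(which(diff(keys) != 0), length(keys))
    uniq <- keys[ends]
    counts <- 2L * as.integer(diff(c(0L, ends)))
    a <- floor((uniq - 1) / n_codes)
    b <- as.integer(uniq - a * n_codes)
    pairs <- data.frame(
      gene_a = all_genes[as.integer(a)],
      gene_b = all_genes[b],
      count = counts,
      stringsAsFactors = FALSE
    )
  } else {
    pairs <- data.frame(gene_a = character(0L), gene_b = character(0L),
                        count = integer(0L), stringsAsFactors = FALSE)
  }
  structure(
    list(pairs = pairs, raw_pair_records = raw, hit_genes = hit_genes,
         k = k),
    class = "pair_matrix"
  )
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf(
    "<pair_matrix> %d hits, k=%d: %d raw pair records -> %d unique pairs\n",
    length(x$hit_genes), x$k, x$raw_pair_records, nrow(x$pairs)))
  invisible(x)
}

#' Write / read the connection matrix as TSV
#'
#' Columns `gene_a`, `gene_b`, `occurrence_count`, pairs in lexicographic
#' order; `raw_pair_records`, hit genes and `k` are carried in `#`-prefixed
#' header comments so the dump round-trips.
#'
#' @param matrix A `pair_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pair_matrix"))
  lines <- c(
    sprintf("# raw_pair_records\t%d", matrix$raw_pair_records),
    sprintf("# k\t%d", matrix$k),
    sprintf("# hits\t%s", paste(matrix$hit_genes, collapse = ",")),
    "gene_a\tgene_b\toccurrence_count",
    sprintf("%s\t%s\t%d", matrix$pairs$gene_a, matrix$pairs$gene_b,
            matrix$pairs$count)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @param path Path of a file written by [write_pair_matrix()].
#' @return For `read_pair_matrix`, the reconstructed `pair_matrix`.
#' @export
read_pair_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)
    if (length(m) != 1L) stop("matrix dump lacks metadata: ", key,
                              call. = FALSE)
    sub(paste0("^# ", key, "\t"), "", m)
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))][-1L]  # drop column header
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    pairs <- data.frame(
      gene_a = vapply(f, `[[`, character(1L), 1L),
      gene_b = vapply(f, `[[`, character(1L), 2L),
      count = as.integer(vapply(f, `[[`, character(1L), 3L)),
      stringsAsFactors = FALSE
    )
  } else {
    pairs <- data.frame(gene_a = character(0L), gene_b = character(0L),
                        count = integer(0L), stringsAsFactors = FALSE)
  }
  structure(
    list(pairs = pairs,
         raw_pair_records = as.integer(get_meta("raw_pair_records")),
         hit_genes = strsplit(get_meta("hits"), ",", fixed = TRUE)[[1L]],
         k = as.integer(get_meta("k"))),
    class = "pair_matrix"
  )
}

#' Assemble the network over hits and optional connectors
#'
#' Network nodes are the hit genes plus any selected connector genes; edges
#' are exactly the matrix pairs whose both endpoints are nodes, weighted by
#' occurrence count. Co-regulators that are neither hits nor connectors stay
#' latent in the matrix. Per-node expression deltas are attached when
#' available.
#'
#' @param matrix A `pair_matrix` from [build_pair_matrix()].
#' @param hits The [hit_list()] the matrix was built from.
#' @param connectors Character vector of connector genes (disjoint from the
#'   hits), e.g. from [select_connectors()].
#' @param deltas Optional named numeric vector of expression differences.
#' @return An object of class `coreg_network`: list with `nodes` (data frame
#'   `gene`, `role` in hit/connector, `delta`) and `edges` (data frame
#'   `gene_a`, `gene_b`, `weight`), both in lexicographic order.
#' @export
assemble_network <- function(matrix, hits, connectors = character(0L),
                             deltas = NULL) {
  stopifnot(inherits(matrix, "pair_matrix"), inherits(hits, "hit_list"))
  connectors <- as.character(connectors)
  overlap <- intersect(connectors, hits$genes)
  if (length(overlap)) {
    stop("connector gene(s) also present in the hit list: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  genes <- c(sort(hits$genes, method = "radix"),
             sort(connectors, method = "radix"))
  nodes <- data.frame(
    gene = genes,
    role = c(rep("hit", hits$h), rep("connector", length(connectors))),
    delta = if (is.null(deltas)) NA_real_ else unname(deltas[genes]),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$gene, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  member <- matrix$pairs$gene_a %in% genes & matrix$pairs$gene_b %in% genes
  edges <- matrix$pairs[member, , drop = FALSE]
  names(edges) <- c("gene_a", "gene_b", "weight")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 direction = hits$direction),
            class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  cat(sprintf("<coreg_network> %d nodes (%d hits, %d connectors), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "hit"),
              sum(x$nodes$role == "connector"), nrow(x$edges)))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' Vertex attributes `role` and `delta` and edge attribute `weight` are
#' carried over, so downstream graph analysis and layout can use the igraph
#' toolbox directly.
#'
#' @param net A `coreg_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coreg_network"))
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$gene, role = net$nodes$role,
                          delta = net$nodes$delta, stringsAsFactors = FALSE))
  g
}

#' Connectivity parameters of a network
#'
#' Two parameters characterize network quality:
#' \describe{
#'   \item{percent included}{percentage of hit genes with at least one edge to
#'     any node of the network (hit or connector).}
#'   \item{connections per hit}{occurrence-weighted degree of the hit nodes
#'     averaged over all hits — each hit-hit edge contributes its weight to
#'     both endpoints, a hit-connector edge to its hit endpoint; isolated hits
#'     stay in the denominator.}
#' }
#'
#' @param net A `coreg_network` with at least one hit node.
#' @return List with `percent_included` (0--100), `connections_per_hit` and
#'   `n_hits`.
#' @export
connectivity_metrics <- function(net) {
  stopifnot(inherits(net, "coreg_network"))
  hit_genes <- net$nodes$gene[net$nodes$role == "hit"]
  if (length(hit_genes) == 0L) {
    stop("network has no hit nodes", call. = FALSE)
  }
  endpoint <- c(net$edges$gene_a, net$edges$gene_b)
  wt <- c(net$edges$weight, net$edges$weight)
  strength <- tapply(wt, factor(endpoint, levels = hit_genes), sum,
                     default = 0)
  included <- sum(strength > 0)
  list(
    percent_included = 100 * included / length(hit_genes),
    connections_per_hit = sum(strength) / length(hit_genes),
    n_hits = length(hit_genes)
  )
}
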