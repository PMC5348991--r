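#' Rank connector candidates by their connections to the hits
#'
#' A connector candidate is any non-hit gene appearing in the connection
#' matrix. Its score is the number of connections linking it to hit genes:
#' by default the occurrence-weighted sum of the counts of its gene-hit pairs
#' (`weighting = "occurrence"`), or alternatively the number of distinct hits
#' it is paired with (`weighting = "distinct"`). Connections to other non-hit
#' genes never count.
#'
#' @param matrix A `pair_matrix` from [build_pair_matrix()].
#' @param weighting `"occurrence"` (default) or `"distinct"`.
#' @return Data frame of class `connector_candidates` with columns `gene` and
#'   `connections_to_hits`, sorted by `connections_to_hits` descending, ties
#'   broken lexicographically by gene. Possibly zero rows.
#' @export
rank_candidates <- function(matrix, weighting = c("occurrence", "distinct")) {
  stopifnot(inherits(matrix, "pair_matrix"))
  weighting <- match.arg(weighting)
  hits <- matrix$hit_genes
  p <- matrix$pairs
  a_hit <- p$gene_a %in% hits
  b_hit <- p$gene_b %in% hits
  # a pair contributes to a candidate when the candidate is the non-hit
  # endpoint and the other endpoint is a hit
  cand_gene <- c(p$gene_b[a_hit & !b_hit], p$gene_a[b_hit & !a_hit])
  cand_cnt <- c(p$count[a_hit & !b_hit], p$count[b_hit & !a_hit])
  if (length(cand_gene) == 0L) {
    out <- data.frame(gene = character(0L),
                      connections_to_hits = integer(0L),
                      stringsAsFactors = FALSE)
  } else {
    if (weighting == "distinct") cand_cnt <- rep(1L, length(cand_cnt))
    sums <- tapply(cand_cnt, cand_gene, sum)
    out <- data.frame(gene = names(sums),
                      connections_to_hits = as.integer(sums),
                      stringsAsFactors = FALSE)
    out <- out[out$connections_to_hits >= 1L, , drop = FALSE]
    out <- out[order(-out$connections_to_hits, out$gene, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("connector_candidates", "data.frame")
  out
}

#' Select connectors by the connection-count threshold rule
#'
#' Given a user-chosen maximum number of connectors, the selection threshold
#' T is the smallest connection count such that at most `max_c` candidates
#' have strictly more than T connections to the hits; exactly those
#' strictly-above-threshold genes are kept. Because the rule is strict, ties
#' straddling the cut can leave the selection smaller than `max_c` — with
#' weakly connected (e.g. random) hit lists often only a few connectors are
#' selected even when many are requested. The selection never exceeds
#' `max_c`.
#'
#' @param candidates A `connector_candidates` data frame from
#'   [rank_candidates()].
#' @param max_c Maximum number of connectors (`>= 1`).
#' @return Character vector of selected connector genes, in candidate order;
#'   the selection threshold is attached as attribute `threshold`.
#' @export
select_connectors <- function(candidates, max_c) {
  stopifnot(inherits(candidates, "connector_candidates"))
  max_c <- .sn_assert_scalar_count(max_c, "max_c")
  if (nrow(candidates) == 0L) {
    .sn_log("no connector candidates available; empty selection")
    return(structure(character(0L), threshold = 0L))
  }
  counts <- candidates$connections_to_hits
  for (t in c(0L, sort(unique(counts)))) {
    if (sum(counts > t) <= max_c) {
      sel <- candidates$gene[counts > t]
      if (length(sel) < max_c) {
        .sn_log(sprintf(
          "connector selection under-filled: %d of %d requested (threshold %d)",
          length(sel), max_c, t))
      }
      return(structure(sel, threshold = t))
    }
  }
  # unreachable: t = max(counts) always satisfies the bound
  stop("internal error in connector threshold scan")
}

#' Connector report table
#'
#' Summarizes candidates, selection status and (optionally) each candidate's
#' position in the full expression ranking, suitable for writing as TSV.
#'
#' @param candidates A `connector_candidates` data frame.
#' @param selected Character vector from [select_connectors()].
#' @param ranking Optional `differential_ranking` used to annotate each
#'   candidate's expression rank.
#' @return Data frame with columns `gene`, `connections_to_hits`, `selected`
#'   (`"yes"`/`"no"`), `rank_in_expression` (integer or `NA`).
#' @export
connector_report <- function(candidates, selected, ranking = NULL) {
  stopifnot(inherits(candidates, "connector_candidates"))
  rk <- rep(NA_integer_, nrow(candidates))
  if (!is.null(ranking)) {
    stopifnot(inherits(ranking, "differential_ranking"))
    rk <- ranking$rank[match(candidates$gene, ranking$gene)]
  }
  data.frame(
    gene = candidates$gene,
    connections_to_hits = candidates$connections_to_hits,
    selected = ifelse(candidates$gene %in% selected, "yes", "no"),
    rank_in_expression = rk,
    stringsAsFactors = FALSE
  )
}
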