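#' Gene universes for random sampling
#'
#' The set of genes random hit lists are drawn from — typically all genes of
#' the yeast genome, read from a FASTA library or a plain list.
#'
#' @param genes Character vector of gene identifiers (duplicates dropped).
#' @param source_label Free-text provenance label.
#' @return List of class `gene_universe` with `genes`, `source_label`.
#' @export
gene_universe <- function(genes, source_label = "") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene universe", call. = FALSE)
  structure(list(genes = genes, source_label = source_label),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe> %d genes%s\n", length(x$genes),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]")
              else ""))
  invisible(x)
}

#' Read a gene universe from FASTA or a plain gene list
#'
#' FASTA headers are parsed for their first whitespace-delimited token after
#' `>`; plain lists take one gene per line (`#` comments ignored).
#'
#' @param path File path.
#' @param format `"auto"` (FASTA if the first non-blank line starts with
#'   `>`), `"fasta"` or `"list"`.
#' @return A [gene_universe()].
#' @export
read_gene_universe <- function(path, format = c("auto", "fasta", "list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("universe file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty universe file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (startsWith(trimws(lines[[1L]]), ">")) "fasta" else "list"
  }
  genes <- if (format == "fasta") {
    hdr <- grep("^>", lines, value = TRUE)
    if (length(hdr) == 0L) stop("no FASTA headers in ", path, call. = FALSE)
    vapply(strsplit(sub("^>\\s*", "", hdr), "\\s+"), `[[`, character(1L), 1L)
  } else {
    lines <- lines[!grepl("^\\s*#", lines)]
    vapply(strsplit(lines, "\t", fixed = TRUE), function(f) trimws(f[[1L]]),
           character(1L))
  }
  gene_universe(genes, source_label = path)
}

#' Draw random hit lists
#'
#' Each list is a uniform sample without replacement of `size` genes from the
#' universe, restricted to genes that have an entry in the co-regulator table
#' (genes without an entry cannot contribute connections and are omitted, as
#' roughly 10--15\% of the yeast genome is uncovered). Fully reproducible
#' from `seed`.
#'
#' @param universe A [gene_universe()].
#' @param table A [coreg_table()]; only covered genes are eligible.
#' @param size Genes per list.
#' @param n_sets Number of lists (default 100).
#' @param seed Integer RNG seed.
#' @param direction Direction label to stamp on the lists.
#' @return List of `n_sets` [hit_list()] objects.
#' @export
random_hit_lists <- function(universe, table, size, n_sets = 100L, seed,
                             direction = "up") {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(table, "coreg_table"))
  size <- .sn_assert_scalar_count(size, "size")
  n_sets <- .sn_assert_scalar_count(n_sets, "n_sets")
  eligible <- intersect(universe$genes, names(table$entries))
  if (length(eligible) < size) {
    stop(sprintf(
      "only %d universe genes have a co-regulator entry; cannot draw lists of size %d",
      length(eligible), size), call. = FALSE)
  }
  .sn_with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      hit_list(sample(eligible, size), direction = direction,
               source = "external")
    })
  })
}

#' Generate randomized expression datasets
#'
#' Two randomization modes:
#' \describe{
#'   \item{`"permute_genes"`}{gene labels are randomly reassigned to the value
#'     rows; the matrix values are untouched, so the expression distribution
#'     is preserved exactly while all gene-specific signal is destroyed. This
#'     assumption-free mode is the default.}
#'   \item{`"iid"`}{every value is drawn independently from a log-normal
#'     distribution fitted to the template's pooled (positive) values.}
#' }
#'
#' @param template An [expression_dataset()] providing dimensions, sample
#'   layout and the value distribution.
#' @param n_sets Number of randomized datasets (default 100).
#' @param seed Integer RNG seed.
#' @param mode `"permute_genes"` or `"iid"`.
#' @return List of `n_sets` [expression_dataset()] objects.
#' @export
random_expression_datasets <- function(template, n_sets = 100L, seed,
                                       mode = c("permute_genes", "iid")) {
  stopifnot(inherits(template, "expression_dataset"))
  mode <- match.arg(mode)
  n_sets <- .sn_assert_scalar_count(n_sets, "n_sets")
  v <- template$values
  if (mode == "iid") {
    pos <- v[v > 0]
    if (length(pos) < 2L) {
      stop("iid mode needs >= 2 positive template values", call. = FALSE)
    }
    meanlog <- mean(log(pos))
    sdlog <- stats::sd(log(pos))
  }
  .sn_with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      out <- template
      if (mode == "permute_genes") {
        rownames(out$values) <- rownames(v)[sample.int(nrow(v))]
        out$values <- out$values[rownames(v), , drop = FALSE]
      } else {
        out$values <- matrix(
          stats::rlnorm(length(v), meanlog = meanlog, sdlog = sdlog),
          nrow = nrow(v), dimnames = dimnames(v))
      }
      out
    })
  })
}

#' Null distribution of connectivity metrics over random hit lists
#'
#' Runs the network construction ([build_pair_matrix()],
#' [assemble_network()], [connectivity_metrics()]) on each of `n_sets` random
#' hit lists and summarizes percent included and connections per hit into
#' [null_summary()] objects.
#'
#' @inheritParams random_hit_lists
#' @param k Co-regulators per hit.
#' @return List with `percent_included` and `connections_per_hit`
#'   ([null_summary()] each) and `values` (data frame of the per-set
#'   readings).
#' @export
null_connectivity <- function(universe, table, size, k, n_sets = 100L, seed) {
  lists <- random_hit_lists(universe, table, size = size, n_sets = n_sets,
                            seed = seed)
  vals <- vapply(lists, function(hl) {
    m <- build_pair_matrix(hl, table, k = k)
    met <- connectivity_metrics(assemble_network(m, hl))
    c(met$percent_included, met$connections_per_hit)
  }, numeric(2L))
  values <- data.frame(percent_included = vals[1L, ],
                       connections_per_hit = vals[2L, ])
  list(percent_included = null_summary(values$percent_included),
       connections_per_hit = null_summary(values$connections_per_hit),
       values = values)
}

#' Null distribution of the CoRegScore over randomized expression datasets
#'
#' Each randomized dataset is analyzed exactly like an experimental one:
#' rank genes, take the top-h hits, build the pair matrix, select up to
#' `max_c` connectors, and score them in the randomized ranking. Randomized
#' datasets are weakly connected, so often only a few connectors pass the
#' threshold; sets with one or two connectors are retained (not excluded),
#' and only sets with zero selectable connectors are skipped (logged), since
#' no score exists for them.
#'
#' @param template An [expression_dataset()] (the experimental dataset).
#' @param table A [coreg_table()].
#' @param cond_a,cond_b Condition labels compared.
#' @param h Hit-list size.
#' @param k Co-regulators per hit.
#' @param max_c Maximum connectors.
#' @param direction `"up"` or `"down"`.
#' @param n_sets Number of randomized datasets (default 100).
#' @param seed Integer RNG seed.
#' @param mode Randomization mode, see [random_expression_datasets()].
#' @param noise_floor Noise floor applied before differences (default 15).
#' @param weighting Candidate weighting, see [rank_candidates()].
#' @return List with `score` (a [null_summary()]), `values` (numeric vector
#'   of per-set scores) and `n_skipped` (sets with no selectable connector).
#' @export
null_coreg_score <- function(template, table, cond_a, cond_b, h, k, max_c,
                             direction = "up", n_sets = 100L, seed,
                             mode = c("permute_genes", "iid"),
                             noise_floor = 15,
                             weighting = c("occurrence", "distinct")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  sets <- random_expression_datasets(template, n_sets = n_sets, seed = seed,
                                     mode = mode)
  scores <- numeric(0L)
  n_skipped <- 0L
  for (ds in sets) {
    ds <- apply_noise_floor(ds, noise_floor)
    deltas <- compute_differences(ds, cond_a, cond_b)
    ranking <- rank_genes(deltas, direction = direction)
    hl <- top_hits(ranking, h)
    m <- suppressMessages(build_pair_matrix(hl, table, k = k))
    sel <- suppressMessages(
      select_connectors(rank_candidates(m, weighting = weighting),
                        max_c = max_c))
    if (length(sel) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    scores <- c(scores, coreg_score(ranking, h, sel)$score)
  }
  if (n_skipped > 0L) {
    .sn_log(n_skipped, " randomized set(s) had no selectable connector and ",
            "could not be scored")
  }
  list(score = null_summary(scores), values = scores, n_skipped = n_skipped)
}
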