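#' Co-regulator tables
#'
#' A `coreg_table` stores, for each query gene, an ordered list of up to 50
#' co-regulated genes ("co-regulators") ranked by transcriptional correlation,
#' strongest first, as distributed per gene by the SPELL yeast expression
#' compendium. Only the rank order is used by the network algorithms;
#' correlation scores, when present, are retained for provenance.
#'
#' Invariants enforced on construction: no per-gene list contains duplicates,
#' a gene never lists itself, and lists are truncated to at most
#' `max_coregulators` (default 50, the length of a SPELL sheet).
#'
#' @param entries Named list. Each element is a character vector of
#'   co-regulator gene identifiers for the gene named by the element,
#'   strongest correlation first.
#' @param scores Optional named list parallel to `entries` with numeric
#'   correlation scores.
#' @param source_label Free-text provenance label.
#' @param max_coregulators Maximum stored list length; longer lists are
#'   truncated to this prefix with a warning.
#'
#' @return An object of class `coreg_table`.
#' @examples
#' tab <- coreg_table(list(GENE1 = c("GENE2", "GENE3")))
#' top_coregulators(tab, "GENE1", 1)
#' @export
coreg_table <- function(entries, scores = NULL, source_label = "",
                        max_coregulators = 50L) {
  if (!is.list(entries) || is.null(names(entries)) ||
      any(!nzchar(names(entries)))) {
    stop("`entries` must be a named list of character vectors", call. = FALSE)
  }
  if (anyDuplicated(names(entries))) {
    stop("duplicate query gene in co-regulator entries: ",
         names(entries)[duplicated(names(entries))][1L], call. = FALSE)
  }
  genes <- names(entries)
  cleaned <- vector("list", length(entries))
  names(cleaned) <- genes
  kept_scores <- if (is.null(scores)) NULL else vector("list", length(entries))
  if (!is.null(kept_scores)) names(kept_scores) <- genes
  n_self <- 0L
  n_dup <- 0L
  n_trunc <- 0L
  for (g in genes) {
    lst <- as.character(entries[[g]])
    sc <- if (is.null(scores)) NULL else as.numeric(scores[[g]])
    if (!is.null(sc) && length(sc) != length(lst)) {
      stop("score list for gene ", g, " does not match its co-regulator list",
           call. = FALSE)
    }
    keep <- lst != g
    n_self <- n_self + sum(!keep)
    lst <- lst[keep]
    if (!is.null(sc)) sc <- sc[keep]
    keep <- !duplicated(lst)
    n_dup <- n_dup + sum(!keep)
    lst <- lst[keep]
    if (!is.null(sc)) sc <- sc[keep]
    if (length(lst) > max_coregulators) {
      n_trunc <- n_trunc + 1L
      lst <- lst[seq_len(max_coregulators)]
      if (!is.null(sc)) sc <- sc[seq_len(max_coregulators)]
    }
    cleaned[[g]] <- lst
    if (!is.null(kept_scores)) kept_scores[[g]] <- sc
  }
  if (n_self > 0L) {
    .sn_warn(n_self, " self-reference(s) dropped from co-regulator lists")
  }
  if (n_dup > 0L) {
    .sn_warn(n_dup, " duplicate co-regulator(s) dropped, rank order preserved")
  }
  if (n_trunc > 0L) {
    .sn_warn(n_trunc, " list(s) truncated to ", max_coregulators,
             " co-regulators")
  }
  structure(
    list(entries = cleaned, scores = kept_scores,
         source_label = source_label),
    class = "coreg_table"
  )
}

#' @export
print.coreg_table <- function(x, ...) {
  cat(sprintf("<coreg_table> %d query genes, list lengths %s..%s%s\n",
              length(x$entries),
              if (length(x$entries)) min(lengths(x$entries)) else 0,
              if (length(x$entries)) max(lengths(x$entries)) else 0,
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]")
              else ""))
  invisible(x)
}

#' @export
length.coreg_table <- function(x) length(x$entries)

#' Read a SPELL-style co-regulator sheet
#'
#' Two tab-separated dialects are accepted, both trivially produced from SPELL
#' per-gene exports:
#' \describe{
#'   \item{`"wide"`}{one row per query gene: the gene identifier followed by
#'     its co-regulators in rank order.}
#'   \item{`"long"`}{one row per (query, co-regulator) pair with columns
#'     `query`, `coregulator`, `rank` and optionally `score`; rows may appear
#'     in any order and are sorted by rank within each query.}
#' }
#' Lines starting with `#` are ignored. Files are read as UTF-8.
#'
#' @param path Path to the sheet.
#' @param format `"wide"` or `"long"`.
#' @param ... Passed to [coreg_table()] (e.g. `max_coregulators`).
#'
#' @return A [coreg_table()].
#' @seealso [write_coreg_sheets()] for the inverse operation.
#' @export
read_coreg_sheets <- function(path, format = c("wide", "long"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("co-regulator sheet not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("empty co-regulator sheet: ", path, call. = FALSE)
  }
  if (format == "wide") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad)) {
      stop(sprintf(
        "malformed co-regulator row at line %d of %s: need a query gene and >= 1 co-regulator",
        line_no[bad[1L]], path), call. = FALSE)
    }
    entries <- lapply(fields, function(f) trimws(f[-1L]))
    names(entries) <- trimws(vapply(fields, `[[`, character(1L), 1L))
    coreg_table(entries, source_label = path, ...)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- trimws(fields[[1L]])
    need <- c("query", "coregulator", "rank")
    if (!all(need %in% header)) {
      stop("long-format sheet must have a header with columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    body <- fields[-1L]
    body_no <- line_no[-1L]
    bad <- which(lengths(body) < length(header))
    if (length(bad)) {
      stop(sprintf("malformed co-regulator row at line %d of %s",
                   body_no[bad[1L]], path), call. = FALSE)
    }
    get_col <- function(col) {
      idx <- match(col, header)
      vapply(body, function(f) trimws(f[[idx]]), character(1L))
    }
    query <- get_col("query")
    coreg <- get_col("coregulator")
    rk <- suppressWarnings(as.numeric(get_col("rank")))
    if (anyNA(rk)) {
      stop(sprintf("non-numeric rank at line %d of %s",
                   body_no[which(is.na(rk))[1L]], path), call. = FALSE)
    }
    sc <- if ("score" %in% header) {
      suppressWarnings(as.numeric(get_col("score")))
    } else NULL
    ord <- order(query, rk)
    query <- query[ord]; coreg <- coreg[ord]
    if (!is.null(sc)) sc <- sc[ord]
    entries <- split(coreg, factor(query, levels = unique(query)))
    scores <- if (is.null(sc)) NULL else {
      split(sc, factor(query, levels = unique(query)))
    }
    coreg_table(as.list(entries), scores = if (is.null(scores)) NULL else
      as.list(scores), source_label = path, ...)
  }
}

#' Write a co-regulator table to a TSV sheet
#'
#' Inverse of [read_coreg_sheets()]; writing then reading reproduces the
#' table exactly (scores are preserved only by the `"long"` dialect).
#'
#' @param table A [coreg_table()].
#' @param path Output file path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_coreg_sheets <- function(table, path, format = c("wide", "long")) {
  stopifnot(inherits(table, "coreg_table"))
  format <- match.arg(format)
  if (format == "wide") {
    lines <- vapply(names(table$entries), function(g) {
      paste(c(g, table$entries[[g]]), collapse = "\t")
    }, character(1L))
  } else {
    has_scores <- !is.null(table$scores)
    header <- c("query", "coregulator", "rank", if (has_scores) "score")
    rows <- unlist(lapply(names(table$entries), function(g) {
      crs <- table$entries[[g]]
      if (length(crs) == 0L) return(character(0L))
      sc <- if (has_scores) table$scores[[g]] else NULL
      vapply(seq_along(crs), function(i) {
        paste(c(g, crs[[i]], i, if (has_scores) format(sc[[i]], digits = 15)),
              collapse = "\t")
      }, character(1L))
    }), use.names = FALSE)
    lines <- c(paste(header, collapse = "\t"), rows)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Top-k co-regulators of a gene
#'
#' Returns the length-`min(k, stored)` prefix of the stored rank-ordered
#' co-regulator list. A gene with no entry yields an empty vector; callers
#' decide whether that is an error for their purpose.
#'
#' @param table A [coreg_table()].
#' @param gene Query gene identifier.
#' @param k Number of co-regulators requested (`>= 1`).
#' @return Character vector of at most `k` gene identifiers, rank order.
#' @export
top_coregulators <- function(table, gene, k) {
  stopifnot(inherits(table, "coreg_table"))
  .sn_assert_scalar_count(k, "k")
  lst <- table$entries[[gene]]
  if (is.null(lst)) return(character(0L))
  lst[seq_len(min(as.integer(k), length(lst)))]
}

#' Fraction of genes covered by the co-regulator table
#'
#' The SPELL-derived database does not cover every gene of the genome; genes
#' without an entry are excluded when random hit lists are drawn (typically
#' 10--15\% of the yeast genome).
#'
#' @param table A [coreg_table()].
#' @param genes Non-empty character vector of gene identifiers.
#' @return Fraction in `[0, 1]` of `genes` that have a table entry.
#' @export
coverage_fraction <- function(table, genes) {
  stopifnot(inherits(table, "coreg_table"))
  if (length(genes) == 0L) {
    stop("`genes` must be non-empty", call. = FALSE)
  }
  mean(genes %in% names(table$entries))
}
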