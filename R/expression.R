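#' Expression datasets
#'
#' Container for a normalized expression matrix (genes in rows, samples in
#' columns) together with the condition label of each sample. Values are
#' expected on the MAS5/RMA intensity scale (non-negative).
#'
#' @param values Numeric matrix, genes x samples, with unique rownames (gene
#'   identifiers) and colnames (sample names). All values must be finite and
#'   non-negative.
#' @param conditions Named character vector mapping every sample name to a
#'   condition label.
#' @param normalization One of `"MAS5"`, `"RMA"`, `"PCL"`, `"unknown"`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, conditions,
                               normalization = c("unknown", "MAS5", "RMA",
                                                 "PCL")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifier: ",
         rownames(values)[duplicated(rownames(values))][1L], call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  conditions <- vapply(conditions, as.character, character(1L))
  missing <- setdiff(colnames(values), names(conditions))
  if (length(missing)) {
    stop("no condition label for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  conditions <- conditions[colnames(values)]
  structure(
    list(values = values, conditions = conditions,
         normalization = normalization),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%s), conditions: %s\n",
              nrow(x$values), ncol(x$values), x$normalization,
              paste(unique(x$conditions), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression table
#'
#' Two dialects:
#' \describe{
#'   \item{`"tsv"`}{header row of sample names, first column gene identifiers,
#'     remaining cells numeric. Condition labels come from `conditions` or a
#'     YAML sidecar (`conditions_file`) mapping sample name to label.}
#'   \item{`"pcl"`}{Stanford PCL as served by SPELL: columns `GID`/`YORF`,
#'     `NAME`, `GWEIGHT`, then data columns; an `EWEIGHT` row may follow the
#'     header. `GWEIGHT` and `EWEIGHT` are parsed and discarded with a log
#'     note.}
#' }
#'
#' @param path File path.
#' @param format `"tsv"` or `"pcl"`.
#' @param conditions Named character vector (sample -> condition label).
#' @param conditions_file YAML file with a `sample: condition` mapping, used
#'   when `conditions` is not given.
#' @param normalization Normalization tag to record; defaults to `"PCL"` for
#'   PCL input and `"unknown"` otherwise.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, format = c("tsv", "pcl"),
                                  conditions = NULL, conditions_file = NULL,
                                  normalization = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("expression table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (format == "pcl") {
    cols <- names(raw)
    ann_cols <- which(toupper(cols) %in% c("GID", "YORF", "NAME", "GWEIGHT"))
    if (length(ann_cols) == 0L) {
      stop("PCL file lacks GID/YORF annotation columns: ", path,
           call. = FALSE)
    }
    gene_col <- ann_cols[[1L]]
    if ("GWEIGHT" %in% toupper(cols)) {
      .sn_log("PCL GWEIGHT column parsed and discarded")
    }
    eweight <- toupper(trimws(as.character(raw[[gene_col]]))) == "EWEIGHT"
    if (any(eweight)) {
      .sn_log("PCL EWEIGHT row parsed and discarded")
      raw <- raw[!eweight, , drop = FALSE]
    }
    genes <- as.character(raw[[gene_col]])
    data <- raw[, -ann_cols, drop = FALSE]
  } else {
    genes <- as.character(raw[[1L]])
    data <- raw[, -1L, drop = FALSE]
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene row in ", path, ": ",
         genes[duplicated(genes)][1L], call. = FALSE)
  }
  for (j in seq_along(data)) {
    v <- data[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num) && !all(is.na(v))) {
        i <- which(is.na(num) & !is.na(v))[1L]
        stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                     path, genes[[i]], names(data)[[j]]), call. = FALSE)
      }
      data[[j]] <- num
    }
  }
  values <- as.matrix(data)
  rownames(values) <- genes
  if (is.null(conditions)) {
    if (!is.null(conditions_file)) {
      cmap <- yaml::read_yaml(conditions_file)
      conditions <- vapply(cmap, as.character, character(1L))
    } else {
      # default: every sample its own condition; caller must relabel before
      # computing differences
      conditions <- stats::setNames(colnames(values), colnames(values))
    }
  }
  if (is.null(normalization)) {
    normalization <- if (format == "pcl") "PCL" else "unknown"
  }
  expression_dataset(values, conditions, normalization = normalization)
}

#' Write an expression dataset as TSV or PCL
#'
#' @param ds An [expression_dataset()].
#' @param path Output path.
#' @param format `"tsv"` or `"pcl"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, format = c("tsv", "pcl")) {
  stopifnot(inherits(ds, "expression_dataset"))
  format <- match.arg(format)
  v <- ds$values
  fmt_row <- function(cells) paste(cells, collapse = "\t")
  if (format == "tsv") {
    lines <- c(
      fmt_row(c("GENE", colnames(v))),
      vapply(seq_len(nrow(v)), function(i) {
        fmt_row(c(rownames(v)[i], format(v[i, ], digits = 15, trim = TRUE,
                                         scientific = FALSE)))
      }, character(1L))
    )
  } else {
    lines <- c(
      fmt_row(c("YORF", "NAME", "GWEIGHT", colnames(v))),
      fmt_row(c("EWEIGHT", "", "", rep("1", ncol(v)))),
      vapply(seq_len(nrow(v)), function(i) {
        fmt_row(c(rownames(v)[i], rownames(v)[i], "1",
                  format(v[i, ], digits = 15, trim = TRUE,
                         scientific = FALSE)))
      }, character(1L))
    )
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Clamp expression values to a noise floor
#'
#' MAS5 intensities below a noise threshold are indistinguishable from
#' background; they are clamped up to the floor rather than removed, so the
#' ranked gene list keeps its full length and genes whose values are all noise
#' get an expression difference of zero. The conventional MAS5 floor is 15.
#'
#' @param ds An [expression_dataset()].
#' @param floor Non-negative noise threshold.
#' @return The dataset with every value below `floor` replaced by `floor`.
#' @export
apply_noise_floor <- function(ds, floor = 15) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor < 0) {
    stop("`floor` must be a single non-negative number", call. = FALSE)
  }
  ds$values[ds$values < floor] <- floor
  ds
}

#' Signed expression differences between two conditions
#'
#' For each gene, the difference of mean log2 intensities:
#' `delta(g) = mean(log2 values in cond_a) - mean(log2 values in cond_b)`.
#' Positive values mean higher expression in `cond_a`. Apply a positive noise
#' floor first ([apply_noise_floor()]) so that logs are defined; a zero value
#' is an error instructing exactly that. `method = "raw"` uses the difference
#' of plain means instead (no positivity requirement).
#'
#' @param ds An [expression_dataset()].
#' @param cond_a,cond_b Condition labels present in the dataset.
#' @param method `"log2"` (default) or `"raw"`.
#' @return Named numeric vector of per-gene deltas.
#' @export
compute_differences <- function(ds, cond_a, cond_b,
                                method = c("log2", "raw")) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% ds$conditions) {
      stop("unknown condition label: ", cond, call. = FALSE)
    }
  }
  a <- ds$values[, ds$conditions == cond_a, drop = FALSE]
  b <- ds$values[, ds$conditions == cond_b, drop = FALSE]
  if (method == "log2") {
    if (any(a == 0) || any(b == 0)) {
      stop("zero expression values: apply a positive noise floor ",
           "(apply_noise_floor) before taking log2 differences",
           call. = FALSE)
    }
    rowMeans(log2(a)) - rowMeans(log2(b))
  } else {
    rowMeans(a) - rowMeans(b)
  }
}

#' Rank all genes by signed expression difference
#'
#' Sorts every gene of the experiment by its delta, strongest first in the
#' requested direction (`"up"`: descending delta; `"down"`: ascending).
#' Ties are broken by gene identifier so rankings are fully deterministic.
#'
#' @param deltas Named numeric vector from [compute_differences()].
#' @param direction `"up"` or `"down"`.
#' @return An object of class `differential_ranking`: a data frame with
#'   columns `gene`, `delta`, `rank` (1 = strongest in the direction), plus
#'   attributes `direction` and `N`.
#' @export
rank_genes <- function(deltas, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(deltas) == 0L) {
    stop("`deltas` must be non-empty", call. = FALSE)
  }
  if (is.null(names(deltas)) || anyDuplicated(names(deltas))) {
    stop("`deltas` must be uniquely named by gene", call. = FALSE)
  }
  ord <- if (direction == "up") {
    order(-deltas, names(deltas), method = "radix")
  } else {
    order(deltas, names(deltas), method = "radix")
  }
  out <- data.frame(gene = names(deltas)[ord],
                    delta = unname(deltas[ord]),
                    rank = seq_along(deltas),
                    stringsAsFactors = FALSE)
  structure(out, direction = direction, N = length(deltas),
            class = c("differential_ranking", "data.frame"))
}

#' @export
print.differential_ranking <- function(x, ...) {
  cat(sprintf("<differential_ranking> direction=%s, N=%d\n",
              attr(x, "direction"), attr(x, "N")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Hit list: the top of a differential ranking
#'
#' @param ranking A `differential_ranking` from [rank_genes()].
#' @param h Number of hits, `1 <= h <= N`.
#' @return An object of class `hit_list` with fields `genes` (rank order),
#'   `direction`, `h` and `source` (`"ranking"`).
#' @export
top_hits <- function(ranking, h) {
  stopifnot(inherits(ranking, "differential_ranking"))
  .sn_assert_scalar_count(h, "h")
  N <- attr(ranking, "N")
  if (h > N) {
    stop(sprintf("h = %d exceeds the ranking size N = %d", h, N),
         call. = FALSE)
  }
  hit_list(ranking$gene[seq_len(h)], direction = attr(ranking, "direction"),
           source = "ranking")
}

#' Construct a hit list directly
#'
#' Hit lists may come from [top_hits()] or be supplied externally (one gene
#' per line). Externally supplied hit lists carry `source = "external"`; the
#' CoRegScore then needs a separately supplied full ranking.
#'
#' @param genes Character vector of hit genes in rank order, no duplicates.
#' @param direction `"up"` or `"down"`.
#' @param source `"ranking"` or `"external"`.
#' @return An object of class `hit_list`.
#' @export
hit_list <- function(genes, direction = c("up", "down"),
                     source = c("external", "ranking")) {
  direction <- match.arg(direction)
  source <- match.arg(source)
  genes <- as.character(genes)
  if (length(genes) < 1L) stop("a hit list needs >= 1 gene", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("duplicate gene in hit list: ", genes[duplicated(genes)][1L],
         call. = FALSE)
  }
  structure(list(genes = genes, direction = direction, h = length(genes),
                 source = source),
            class = "hit_list")
}

#' @export
print.hit_list <- function(x, ...) {
  cat(sprintf("<hit_list> %d %s-regulated hits (%s)\n", x$h, x$direction,
              x$source))
  invisible(x)
}

#' Read a hit list from a plain text file
#'
#' One gene per line; an optional second tab-separated column with the gene's
#' expression delta is ignored here (rank order is taken from line order).
#'
#' @param path File path.
#' @param direction `"up"` or `"down"`.
#' @return A [hit_list()] with `source = "external"`.
#' @export
read_hit_list <- function(path, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("hit list not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty hit list: ", path, call. = FALSE)
  genes <- vapply(strsplit(lines, "\t", fixed = TRUE), function(f)
    trimws(f[[1L]]), character(1L))
  hit_list(genes, direction = direction, source = "external")
}
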