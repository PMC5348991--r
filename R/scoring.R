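#' CoRegScore: rank-sum quality of connector predictions
#'
#' The CoRegScore asks where the predicted connectors fall in the full
#' expression ranking of the experiment. A perfect prediction places the C
#' connectors immediately after the h hits (ranks h+1 .. h+C), an entirely
#' wrong prediction places them at the very bottom (ranks N-C+1 .. N), and a
#' useless prediction scatters them uniformly over the non-hit ranks.
#'
#' With connector ranks r_1..r_C and S = sum(r_i), the score is the affine
#' function of S anchored at those three reference placements:
#' \deqn{S_{best} = \sum_{i=h+1}^{h+C} i, \quad
#'       S_{worst} = \sum_{i=N-C+1}^{N} i, \quad
#'       S_{mid} = (S_{best} + S_{worst})/2 = C(h + 1 + N)/2}
#' \deqn{score = 100 \, (S_{mid} - S) / (S_{mid} - S_{best})}
#' so score = +100 at the best packing, -100 at the worst, and its
#' expectation is 0 for connectors drawn uniformly without replacement from
#' the non-hit ranks (the uniform mean rank is (h+1+N)/2).
#'
#' @param ranking A `differential_ranking` over all N genes of the
#'   experiment, same direction as the hit list the connectors extend.
#' @param h Hit-list size; connectors must all rank strictly below h.
#' @param connector_genes Character vector of predicted connector genes
#'   (C >= 1).
#' @param missing How to treat connectors absent from the ranking:
#'   `"error"` (default) or `"skip"` (drop them, reducing C, with a warning).
#' @return List of class `coreg_score_result` with fields `score`, `S`,
#'   `S_best`, `S_worst`, `S_mid`, `C`, `N`, `h`, `connector_ranks`.
#' @export
coreg_score <- function(ranking, h, connector_genes,
                        missing = c("error", "skip")) {
  stopifnot(inherits(ranking, "differential_ranking"))
  missing <- match.arg(missing)
  h <- .sn_assert_scalar_count(h, "h")
  connector_genes <- as.character(connector_genes)
  if (length(connector_genes) == 0L) {
    stop("no connectors to score", call. = FALSE)
  }
  N <- attr(ranking, "N")
  idx <- match(connector_genes, ranking$gene)
  if (anyNA(idx)) {
    absent <- connector_genes[is.na(idx)]
    if (missing == "error") {
      stop("connector gene(s) missing from the ranking: ",
           paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
    }
    .sn_warn(length(absent), " connector(s) missing from the ranking ",
             "skipped; C reduced accordingly")
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) {
      stop("no connectors to score", call. = FALSE)
    }
  }
  r <- ranking$rank[idx]
  if (any(r <= h)) {
    stop("connector gene(s) rank within the hit list (rank <= h): ",
         paste(utils::head(connector_genes[r <= h], 5L), collapse = ", "),
         call. = FALSE)
  }
  C <- length(r)
  if (N <= h + C) {
    stop(sprintf("ranking too small: need N > h + C (N=%d, h=%d, C=%d)",
                 N, h, C), call. = FALSE)
  }
  S <- sum(r)
  S_best <- sum(seq.int(h + 1L, h + C))
  S_worst <- sum(seq.int(N - C + 1L, N))
  S_mid <- (S_best + S_worst) / 2
  structure(
    list(score = 100 * (S_mid - S) / (S_mid - S_best),
         S = S, S_best = S_best, S_worst = S_worst, S_mid = S_mid,
         C = C, N = N, h = h, connector_ranks = sort(r)),
    class = "coreg_score_result"
  )
}

#' @export
print.coreg_score_result <- function(x, ...) {
  cat(sprintf(
    "<coreg_score_result> score=%.2f (C=%d connectors, h=%d hits, N=%d)\n",
    x$score, x$C, x$h, x$N))
  invisible(x)
}

#' Empirical null summary of a network metric
#'
#' Mean and sample standard deviation (n-1 denominator) of a metric evaluated
#' over random sets — typically 100 random hit lists or 100 randomized
#' expression datasets.
#'
#' @param metric_values Numeric vector of at least two metric readings.
#' @return List of class `null_summary` with `mu`, `sigma`, `n_sets`.
#' @export
null_summary <- function(metric_values) {
  metric_values <- as.numeric(metric_values)
  if (length(metric_values) < 2L) {
    stop("need >= 2 metric values to summarize a null", call. = FALSE)
  }
  if (any(!is.finite(metric_values))) {
    stop("metric values must all be finite", call. = FALSE)
  }
  structure(
    list(mu = mean(metric_values), sigma = stats::sd(metric_values),
         n_sets = length(metric_values)),
    class = "null_summary"
  )
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("<null_summary> mu=%.4g, sigma=%.4g over %d sets\n",
              x$mu, x$sigma, x$n_sets))
  invisible(x)
}

#' Z-score and one-tailed p-value against an empirical null
#'
#' Z = (X - mu) / sigma, with mu and sigma taken from the random-set null
#' summary; p is the upper-tail standard-normal probability, i.e. the chance
#' of a random set giving a reading higher than X.
#'
#' @param X Experimental reading of the metric.
#' @param null A [null_summary()] with `sigma > 0`.
#' @return List of class `z_test_result` with `X`, `Z`, `p`.
#' @export
z_test <- function(X, null) {
  stopifnot(inherits(null, "null_summary"))
  if (!is.numeric(X) || length(X) != 1L || !is.finite(X)) {
    stop("`X` must be a single finite number", call. = FALSE)
  }
  if (null$sigma <= 0) {
    stop("degenerate null: sigma must be > 0", call. = FALSE)
  }
  Z <- (X - null$mu) / null$sigma
  structure(
    list(X = X, Z = Z, p = stats::pnorm(Z, lower.tail = FALSE)),
    class = "z_test_result"
  )
}

#' @export
print.z_test_result <- function(x, ...) {
  cat(sprintf("<z_test_result> X=%.4g, Z=%.3f, one-tailed p=%.4g\n",
              x$X, x$Z, x$p))
  invisible(x)
}
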