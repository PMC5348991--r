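#' Specification for a synthetic fixture
#'
#' Parameters of the planted-module generator. The defaults describe a small
#' but realistic yeast-like benchmark: 2000 genes, three co-regulated modules
#' of 30 genes that are all up-regulated two-fold-squared (2 log2 units) in
#' condition A, co-regulator lists of length 20 in which 70\% of the entries
#' are same-module partners, MAS5-scale log-normal baselines, and three
#' replicates per condition with multiplicative log-normal noise
#' (sdlog 0.5).
#'
#' @param n_genes Total genes.
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module (`n_modules * module_size <= n_genes`).
#' @param coreg_within_module_fraction Fraction of each module gene's
#'   co-regulator list drawn from its own module (top-ranked), in `[0, 1]`.
#' @param list_length Co-regulator list length (`1..50`).
#' @param effect_size Log2 expression effect of differential modules in
#'   condition A; may be a vector of length `n_modules` (signed).
#' @param noise_sd Standard deviation (natural-log scale) of the
#'   multiplicative log-normal noise on every expression value.
#' @param replicates_per_condition Samples per condition.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensity
#'   parameters (natural log), defaulting to a median of ~150 MAS5 units.
#' @param seed Integer RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_modules = 3L,
                           module_size = 30L,
                           coreg_within_module_fraction = 0.7,
                           list_length = 20L, effect_size = 2,
                           noise_sd = 0.5, replicates_per_condition = 3L,
                           baseline_meanlog = log(150), baseline_sdlog = 1,
                           seed = 1L) {
  n_genes <- .sn_assert_scalar_count(n_genes, "n_genes")
  n_modules <- .sn_assert_scalar_count(n_modules, "n_modules", minimum = 0L)
  module_size <- .sn_assert_scalar_count(module_size, "module_size")
  list_length <- .sn_assert_scalar_count(list_length, "list_length")
  replicates_per_condition <-
    .sn_assert_scalar_count(replicates_per_condition,
                            "replicates_per_condition")
  if (n_modules * module_size > n_genes) {
    stop("infeasible spec: n_modules * module_size exceeds n_genes",
         call. = FALSE)
  }
  if (list_length > 50L) {
    stop("infeasible spec: list_length exceeds 50 (SPELL sheet length)",
         call. = FALSE)
  }
  if (coreg_within_module_fraction < 0 || coreg_within_module_fraction > 1) {
    stop("coreg_within_module_fraction must be in [0, 1]", call. = FALSE)
  }
  n_within <- round(coreg_within_module_fraction * list_length)
  if (n_modules > 0L && n_within > module_size - 1L) {
    stop("infeasible spec: within-module list share exceeds module_size - 1",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  effects <- rep_len(as.numeric(effect_size), max(n_modules, 1L))
  structure(
    list(n_genes = n_genes, n_modules = n_modules,
         module_size = module_size,
         coreg_within_module_fraction = coreg_within_module_fraction,
         list_length = list_length, effects = effects[seq_len(n_modules)],
         noise_sd = noise_sd,
         replicates_per_condition = replicates_per_condition,
         baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic fixture with planted co-regulated modules
#'
#' Produces a matched triple — co-regulator table, expression dataset, and
#' ground truth — emulating the structure the network method assumes:
#' \itemize{
#'   \item every module gene's co-regulator list starts with
#'     `round(fraction * list_length)` randomly ordered same-module partners
#'     and is padded with genes drawn uniformly from the rest of the genome
#'     (so a fraction of zero reduces module genes to background behavior);
#'   \item background genes receive fully random lists;
#'   \item expression values are log-normal baselines, multiplied by
#'     `2^effect` for differential-module genes in condition A, with
#'     multiplicative log-normal noise (`sdlog = noise_sd`) everywhere.
#' }
#' All randomness derives from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_fixture` with elements `coreg`
#'   ([coreg_table()]), `expression` ([expression_dataset()], conditions
#'   `"A"` and `"B"`), `universe` ([gene_universe()]), and `truth` (list with
#'   `module_of_gene`, a named integer vector with `NA` for background genes,
#'   and `module_effects`, the signed log2 effect per module).
#' @export
generate_fixture <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  n_mod_genes <- spec$n_modules * spec$module_size
  module_of <- rep(NA_integer_, spec$n_genes)
  if (spec$n_modules > 0L) {
    module_of[seq_len(n_mod_genes)] <-
      rep(seq_len(spec$n_modules), each = spec$module_size)
  }
  names(module_of) <- genes
  n_within <- round(spec$coreg_within_module_fraction * spec$list_length)

  seeds <- .sn_child_seeds(spec$seed, 2L)

  entries <- .sn_with_seed(seeds[[1L]], {
    lapply(seq_len(spec$n_genes), function(i) {
      g <- genes[[i]]
      mod <- module_of[[i]]
      if (!is.na(mod) && n_within > 0L) {
        partners <- genes[which(module_of == mod)]
        partners <- setdiff(partners, g)
        within <- sample(partners, n_within)
        # pad uniformly from everything not already listed, so that at
        # fraction 0 module genes are indistinguishable from background
        pool <- setdiff(genes, c(g, within))
        pad <- sample(pool, spec$list_length - n_within)
        c(within, pad)
      } else {
        sample(setdiff(genes, g), spec$list_length)
      }
    })
  })
  names(entries) <- genes
  coreg <- coreg_table(entries, source_label = "synthetic planted-module table")

  reps <- spec$replicates_per_condition
  samples <- c(sprintf("A_rep%d", seq_len(reps)),
               sprintf("B_rep%d", seq_len(reps)))
  conditions <- stats::setNames(rep(c("A", "B"), each = reps), samples)
  effect_of_gene <- numeric(spec$n_genes)
  in_module <- !is.na(module_of)
  effect_of_gene[in_module] <- spec$effects[module_of[in_module]]
  values <- .sn_with_seed(seeds[[2L]], {
    baseline <- stats::rlnorm(spec$n_genes,
                              meanlog = spec$baseline_meanlog,
                              sdlog = spec$baseline_sdlog)
    noise <- matrix(stats::rlnorm(spec$n_genes * 2L * reps, 0,
                                  spec$noise_sd),
                    nrow = spec$n_genes)
    signal <- cbind(
      matrix(rep(baseline * 2 ^ effect_of_gene, reps), ncol = reps),
      matrix(rep(baseline, reps), ncol = reps)
    )
    m <- signal * noise
    dimnames(m) <- list(genes, samples)
    m
  })
  ds <- expression_dataset(values, conditions, normalization = "MAS5")

  structure(
    list(coreg = coreg, expression = ds,
         universe = gene_universe(genes,
                                  source_label = "synthetic gene universe"),
         truth = list(module_of_gene = module_of,
                      module_effects = spec$effects),
         spec = spec),
    class = "synthetic_fixture"
  )
}

#' @export
print.synthetic_fixture <- function(x, ...) {
  cat(sprintf(
    "<synthetic_fixture> %d genes, %d planted modules of %d (seed %d)\n",
    x$spec$n_genes, x$spec$n_modules, x$spec$module_size, x$spec$seed))
  invisible(x)
}

#' Write a synthetic fixture to disk in the package's external dialects
#'
#' Emits the co-regulation sheet (wide TSV), the expression table (TSV and
#' PCL), a condition sidecar (YAML), the gene-universe list and the ground
#' truth (YAML) under `dir`, exercising every reader the package provides.
#'
#' @param fixture A `synthetic_fixture` from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "synthetic_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    coreg = file.path(dir, "coreg_sheet.tsv"),
    expression_tsv = file.path(dir, "expression.tsv"),
    expression_pcl = file.path(dir, "expression.pcl"),
    conditions = file.path(dir, "conditions.yaml"),
    universe = file.path(dir, "universe.txt"),
    truth = file.path(dir, "ground_truth.yaml")
  )
  write_coreg_sheets(fixture$coreg, paths[["coreg"]], format = "wide")
  write_expression_table(fixture$expression, paths[["expression_tsv"]],
                         format = "tsv")
  write_expression_table(fixture$expression, paths[["expression_pcl"]],
                         format = "pcl")
  yaml::write_yaml(as.list(fixture$expression$conditions),
                   paths[["conditions"]])
  writeLines(fixture$universe$genes, paths[["universe"]], useBytes = TRUE)
  truth <- fixture$truth
  yaml::write_yaml(
    list(module_of_gene = lapply(as.list(truth$module_of_gene), function(m)
      if (is.na(m)) "none" else as.integer(m)),
         module_effects = as.numeric(truth$module_effects)),
    paths[["truth"]])
  invisible(paths)
}
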