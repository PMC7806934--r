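#' Two-group expression study container
#'
#' Minimal container for a genes x samples expression matrix with case /
#' control labels, the input of the per-gene differential calls feeding the
#' cross-study intersection statistic.
#'
#' @param matrix numeric genes x samples matrix with rownames = gene ids.
#' @param group_labels character vector, one per column, values `"case"` or
#'   `"control"`; both groups must be nonempty.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(matrix, group_labels) {
  if (is.null(rownames(matrix)))
    stop("expression matrix needs gene ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene ids", call. = FALSE)
  if (length(group_labels) != ncol(matrix))
    stop("one group label per sample required", call. = FALSE)
  if (!all(group_labels %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (!all(c("case", "control") %in% group_labels))
    stop("both groups must be nonempty", call. = FALSE)
  structure(list(matrix = matrix, group_labels = group_labels),
            class = "expression_study")
}

#' Expression-pair simulation parameters
#'
#' Parameters for a pair of two-group expression studies over a shared gene
#' universe with a planted set of genes up-regulated in the cases of both
#' studies (the signal the intersection statistic should recover),
#' study-specific up-regulated genes, and null genes.
#'
#' @param n_genes size of the shared gene universe.
#' @param n_per_group samples per group in each study.
#' @param n_shared_up genes planted up-regulated in both studies.
#' @param n_specific_up genes planted up-regulated in one study only
#'   (that many per study).
#' @param effect_size standardized mean difference of planted genes
#'   (case mean shift = `effect_size * noise_sd`).
#' @param noise_sd residual SD on the expression scale.
#' @param list_size,list_enrichment size of the fixed gene list drawn by
#'   [generate_gene_list()] and the fraction of it drawn from the planted
#'   shared-up set.
#' @param seed optional integer seed.
#' @return an object of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 1000L, n_per_group = 20L,
                                  n_shared_up = 50L, n_specific_up = 50L,
                                  effect_size = 2, noise_sd = 1,
                                  list_size = 100L, list_enrichment = 0.8,
                                  seed = NULL) {
  if (n_genes < 1 || n_per_group < 2)
    stop("need n_genes >= 1 and n_per_group >= 2", call. = FALSE)
  if (n_shared_up + 2 * n_specific_up > n_genes)
    stop("planted gene sets exceed the gene universe", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (list_enrichment < 0 || list_enrichment > 1)
    stop("list_enrichment must lie in [0, 1]", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 n_shared_up = as.integer(n_shared_up),
                 n_specific_up = as.integer(n_specific_up),
                 effect_size = effect_size, noise_sd = noise_sd,
                 list_size = as.integer(list_size),
                 list_enrichment = list_enrichment, seed = seed),
            class = "expression_sim_params")
}

sim_one_study <- function(gene_ids, up_genes, n_per_group, shift, noise_sd) {
  n_genes <- length(gene_ids)
  n <- 2L * n_per_group
  mat <- matrix(stats::rnorm(n_genes * n, mean = 8, sd = noise_sd),
                nrow = n_genes, ncol = n,
                dimnames = list(gene_ids,
                                sprintf("S%03d", seq_len(n))))
  groups <- rep(c("case", "control"), each = n_per_group)
  if (length(up_genes))
    mat[up_genes, groups == "case"] <- mat[up_genes, groups == "case"] + shift
  expression_study(mat, groups)
}

#' Simulate a pair of expression studies with planted shared signal
#'
#' Both studies share the same gene universe. The first `n_shared_up` genes
#' are up-regulated (case mean + `effect_size * noise_sd`) in both studies;
#' the next `n_specific_up` genes in study A only and the following
#' `n_specific_up` in study B only; the rest are null.
#'
#' @param params an [expression_sim_params()].
#' @return list with `study_a`, `study_b` ([expression_study()] objects) and
#'   `planted` (named list of gene-id vectors: `shared_up`, `a_only_up`,
#'   `b_only_up`).
#' @export
generate_expression_pair <- function(params) {
  stopifnot(inherits(params, "expression_sim_params"))
  run <- function() {
    ids <- sprintf("G%05d", seq_len(params$n_genes))
    shared <- ids[seq_len(params$n_shared_up)]
    a_only <- ids[params$n_shared_up + seq_len(params$n_specific_up)]
    b_only <- ids[params$n_shared_up + params$n_specific_up +
                    seq_len(params$n_specific_up)]
    shift <- params$effect_size * params$noise_sd
    sa <- sim_one_study(ids, c(shared, a_only), params$n_per_group, shift,
                        params$noise_sd)
    sb <- sim_one_study(ids, c(shared, b_only), params$n_per_group, shift,
                        params$noise_sd)
    list(study_a = sa, study_b = sb,
         planted = list(shared_up = shared, a_only_up = a_only,
                        b_only_up = b_only))
  }
  if (!is.null(params$seed)) withr::with_seed(params$seed, run()) else run()
}

#' Draw a fixed gene list enriched for the planted shared-up genes
#'
#' Emulates a curated candidate list (e.g. genes harbouring a retrotransposon
#' family) used by the list-variant intersection: a fraction
#' `list_enrichment` of the list is drawn from the planted shared-up genes,
#' the remainder from the null genes.
#'
#' @param params an [expression_sim_params()].
#' @param planted the `planted` element of [generate_expression_pair()].
#' @return character vector of gene ids.
#' @export
generate_gene_list <- function(params, planted) {
  stopifnot(inherits(params, "expression_sim_params"))
  run <- function() {
    ids <- sprintf("G%05d", seq_len(params$n_genes))
    n_from_planted <- min(round(params$list_enrichment * params$list_size),
                          length(planted$shared_up))
    nulls <- setdiff(ids, c(planted$shared_up, planted$a_only_up,
                            planted$b_only_up))
    n_from_null <- min(params$list_size - n_from_planted, length(nulls))
    sort(c(sample(planted$shared_up, n_from_planted),
           sample(nulls, n_from_null)))
  }
  if (!is.null(params$seed)) withr::with_seed(params$seed + 1L, run()) else run()
}

#' Write / read an expression study as TSV
#'
#' Layout: genes x samples, first row holds the per-sample group labels
#' (`case` / `control`), gene ids in the first column.
#'
#' @param study an [expression_study()].
#' @param path TSV file path.
#' @export
write_expression_tsv <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  hdr <- c("gene_id", colnames(study$matrix))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(paste(c("group", study$group_labels), collapse = "\t"), con)
  utils::write.table(cbind(gene_id = rownames(study$matrix), study$matrix),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path, n = 2L)
  groups <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  df <- utils::read.delim(path, skip = 2L, header = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  colnames(mat) <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  expression_study(mat, groups)
}
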