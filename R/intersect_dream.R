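#' Per-gene differential-expression calls
#'
#' Row-wise two-sample t-tests (equal-variance by default, the classic
#' microarray convention; Welch optional) of case vs control. A gene is
#' called `up` when `p < alpha` and the case mean exceeds the control mean,
#' `down` when `p < alpha` with the opposite sign, else `ns`. No
#' multiple-testing correction is applied: the downstream intersection
#' statistic operates on the raw per-gene calls.
#'
#' @param study an [expression_study()] with >= 2 samples per group.
#' @param alpha per-gene significance threshold (default 0.05).
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return `data.frame`: `gene`, `mean_case`, `mean_control`,
#'   `t_statistic`, `p_value`, `direction` (`up`/`down`/`ns`).
#' @export
call_genes <- function(study, alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  case <- study$matrix[, study$group_labels == "case", drop = FALSE]
  ctrl <- study$matrix[, study$group_labels == "control", drop = FALSE]
  nx <- ncol(case); ny <- ncol(ctrl)
  if (nx < 2 || ny < 2) stop("need >= 2 samples per group", call. = FALSE)
  mx <- rowMeans(case); my <- rowMeans(ctrl)
  vx <- rowSums((case - mx)^2) / (nx - 1)
  vy <- rowSums((ctrl - my)^2) / (ny - 1)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(mx))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows (zero pooled variance): identical means -> ns
  zero_se <- se == 0
  tstat[zero_se & mx == my] <- 0
  p[zero_se & mx == my] <- 1
  p[zero_se & mx != my] <- 0
  tstat[zero_se & mx != my] <- sign(mx - my)[zero_se & mx != my] * Inf
  direction <- ifelse(p < alpha, ifelse(mx > my, "up", "down"), "ns")
  data.frame(gene = rownames(study$matrix),
             mean_case = mx, mean_control = my,
             t_statistic = tstat, p_value = p, direction = direction,
             row.names = NULL)
}

# 2x2 association test between two logical gene indicators over a shared
# universe: chi-squared without continuity correction, falling back to
# Fisher's exact test when any expected cell count is < 5; odds ratio with
# Haldane-Anscombe +0.5 on zero cells.
intersection_2x2 <- function(in_a, in_b, genes) {
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  c_ <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  tab <- matrix(c(a, c_, b, d), nrow = 2)
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  degenerate <- any(rs == 0) || any(cs == 0)
  if (degenerate) {
    p <- 1
    method <- "degenerate-margin"
  } else {
    expected <- outer(rs, cs) / n
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      method <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      method <- "chisq"
    }
  }
  haldane <- any(c(a, b, c_, d) == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
  structure(list(
    table = c(in_both = a, a_only = b, b_only = c_, neither = d),
    p_value = p, odds_ratio = or, method = method,
    haldane_corrected = haldane, degenerate_margin = degenerate,
    genes_in_both = sort(genes[in_a & in_b])),
    class = "intersection_result")
}

#' Cross-study intersection of differential calls
#'
#' The marker-discovery statistic: over the shared gene universe, a 2x2
#' table of called-in-direction in study A x called-in-direction in study B,
#' tested for association (chi-squared, Fisher when sparse) with an odds
#' ratio. An odds ratio above 1 with a small p-value means the two studies
#' share more same-direction differential genes than chance.
#'
#' @param calls_a,calls_b per-gene call tables from [call_genes()].
#' @param direction which calls to intersect: `"up"` or `"down"`.
#' @return an `intersection_result`: 2x2 `table` (in-both / A-only /
#'   B-only / neither; cells sum to the shared-universe size), `p_value`,
#'   `odds_ratio`, `method`, flags, and `genes_in_both`.
#' @export
intersect_studies <- function(calls_a, calls_b, direction = c("up", "down")) {
  direction <- match.arg(direction)
  universe <- intersect(calls_a$gene, calls_b$gene)
  if (length(universe) == 0) stop("empty shared gene universe", call. = FALSE)
  da <- calls_a$direction[match(universe, calls_a$gene)]
  db <- calls_b$direction[match(universe, calls_b$gene)]
  intersection_2x2(da == direction, db == direction, universe)
}

#' Intersection of differential calls with a fixed gene list
#'
#' Same 2x2 machinery as [intersect_studies()], crossing the study's
#' directional calls with membership in a supplied candidate list
#' (restricted to the study universe).
#'
#' @param calls per-gene call table from [call_genes()].
#' @param gene_list character vector of candidate gene ids.
#' @param direction `"up"` or `"down"`.
#' @return an `intersection_result` (see [intersect_studies()]).
#' @export
intersect_with_list <- function(calls, gene_list, direction = c("up", "down")) {
  direction <- match.arg(direction)
  universe <- calls$gene
  gene_list <- intersect(gene_list, universe)
  if (length(gene_list) == 0)
    stop("gene list empty after restriction to the study universe",
         call. = FALSE)
  d <- calls$direction
  intersection_2x2(d == direction, universe %in% gene_list, universe)
}

#' Genes shared by several up-regulated lists
#'
#' Order-stable (alphabetical) set intersection of two or more gene lists,
#' e.g. the in-both lists of several pairwise intersections.
#'
#' @param lists list of character vectors (>= 2).
#' @return sorted character vector of genes present in every list.
#' @export
shared_upregulated <- function(lists) {
  if (length(lists) < 2) stop("need at least two gene lists", call. = FALSE)
  sort(Reduce(intersect, lists))
}
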