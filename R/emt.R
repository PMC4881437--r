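# Single-sample epithelial-mesenchymal transition scoring: rank-based
# running-sum enrichment per sample (ssGSEA), extreme-phenotype signature
# refinement (permutation q = 0 plus ROC), and the normalised EMT score in
# [-1, +1] (-1 fully epithelial, +1 fully mesenchymal).

#' Single-sample enrichment score (ssGSEA running sum)
#'
#' Genes are ranked by within-sample expression (descending). The score is
#' the integral (sum over ranks) of the difference between the weighted
#' in-set empirical CDF — weights are rank-normalised expression raised to
#' `weight_exponent` — and the unweighted out-of-set ECDF. With
#' `weight_exponent = 0` the statistic depends on gene ranks only.
#'
#' @param values named numeric vector: one sample's expression, names are
#'   gene symbols (no duplicates).
#' @param gene_set character vector of gene symbols.
#' @param weight_exponent exponent on the rank-normalised expression
#'   (default 0.25).
#' @return scalar enrichment score.
#' @export
ssgsea_es <- function(values, gene_set, weight_exponent = 0.25) {
  stopifnot(!is.null(names(values)), !anyDuplicated(names(values)))
  in_set <- names(values) %in% gene_set
  m <- sum(in_set)
  if (m == 0L) stop("gene set has no measured genes: empty intersection")
  G <- length(values)
  if (m == G) stop("gene set covers all measured genes: out-of-set ECDF undefined")
  ord <- order(values, decreasing = TRUE)
  in_ord <- in_set[ord]
  # rank-normalised expression: top rank -> 1, bottom -> 1/G
  rnorm_expr <- (G - seq_len(G) + 1) / G
  w <- rnorm_expr^weight_exponent
  w[!in_ord] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (G - m)
  sum(p_in - p_out)
}

#' Preliminary per-sample epithelial/mesenchymal phenotype score
#'
#' Rank-enrichment phenotype pre-score used only to order samples for
#' extreme-tail selection: per sample, the mesenchymal minus epithelial
#' enrichment difference, rank-scaled to \[0, 1\] across the cohort
#' (1 = most mesenchymal-like).
#'
#' @param expr genes x samples matrix.
#' @param curated list with `epithelial` and `mesenchymal` gene vectors.
#' @param weight_exponent passed to [ssgsea_es()].
#' @return named numeric vector of prescores in \[0, 1\].
#' @export
phenotype_prescore <- function(expr, curated, weight_exponent = 0.25) {
  stopifnot(all(c("epithelial", "mesenchymal") %in% names(curated)))
  if (length(intersect(curated$epithelial, curated$mesenchymal))) {
    stop("epithelial and mesenchymal sets must be disjoint")
  }
  raw <- vapply(seq_len(ncol(expr)), function(j) {
    v <- expr[, j]
    ssgsea_es(v, curated$mesenchymal, weight_exponent) -
      ssgsea_es(v, curated$epithelial, weight_exponent)
  }, 0)
  n <- length(raw)
  if (n < 2L) stop("prescore needs at least two samples")
  out <- (rank(raw, ties.method = "average") - 1) / (n - 1)
  names(out) <- colnames(expr)
  out
}

# rank-based ROC AUC of x for binary labels (1 = positive class)
roc_auc <- function(x, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(x)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Refine epithelial/mesenchymal signatures from extreme-phenotype samples
#'
#' The top and bottom `extreme_fraction` of samples by prescore are labelled
#' mesenchymal- and epithelial-like. Per gene: (a) the observed between-tail
#' mean difference must exceed in magnitude every one of `n_perm` label
#' permutations (empirical q = 0), and (b) the ROC AUC for tail membership
#' must reach `roc_min` (mesenchymal side) or `1 - roc_min` (epithelial
#' side). Genes passing both are assigned to the mesenchymal or epithelial
#' list by the sign of the observed difference.
#'
#' @param expr genes x samples matrix.
#' @param prescores output of [phenotype_prescore()].
#' @param extreme_fraction tail fraction per side (default 0.25).
#' @param roc_min AUC threshold (default 0.85).
#' @param n_perm label permutations for the q = 0 criterion (default 1000).
#' @param seed permutation seed.
#' @return list with `epithelial` and `mesenchymal` gene vectors.
#' @export
refine_signatures <- function(expr, prescores, extreme_fraction = 0.25,
                              roc_min = 0.85, n_perm = 1000L, seed = 1L) {
  n <- length(prescores)
  k <- floor(n * extreme_fraction)
  if (k < 8L) stop("fewer than 8 samples per extreme tail")
  ord <- order(prescores)
  epi_idx <- ord[seq_len(k)]
  mes_idx <- ord[(n - k + 1L):n]
  sub <- expr[, c(epi_idx, mes_idx), drop = FALSE]
  is_mes <- rep(c(FALSE, TRUE), c(k, k))
  obs <- rowMeans(sub[, is_mes, drop = FALSE]) - rowMeans(sub[, !is_mes, drop = FALSE])
  set.seed(seed)
  exceed <- integer(nrow(sub))
  for (b in seq_len(n_perm)) {
    perm <- sample(is_mes)
    d <- rowMeans(sub[, perm, drop = FALSE]) - rowMeans(sub[, !perm, drop = FALSE])
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  q0 <- exceed == 0L
  auc <- apply(sub, 1L, roc_auc, positive = is_mes)
  mes_keep <- q0 & auc >= roc_min & obs > 0
  epi_keep <- q0 & auc <= 1 - roc_min & obs < 0
  if (!any(mes_keep) && !any(epi_keep)) {
    stop("no genes survive signature refinement; relax roc_min or extreme_fraction")
  }
  list(epithelial = rownames(expr)[epi_keep],
       mesenchymal = rownames(expr)[mes_keep])
}

#' Per-sample EMT score
#'
#' Epithelial and mesenchymal enrichment scores per sample via
#' [ssgsea_es()], each min-max normalised to \[0, 1\] across the cohort;
#' the EMT score is normalised mesenchymal minus normalised epithelial
#' enrichment, hence in \[-1, +1\] with -1 fully epithelial and +1 fully
#' mesenchymal, and exactly antisymmetric under swapping the two
#' signatures.
#'
#' @param expr genes x samples matrix (>= 2 samples).
#' @param signatures list with `epithelial` and `mesenchymal` gene vectors.
#' @param weight_exponent passed to [ssgsea_es()].
#' @return data.frame `sample_id`, `es_epithelial`, `es_mesenchymal`,
#'   `emt_score`.
#' @export
emt_score <- function(expr, signatures, weight_exponent = 0.25) {
  if (ncol(expr) < 2L) stop("cohort normalisation needs at least two samples")
  es_e <- vapply(seq_len(ncol(expr)), function(j)
    ssgsea_es(expr[, j], signatures$epithelial, weight_exponent), 0)
  es_m <- vapply(seq_len(ncol(expr)), function(j)
    ssgsea_es(expr[, j], signatures$mesenchymal, weight_exponent), 0)
  minmax <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) rep(0.5, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  data.frame(sample_id = colnames(expr),
             es_epithelial = es_e, es_mesenchymal = es_m,
             emt_score = minmax(es_m) - minmax(es_e),
             stringsAsFactors = FALSE)
}

#' Spearman association of a gene with the EMT score
#'
#' @param gene gene symbol present in `expr`.
#' @param expr genes x samples matrix (>= 10 samples).
#' @param emt data.frame from [emt_score()].
#' @return list `rho`, `p`.
#' @export
gene_emt_association <- function(gene, expr, emt) {
  stopifnot(gene %in% rownames(expr))
  m <- match(emt$sample_id, colnames(expr))
  ok <- !is.na(m)
  if (sum(ok) < 10L) stop("need at least 10 samples")
  x <- expr[gene, m[ok]]
  if (length(unique(x)) == 1L) stop("constant gene: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, emt$emt_score[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
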