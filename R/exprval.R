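# Expression-level validation: batch-standardised meta-cohort assembly,
# per-gene Cox screening with a CNA direction-consistency rule, the
# stringent significance filter, quartile stratification, and the
# combination analysis of co-deleted genes.

#' Assemble a batch-standardised expression meta-cohort
#'
#' Restricts all datasets to their common genes, then standardises each
#' gene within each dataset to mean 0 and unit variance (exact per-batch
#' location/scale removal) before recombining. Within-batch constant genes
#' are set to 0.
#'
#' @param datasets list of datasets, each a list with `expr` (genes x
#'   samples matrix) and `samples` (data.frame with at least `sample_id`
#'   and `tissue`; a `dataset` label is added from the list names if
#'   absent).
#' @return list of class `meta_cohort`: `expr` (common genes x all
#'   samples, standardised), `samples` (row-bound metadata), `counts`
#'   (samples per dataset and tissue).
#' @export
assemble_meta_cohort <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least two datasets")
  if (is.null(names(datasets))) names(datasets) <- sprintf("DS%02d", seq_along(datasets))
  genes <- Reduce(intersect, lapply(datasets, function(d) rownames(d$expr)))
  if (!length(genes)) stop("datasets share no genes")
  mats <- list()
  metas <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    m <- d$expr[genes, , drop = FALSE]
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    z <- (m - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    mats[[nm]] <- z
    meta <- d$samples
    if (!"dataset" %in% names(meta)) meta$dataset <- nm
    metas[[nm]] <- meta
  }
  samples <- do.call(rbind, lapply(metas, function(m) m[, intersect(names(metas[[1]]), names(m)), drop = FALSE]))
  rownames(samples) <- NULL
  expr <- do.call(cbind, mats)
  counts <- as.data.frame(table(dataset = samples$dataset, tissue = samples$tissue),
                          stringsAsFactors = FALSE)
  structure(list(expr = expr, samples = samples, counts = counts),
            class = "meta_cohort")
}

#' Split a simulated expression cohort into its per-dataset pieces
#'
#' Convenience inverse of the simulator's combined output, producing the
#' input shape [assemble_meta_cohort()] expects.
#' @param sim a `sim_expression`.
#' @return named list of `list(expr, samples)` per dataset label.
#' @export
split_by_dataset <- function(sim) {
  lapply(split(seq_len(nrow(sim$samples)), sim$samples$dataset), function(idx) {
    list(expr = sim$expr[, idx, drop = FALSE],
         samples = sim$samples[idx, , drop = FALSE])
  })
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison: exact enumeration for small tie-free
#' samples (combined n below 20), normal approximation with tie correction
#' otherwise.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @return list `U`, `p`.
#' @export
mannwhitney_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  exact <- (length(values_a) + length(values_b)) < 20 &&
    !anyDuplicated(c(values_a, values_b))
  wt <- stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Screen one candidate gene in the expression meta-cohort
#'
#' Univariate Cox fits of OS and DFS on the standardised continuous
#' expression; the gene passes the primary screen when at least one
#' endpoint reaches `alpha` and the significant coefficient's sign matches
#' the CNA direction (loss -> negative: losing the gene's expression is
#' bad; gain -> positive). Tumour-vs-normal difference, clinicopathological
#' associations, and an optional EMT-score correlation are recorded
#' alongside.
#'
#' @param gene gene symbol.
#' @param cohort a `meta_cohort`.
#' @param direction "gain" or "loss" (from the CNA stage).
#' @param emt_scores optional data.frame `sample_id`, `emt_score` for the
#'   Spearman association.
#' @param alpha primary screen significance level (default 0.05).
#' @return one-row data.frame (a candidate-gene record).
#' @export
screen_gene <- function(gene, cohort, direction, emt_scores = NULL, alpha = 0.05) {
  stopifnot(inherits(cohort, "meta_cohort"), direction %in% c("gain", "loss"))
  if (!gene %in% rownames(cohort$expr)) stop("gene not in cohort: ", gene)
  x <- cohort$expr[gene, ]
  sm <- cohort$samples
  tum <- sm$tissue == "tumor" & !is.na(sm$dfs_time)
  if (sum(tum) < 20) stop("fewer than 20 tumour samples with survival data")
  xt <- as.numeric(scale(x[tum]))
  cox_os <- cox_fit(xt, sm$os_time[tum], sm$os_event[tum])
  cox_dfs <- cox_fit(xt, sm$dfs_time[tum], sm$dfs_event[tum])
  want_sign <- if (direction == "loss") -1 else 1
  sig_ok <- function(fit) fit$p < alpha && sign(fit$coef) == want_sign
  primary_pass <- sig_ok(cox_os) || sig_ok(cox_dfs)
  tn_p <- if (any(sm$tissue == "normal")) {
    mannwhitney_test(x[sm$tissue == "tumor"], x[sm$tissue == "normal"])$p
  } else NA_real_
  assoc_p <- function(label) {
    g <- sm[[label]][tum]
    if (length(unique(g)) < 2L) return(NA_real_)
    stats::kruskal.test(x[tum], factor(g))$p.value
  }
  emt_rho <- NA_real_; emt_p <- NA_real_
  if (!is.null(emt_scores)) {
    m <- match(emt_scores$sample_id, names(x))
    ok <- !is.na(m)
    ct <- suppressWarnings(stats::cor.test(x[m[ok]], emt_scores$emt_score[ok],
                                           method = "spearman"))
    emt_rho <- unname(ct$estimate); emt_p <- ct$p.value
  }
  data.frame(
    gene = gene, direction = direction,
    cox_os_coef = cox_os$coef, cox_os_p = cox_os$p,
    cox_dfs_coef = cox_dfs$coef, cox_dfs_p = cox_dfs$p,
    primary_pass = primary_pass,
    stringent_flag = min(cox_os$p, cox_dfs$p) < 0.005,
    tumor_vs_normal_p = tn_p,
    msi_p = assoc_p("msi"), stage_p = assoc_p("stage"), grade_p = assoc_p("grade"),
    emt_rho = emt_rho, emt_p = emt_p,
    stringsAsFactors = FALSE
  )
}

#' Stringent significance filter on candidate genes
#'
#' Keeps genes with `min(OS p, DFS p) < alpha`; the conventional stringent
#' cut is 0.005.
#'
#' @param candidates data.frame with `cox_os_p` and `cox_dfs_p` columns
#'   (screen output or the packaged candidate table).
#' @param alpha threshold (default 0.005).
#' @return the surviving rows.
#' @export
stringent_filter <- function(candidates, alpha = 0.005) {
  stopifnot(all(c("cox_os_p", "cox_dfs_p") %in% names(candidates)))
  out <- candidates[pmin(candidates$cox_os_p, candidates$cox_dfs_p) < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quartile stratification of a gene's expression
#'
#' Cut points at the 25th/50th/75th percentiles (linear-interpolation
#' quantiles); values tied with a boundary go to the lower quartile.
#'
#' @param values numeric vector (>= 4 samples, non-constant), or a gene
#'   symbol together with `cohort`.
#' @param cohort optional `meta_cohort` when `values` is a symbol.
#' @return factor of labels Q1-Q4, named by sample when names exist.
#' @export
quartile_stratify <- function(values, cohort = NULL) {
  if (is.character(values) && length(values) == 1L) {
    stopifnot(!is.null(cohort))
    values <- cohort$expr[values, ]
  }
  if (length(values) < 4L) stop("need at least 4 samples for quartiles")
  if (length(unique(values)) == 1L) stop("constant values: quartiles undefined")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lab <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  factor(paste0("Q", lab), levels = paste0("Q", 1:4))
}

#' Combination survival analysis of co-underexpressed genes
#'
#' Group A: samples where every listed gene sits in its own first quartile
#' (joint under-expression); group B: samples where every listed gene is in
#' Q2-Q4; samples mixing the two are excluded. The groups are compared by
#' log-rank on the chosen endpoint, and Kaplan-Meier coordinates for both
#' groups are returned for plotting.
#'
#' @param genes character vector of gene symbols (>= 2 after deduplication
#'   a single gene reduces to its Q1-vs-rest comparison).
#' @param cohort a `meta_cohort`.
#' @param endpoint "dfs" or "os".
#' @return list `n_a`, `n_b`, `statistic`, `p`, `km_a`, `km_b`.
#' @export
combo_survival <- function(genes, cohort, endpoint = "dfs") {
  stopifnot(endpoint %in% c("dfs", "os"), length(genes) >= 1L)
  genes <- unique(genes)
  sm <- cohort$samples
  tum <- which(sm$tissue == "tumor" & !is.na(sm[[paste0(endpoint, "_time")]]))
  qs <- vapply(genes, function(g) {
    as.integer(quartile_stratify(cohort$expr[g, tum]))
  }, integer(length(tum)))
  qs <- matrix(qs, nrow = length(tum))
  in_a <- rowSums(qs == 1L) == length(genes)
  in_b <- rowSums(qs > 1L) == length(genes)
  if (!any(in_a)) stop("no sample co-underexpresses all genes; use fewer genes or a larger cohort")
  if (!any(in_b)) stop("no sample has all genes above Q1")
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  ta <- sm[[tcol]][tum][in_a]; ea <- sm[[ecol]][tum][in_a]
  tb <- sm[[tcol]][tum][in_b]; eb <- sm[[ecol]][tum][in_b]
  lr <- logrank_test(ta, ea, tb, eb)
  list(n_a = sum(in_a), n_b = sum(in_b),
       statistic = lr$statistic, p = lr$p,
       km_a = km_curve(ta, ea), km_b = km_curve(tb, eb))
}
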