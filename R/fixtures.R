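# Packaged reference tables: the published 42-gene candidate table and the
# per-series sample counts of the public expression meta-cohort.

# content checksum of the candidate table: row count plus coefficient mass,
# so silent edits of the fixture are caught at load time
TABLE2_CHECKSUM <- list(n = 42L, coef_sum = 37.43184, p_sum = 18.831601)

#' Load the packaged 42-gene candidate table
#'
#' The published candidate-gene table: symbol, Entrez id, CNA direction,
#' percent overlap of the CNA with normal-population copy-number variants,
#' and univariate Cox coefficients with p-values for overall and
#' disease-free survival. A content checksum (record count, total absolute
#' coefficient and p-value mass) guards against a corrupted fixture.
#'
#' @param path override the packaged file (mainly for integrity testing).
#' @return data.frame with columns `gene`, `gene_id`, `cna_event`,
#'   `pct_overlap_normal`, `cox_os_coef`, `cox_os_p`, `cox_dfs_coef`,
#'   `cox_dfs_p`.
#' @export
load_table2 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_candidates.tsv", package = "cnascreen")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  chk <- list(
    n = nrow(df),
    coef_sum = round(sum(abs(df$cox_os_coef)) + sum(abs(df$cox_dfs_coef)), 5),
    p_sum = round(sum(df$cox_os_p) + sum(df$cox_dfs_p), 6)
  )
  if (!identical(chk$n, TABLE2_CHECKSUM$n) ||
      abs(chk$coef_sum - TABLE2_CHECKSUM$coef_sum) > 1e-5 ||
      abs(chk$p_sum - TABLE2_CHECKSUM$p_sum) > 1e-5) {
    stop("candidate-table fixture failed its checksum; the packaged file is corrupted")
  }
  stopifnot(all(df$cna_event %in% c("Gain", "Loss")))
  df
}

#' Per-series sample counts of the expression meta-cohort
#'
#' The 20 public colorectal expression series combined into the validation
#' meta-cohort, with tumour and normal-tissue sample counts per series.
#'
#' @return data.frame `series`, `description`, `n_tumor`, `n_normal`.
#' @export
load_series_counts <- function() {
  path <- system.file("extdata", "meta_cohort_series.tsv", package = "cnascreen")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
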