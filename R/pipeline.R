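# End-to-end orchestration of the synthetic study: QC -> segmentation ->
# STAC permutation map -> SPPS survival map -> intersection -> gene mapping
# -> normal-CNV exclusion -> expression screen -> EMT -> combination
# analysis, with a funnel report and a reproducibility manifest.

#' Synthetic catalog of common germline copy-number variants
#'
#' Random small intervals (50-500 kb) placed on the declared arms but kept
#' clear of the planted driver regions, emulating a population CNV catalog
#' for the exclusion stage. Synthetic stand-in: it is generated, not a
#' published catalog.
#'
#' @param config a [sim_config()].
#' @param n number of catalog intervals.
#' @return BED-style data.frame `chrom`, `start`, `end`.
#' @export
simulate_normal_cnv_catalog <- function(config, n = 60L) {
  set.seed(config$seed + 2L)
  at <- config$arm_table
  dr <- config$driver_regions
  lens <- at$end - at$start
  rows <- list()
  while (length(rows) < n) {
    a <- sample.int(nrow(at), 1L, prob = lens)
    len <- stats::runif(1, 5e4, 5e5)
    st <- stats::runif(1, at$start[a], at$end[a] - len)
    hit_driver <- any(dr$chrom == at$chrom[a] & dr$start < st + len & dr$end > st)
    if (hit_driver) next
    rows[[length(rows) + 1L]] <- data.frame(chrom = at$chrom[a], start = round(st),
                                            end = round(st + len),
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' Stage parameters on top of a [sim_config()]. Defaults are the
#' conventional stringent settings: 35% stacking frequency, permutation
#' p < 0.05, 5% normal-CNV overlap exclusion, stringent Cox p < 0.005,
#' extreme 25% tails and ROC 0.85 for the EMT signature.
#'
#' @param sim a [sim_config()].
#' @param bin_size STAC bin width in bp.
#' @param n_perm STAC permutations.
#' @param freq_min STAC stacking-frequency threshold.
#' @param alpha_stac,alpha_spps significance levels of the two CNA maps.
#' @param spps_candidate_freq minimum whole-cohort occupancy frequency for
#'   a region to be evaluated by SPPS.
#' @param min_cover SPPS In-Group coverage fraction.
#' @param overlap_threshold normal-CNV exclusion threshold.
#' @param whitelist gene symbols exempt from the normal-CNV exclusion.
#' @param screen_alpha primary expression-screen level.
#' @param stringent_alpha stringent Cox filter level.
#' @param extreme_fraction,roc_min,emt_n_perm EMT refinement settings.
#' @param weight_exponent ssGSEA weighting exponent.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), bin_size = 2e6, n_perm = 999L,
                            freq_min = 0.35, alpha_stac = 0.05,
                            alpha_spps = 0.05, spps_candidate_freq = 0.1,
                            min_cover = 0.5, overlap_threshold = 0.05,
                            whitelist = character(0), screen_alpha = 0.05,
                            stringent_alpha = 0.005, extreme_fraction = 0.25,
                            roc_min = 0.85, emt_n_perm = 1000L,
                            weight_exponent = 0.25) {
  stopifnot(inherits(sim, "sim_config"),
            freq_min > 0, freq_min <= 1, alpha_stac > 0, alpha_stac <= 1,
            alpha_spps > 0, alpha_spps <= 1,
            overlap_threshold >= 0, overlap_threshold <= 1,
            stringent_alpha > 0, extreme_fraction > 0, extreme_fraction <= 0.5,
            roc_min >= 0.5, roc_min <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage on a freshly simulated cohort and returns all
#' intermediate artifacts together with the funnel counts. When `out_dir`
#' is given, per-stage artifacts (TSV/BED/SEG/GMT/JSON) and a manifest with
#' parameters, the seed and output md5 hashes are written there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result`; see elements `funnel`,
#'   `stac_regions`, `spps_regions`, `common_regions`, `candidates`,
#'   `stringent`, `emt`, `combo`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  cohort <- simulate_cohort(sim)
  # --- QC ---------------------------------------------------------------
  dlrs <- vapply(colnames(cohort$ratios),
                 function(s) compute_dlrs(cohort_profile(cohort, s)), 0)
  qc_ok <- dlrs_pass(dlrs)
  eligible <- cohort$clinical$sample_id[qc_ok & cohort$clinical$group != "local_recurrence"]
  clin <- cohort$clinical[cohort$clinical$sample_id %in% eligible, ]
  # --- segmentation -----------------------------------------------------
  calls <- do.call(rbind, lapply(eligible, function(s) {
    segment_profile(cohort_profile(cohort, s), sample_id = s)
  }))
  # --- STAC on the metastatic group -------------------------------------
  met <- clin$sample_id[clin$group == "metastatic"]
  met_calls <- calls[calls$sample_id %in% met, ]
  stac_regions <- list()
  stac_results <- list()
  for (dirn in c("gain", "loss")) {
    mat <- binarize_calls(met_calls, sim$arm_table, config$bin_size, dirn, samples = met)
    res <- stac_test(mat, n_perm = config$n_perm,
                     seed = sim$seed + if (dirn == "gain") 11L else 12L)
    stac_results[[dirn]] <- res
    stac_regions[[dirn]] <- significant_regions(res, config$freq_min, config$alpha_stac)
  }
  stac_regions <- do.call(rbind, stac_regions)
  rownames(stac_regions) <- NULL
  # --- SPPS over the whole eligible cohort ------------------------------
  spps_cand <- list()
  for (dirn in c("gain", "loss")) {
    mat <- binarize_calls(calls, sim$arm_table, config$bin_size, dirn, samples = eligible)
    fake <- structure(list(direction = dirn, n_perm = 0L, seed = 0L,
                           arms = lapply(mat$arms, function(a) {
                             nb <- ncol(a$occ)
                             list(chrom = a$chrom, arm = a$arm, edges = a$edges,
                                  freq = colSums(a$occ) / nrow(a$occ),
                                  p = rep(0, nb))
                           })), class = "stac_result")
    spps_cand[[dirn]] <- significant_regions(fake, config$spps_candidate_freq, alpha = 1)
  }
  spps_cand <- do.call(rbind, spps_cand)
  spps_regions <- spps_select(spps_cand, calls, clin, config$min_cover,
                              config$alpha_spps, endpoint = "dfs")
  # --- intersection and gene mapping ------------------------------------
  common <- intersect_maps(stac_regions, spps_regions)
  expr_sim <- simulate_expression(sim, cohort$truth)
  genes <- expr_sim$genes
  mapped <- map_genes(common, genes)
  normal_cnvs <- simulate_normal_cnv_catalog(sim)
  mapped <- annotate_normal_overlap(mapped, normal_cnvs)
  filtered <- filter_candidates(mapped, config$overlap_threshold, config$whitelist)
  # --- expression meta-cohort and EMT -----------------------------------
  meta <- assemble_meta_cohort(split_by_dataset(expr_sim))
  tum_idx <- meta$samples$tissue == "tumor"
  pres <- phenotype_prescore(meta$expr[, tum_idx], expr_sim$gene_sets,
                             config$weight_exponent)
  sigs <- refine_signatures(meta$expr[, tum_idx], pres,
                            config$extreme_fraction, config$roc_min,
                            config$emt_n_perm, seed = sim$seed + 13L)
  emt <- emt_score(meta$expr[, tum_idx], sigs, config$weight_exponent)
  # --- per-gene expression screen ---------------------------------------
  screen_genes <- unique(filtered$symbol[!filtered$ambiguous])
  screen_dir <- filtered$direction[match(screen_genes, filtered$symbol)]
  candidates <- do.call(rbind, lapply(seq_along(screen_genes), function(i) {
    screen_gene(screen_genes[i], meta, screen_dir[i], emt_scores = emt,
                alpha = config$screen_alpha)
  }))
  passed <- if (!is.null(candidates)) {
    candidates[candidates$primary_pass |
                 (!is.na(candidates$emt_p) & candidates$emt_p < 0.05), , drop = FALSE]
  } else candidates
  stringent <- if (!is.null(candidates)) {
    stringent_filter(passed, config$stringent_alpha)
  } else NULL
  # --- combination analysis on deleted candidates -----------------------
  combo <- NULL
  loss_hits <- if (!is.null(passed)) passed$gene[passed$direction == "loss"] else character(0)
  if (length(loss_hits) >= 2L) {
    combo <- tryCatch(combo_survival(utils::head(loss_hits, 3L), meta, "dfs"),
                      error = function(e) NULL)
  }
  funnel <- data.frame(
    stage = c("samples", "qc_eligible", "stac_regions", "spps_regions",
              "common_regions", "genes_mapped", "after_normal_cnv_filter",
              "screen_pass", "stringent"),
    count = c(nrow(cohort$clinical), length(eligible), nrow(stac_regions),
              nrow(spps_regions), nrow(common),
              length(unique(mapped$symbol)), length(unique(filtered$symbol)),
              if (is.null(passed)) 0L else nrow(passed),
              if (is.null(stringent)) 0L else nrow(stringent)),
    rule = c("simulated cohort",
             "DLRS < 0.5 and no local recurrence",
             sprintf("stacking freq >= %g and permutation p < %g", config$freq_min, config$alpha_stac),
             sprintf("In/Out log-rank p < %g at coverage >= %g", config$alpha_spps, config$min_cover),
             "bp intersection of same-direction STAC and SPPS regions",
             ">= 1 bp gene overlap",
             sprintf("normal-CNV region overlap < %g or whitelisted", config$overlap_threshold),
             sprintf("Cox p < %g with direction-consistent sign, or EMT association", config$screen_alpha),
             sprintf("Cox p < %g (OS or DFS)", config$stringent_alpha)),
    stringsAsFactors = FALSE
  )
  result <- structure(list(
    config = config, cohort = cohort, dlrs = dlrs, eligible = eligible,
    calls = calls, stac_results = stac_results, stac_regions = stac_regions,
    spps_candidates = spps_cand, spps_regions = spps_regions,
    common_regions = common, mapped = mapped, filtered = filtered,
    normal_cnvs = normal_cnvs, expr_sim = expr_sim, meta = meta,
    signatures = sigs, emt = emt, candidates = candidates, passed = passed,
    stringent = stringent, combo = combo, funnel = funnel
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

# write per-stage artifacts and a manifest of parameters + md5 hashes
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  write_probe_tsv(result$cohort, f("probes.tsv"))
  utils::write.table(result$cohort$clinical, f("clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_seg(result$calls, f("calls.seg"))
  write_bed(result$stac_regions, f("stac_regions.bed"))
  write_bed(result$spps_regions, f("spps_regions.bed"))
  write_bed(result$common_regions, f("common_regions.bed"))
  write_bed(result$normal_cnvs, f("normal_cnvs.bed"))
  utils::write.table(result$funnel, f("funnel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$candidates)) {
    utils::write.table(result$candidates, f("candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$emt, f("emt_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(result$signatures, f("signatures.gmt"))
  write_ground_truth_json(result$cohort$truth, f("ground_truth.json"))
  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest <- list(
    seed = result$config$sim$seed,
    parameters = list(
      bin_size = result$config$bin_size, n_perm = result$config$n_perm,
      freq_min = result$config$freq_min, alpha_stac = result$config$alpha_stac,
      alpha_spps = result$config$alpha_spps, min_cover = result$config$min_cover,
      overlap_threshold = result$config$overlap_threshold,
      stringent_alpha = result$config$stringent_alpha,
      extreme_fraction = result$config$extreme_fraction,
      roc_min = result$config$roc_min
    ),
    outputs = as.list(tools::md5sum(arts))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Funnel report of a pipeline run
#'
#' Per-stage record counts with the applied rule, as a data.frame (the
#' written `funnel.tsv` renders the same table).
#'
#' @param result a `pipeline_result`.
#' @return data.frame `stage`, `count`, `rule`.
#' @export
funnel_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  result$funnel
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$funnel[, c("stage", "count")], row.names = FALSE)
  invisible(x)
}
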