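#!/usr/bin/env Rscript
# Stage 2: quality control, segmentation and the two CNA maps.
#
# DLRS gates noisy profiles (< 0.5), local recurrences are set aside, and
# each remaining profile is segmented into gain/loss calls. The metastatic
# group's calls feed the STAC-style permutation test (35% stacking
# frequency, p < 0.05 within-arm); the whole cohort's calls feed SPPS,
# which keeps recurrent regions whose carriers have worse disease-free
# survival (log-rank p < 0.05). The intersection of the two maps is the
# driver candidate map.

suppressMessages(library(cnascreen))

dat <- "results/data"
out <- "results/cna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

probes <- read_probe_tsv(file.path(dat, "probes.tsv"))
clinical <- read.delim(file.path(dat, "clinical.tsv"), stringsAsFactors = FALSE)
arms <- read.delim(file.path(dat, "arms.tsv"), stringsAsFactors = FALSE)
cfg <- sim_config()  # thresholds and seed offsets

profile_of <- function(s) {
  data.frame(chrom = probes$probes$chrom, pos = probes$probes$pos,
             log2 = probes$ratios[, s], stringsAsFactors = FALSE)
}

dlrs <- vapply(colnames(probes$ratios), function(s) compute_dlrs(profile_of(s)), 0)
eligible <- clinical$sample_id[dlrs_pass(dlrs) & clinical$group != "local_recurrence"]
clin <- clinical[clinical$sample_id %in% eligible, ]
cat(sprintf("QC: %d of %d samples eligible (DLRS median %.3f)\n",
            length(eligible), nrow(clinical), median(dlrs)))

calls <- do.call(rbind, lapply(eligible, function(s)
  segment_profile(profile_of(s), sample_id = s)))
write_seg(calls, file.path(out, "calls.seg"))
cat(sprintf("Segmentation: %d calls (%d gains, %d losses)\n", nrow(calls),
            sum(calls$direction == "gain"), sum(calls$direction == "loss")))

met <- clin$sample_id[clin$group == "metastatic"]
stac_regions <- do.call(rbind, lapply(c("gain", "loss"), function(dirn) {
  mat <- binarize_calls(calls[calls$sample_id %in% met, ], arms, 2e6, dirn,
                        samples = met)
  res <- stac_test(mat, n_perm = 999,
                   seed = cfg$seed + if (dirn == "gain") 11L else 12L)
  significant_regions(res, freq_min = 0.35, alpha = 0.05)
}))
write_bed(stac_regions, file.path(out, "stac_regions.bed"))
cat("STAC map:\n"); print(stac_regions)

spps_cand <- do.call(rbind, lapply(c("gain", "loss"), function(dirn) {
  mat <- binarize_calls(calls, arms, 2e6, dirn, samples = eligible)
  freq_res <- structure(list(direction = dirn, n_perm = 0L, seed = 0L,
    arms = lapply(mat$arms, function(a)
      list(chrom = a$chrom, arm = a$arm, edges = a$edges,
           freq = colSums(a$occ) / nrow(a$occ), p = rep(0, ncol(a$occ))))),
    class = "stac_result")
  significant_regions(freq_res, freq_min = 0.1, alpha = 1)
}))
spps_regions <- suppressWarnings(
  spps_select(spps_cand, calls, clin, min_cover = 0.5, alpha = 0.05))
write_bed(spps_regions, file.path(out, "spps_regions.bed"))
cat("SPPS map:\n")
print(spps_regions[, c("chrom", "start", "end", "direction", "n_in", "n_out", "p")])

common <- intersect_maps(stac_regions, spps_regions)
write_bed(common, file.path(out, "common_regions.bed"))
cat("Common (STAC ∩ SPPS) map:\n"); print(common)
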