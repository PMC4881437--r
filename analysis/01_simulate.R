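#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the structure of the stage II colorectal cohort (78 disease-free,
# 11 metastatic, 7 local-recurrence samples), a probe-level aCGH matrix with
# three planted focal drivers (8p loss, 18q loss, 20q gain), survival tied
# to driver carriage, and a 6-batch expression meta-cohort plus normals.
# Everything downstream reads the files written here.

suppressMessages(library(cnascreen))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config()
cohort <- simulate_cohort(cfg)
expr <- simulate_expression(cfg, cohort$truth)

write_probe_tsv(cohort, file.path(out, "probes.tsv"))
write.table(cohort$clinical, file.path(out, "clinical.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_ground_truth_json(cohort$truth, file.path(out, "ground_truth.json"))
write.table(cfg$arm_table, file.path(out, "arms.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_expression_tsv(expr$expr, file.path(out, "expression.tsv"))
write.table(expr$samples, file.path(out, "expression_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_bed(expr$genes[, c("chrom", "start", "end", "symbol", "role", "direction")],
          file.path(out, "genes.bed"))
write_gmt(expr$gene_sets, file.path(out, "curated_emt.gmt"))
write_bed(simulate_normal_cnv_catalog(cfg), file.path(out, "normal_cnvs.bed"))

cat("Simulated", ncol(cohort$ratios), "aCGH profiles over",
    nrow(cohort$probes), "probes;",
    ncol(expr$expr), "expression samples across",
    length(unique(expr$samples$dataset)), "batches.\n")
cat("Planted drivers:\n")
print(cohort$truth$drivers[, c("chrom", "arm", "start", "end", "direction")])
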