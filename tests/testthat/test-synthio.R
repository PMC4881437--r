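# Synthetic cohort generator: construction guarantees, determinism,
# planted-effect recovery, and the packaged reference tables.

test_that("default configuration mirrors the study cohort structure", {
  cfg <- sim_config()
  expect_equal(cfg$n_disease_free, 78L)
  expect_equal(cfg$n_metastatic, 11L)
  expect_equal(cfg$n_local_recurrence, 7L)
  co <- simulate_cohort(cfg)
  expect_equal(unname(table(co$clinical$group)[c("disease_free", "metastatic", "local_recurrence")]),
               c(78L, 11L, 7L), ignore_attr = TRUE)
})

test_that("invalid driver geometry is rejected", {
  bad <- default_drivers()
  bad$start[1] <- -5e6
  expect_error(sim_config(driver_regions = bad), "outside declared arm")
  opp <- default_drivers()[c(1, 1), ]
  opp$direction <- c("loss", "gain")
  expect_error(sim_config(driver_regions = opp), "opposite direction")
})

test_that("noise-free single-driver cohort is exactly the planted signal", {
  dr <- data.frame(chrom = "chr8", arm = "p", start = 5e6, end = 15e6,
                   direction = "loss", penetrance = 1, background = 0,
                   stringsAsFactors = FALSE)
  cfg <- sim_config(probe_noise_sd = 0, passenger_rate = 0,
                    driver_regions = dr, n_probes = 800, seed = 5)
  co <- simulate_cohort(cfg)
  met <- co$clinical$sample_id[co$clinical$group == "metastatic"]
  for (s in met) {
    prof <- cohort_profile(co, s)
    inside <- prof$chrom == "chr8" & prof$pos >= 5e6 & prof$pos < 15e6
    expect_true(all(prof$log2[inside] == -cfg$segment_amplitude))
    expect_true(all(prof$log2[!inside] == 0))
  }
  df <- co$clinical$sample_id[co$clinical$group == "disease_free"]
  expect_true(all(co$ratios[, df] == 0))
})

test_that("carrier frequencies match penetrance and background at large n", {
  dr <- default_drivers()
  cfg <- sim_config(n_disease_free = 2000, n_metastatic = 2000,
                    n_local_recurrence = 1, n_probes = 500,
                    passenger_rate = 0, probe_noise_sd = 0, seed = 31)
  co <- simulate_cohort(cfg)
  grp <- co$clinical$group
  for (d in seq_len(nrow(dr))) {
    f_met <- mean(co$truth$carried[grp == "metastatic", d])
    f_df <- mean(co$truth$carried[grp == "disease_free", d])
    expect_equal(f_met, dr$penetrance[d], tolerance = 0.05)
    expect_equal(f_df, dr$background[d], tolerance = 0.2)
  }
})

test_that("simulation is deterministic: byte-identical files on re-run", {
  cfg <- small_sim_config(seed = 99)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_probe_tsv(simulate_cohort(cfg), f1)
  write_probe_tsv(simulate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  e1 <- withr::local_tempfile(fileext = ".tsv")
  e2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(simulate_expression(cfg)$expr, e1)
  write_expression_tsv(simulate_expression(cfg)$expr, e2)
  expect_identical(readLines(e1), readLines(e2))
})

test_that("Cox on the carrier indicator recovers the configured hazard ratio", {
  dr <- data.frame(chrom = "chr8", arm = "p", start = 5e6, end = 15e6,
                   direction = "loss", penetrance = 0.5, background = 0.5,
                   stringsAsFactors = FALSE)
  est <- vapply(1:5, function(s) {
    cfg <- sim_config(n_disease_free = 200, n_metastatic = 200,
                      n_local_recurrence = 1, n_probes = 400,
                      driver_regions = dr, passenger_rate = 0,
                      probe_noise_sd = 0, censoring_rate = 0,
                      hazard_ratio_driver = 3, follow_up_years = Inf, seed = s)
    co <- simulate_cohort(cfg)
    cox_fit(as.numeric(co$truth$carried[, 1]),
            co$clinical$dfs_time, co$clinical$dfs_event)$coef
  }, 0)
  expect_equal(mean(est), log(3), tolerance = 0.15 / log(3))
})

test_that("ground truth survives a JSON round-trip", {
  co <- simulate_cohort(small_sim_config(seed = 7))
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(co$truth, f)
  back <- read_ground_truth_json(f)
  expect_equal(back$carried, co$truth$carried)
  expect_equal(back$drivers$start, co$truth$drivers$start)
  expect_equal(back$passengers$start, co$truth$passengers$start)
  # every planted driver is carried by at least one metastatic sample
  met <- co$clinical$sample_id[co$clinical$group == "metastatic"]
  expect_true(all(colSums(co$truth$carried[met, , drop = FALSE]) >= 1))
})

test_that("dosage coupling shifts carrier expression by exactly beta when noise-free", {
  cfg <- sim_config(expr_noise_sd = 0, batch_shift_sd = 0, batch_scale_sd = 0,
                    emt_shift = 0, dosage_beta = 1, n_datasets = 2,
                    samples_per_dataset = 50, n_expr_normal = 10,
                    n_genes = 120, genes_per_driver = 4, block_size = 10,
                    seed = 13)
  ex <- simulate_expression(cfg)
  g <- ex$genes$symbol[ex$genes$role == "driver" & ex$genes$driver == 1][1]
  carrier <- ex$truth$carried[, 1]
  expect_equal(mean(ex$expr[g, carrier]) - mean(ex$expr[g, !carrier]), -1)
})

test_that("null expression genes reject tumour-vs-normal at the nominal rate", {
  cfg <- sim_config(batch_shift_sd = 0, batch_scale_sd = 0, emt_shift = 0,
                    dosage_beta = 0, n_datasets = 2, samples_per_dataset = 30,
                    n_expr_normal = 30, n_genes = 1000, genes_per_driver = 2,
                    block_size = 5, seed = 17)
  ex <- simulate_expression(cfg)
  tum <- ex$samples$tissue == "tumor"
  p <- apply(ex$expr, 1L, function(v) mannwhitney_test(v[tum], v[!tum])$p)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.35)
})

test_that("the packaged candidate table loads, validates and matches key rows", {
  t2 <- load_table2()
  expect_equal(nrow(t2), 42L)
  expect_equal(sum(t2$cna_event == "Loss"), 29L)
  expect_equal(sum(t2$cna_event == "Gain"), 13L)
  adra1a <- t2[t2$gene == "ADRA1A", ]
  expect_equal(adra1a$cna_event, "Loss")
  expect_equal(adra1a$pct_overlap_normal, 0.42)
  expect_equal(adra1a$cox_os_coef, -0.40185)
  expect_equal(adra1a$cox_os_p, 0.152322)
  expect_equal(adra1a$cox_dfs_coef, -1.67582)
  expect_equal(adra1a$cox_dfs_p, 0.001948)
  mpdz <- t2[t2$gene == "MPDZ", ]
  expect_equal(mpdz$cna_event, "Gain")
  expect_equal(mpdz$cox_dfs_coef, 0.657405)
  expect_equal(mpdz$cox_dfs_p, 3.98e-5)
})

test_that("a tampered candidate table fails its checksum", {
  src <- system.file("extdata", "table2_candidates.tsv", package = "cnascreen")
  df <- utils::read.delim(src)
  df$cox_os_p[1] <- 0.5
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_table2(f), "checksum")
})
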