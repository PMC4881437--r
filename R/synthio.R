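# Synthetic aCGH + survival + expression cohort generator with known ground
# truth. The defaults emulate the structure of a ~96-sample stage II
# colorectal cancer cohort: 78 disease-free, 11 metastatic, 7 local
# recurrence; recurrent driver aberrations concentrated in the metastatic
# group; disease-free survival tied to driver carriage; and a multi-batch
# expression meta-cohort with copy-number dosage coupling and an
# epithelial-mesenchymal phenotype axis.

#' Default chromosome-arm table
#'
#' A reduced genome of 14 arms at approximate hg19 boundaries covering the
#' chromosomes most relevant to colorectal copy-number biology
#' (1, 7, 8, 13, 14, 17, 18, 20). Packaged as
#' `inst/extdata/arms_default.tsv`; any table with columns
#' `chrom`, `arm`, `start`, `end` can be supplied instead.
#'
#' @return data.frame `chrom`, `arm`, `start`, `end` (bp, 0-based half-open).
#' @export
default_arm_table <- function() {
  utils::read.delim(system.file("extdata", "arms_default.tsv", package = "cnascreen"),
                    stringsAsFactors = FALSE)
}

#' Default planted driver regions
#'
#' Three focal drivers in regions recurrently altered in colorectal cancer:
#' an 8p loss, an 18q loss and a 20q gain. Each spans roughly a quarter of
#' its arm: focal enough that chance stacking under within-arm relocation
#' is rare, which is the regime the permutation test is designed for.
#' @return data.frame `chrom`, `arm`, `start`, `end`, `direction`,
#'   `penetrance`, `background`.
#' @export
default_drivers <- function() {
  data.frame(
    chrom = c("chr8", "chr18", "chr20"),
    arm = c("p", "q", "q"),
    start = c(2e6, 48e6, 35e6),
    end = c(14e6, 63e6, 45e6),
    direction = c("loss", "loss", "gain"),
    penetrance = c(0.85, 0.85, 0.85),
    background = c(0.12, 0.12, 0.12),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort. Defaults mirror the
#' structure of the study cohort (78 disease-free / 11 metastatic / 7 local
#' recurrence) with parameter values chosen for statistical realism: probe
#' noise SD 0.15 (DLRS well under the 0.5 QC gate), single-copy segment
#' amplitude 0.6 in log2 units, a three-fold disease-free-survival hazard
#' per driver carried, baseline hazard 1/9.5 per year, and 30% random
#' censoring with a 12-year administrative cutoff.
#'
#' @param n_disease_free,n_metastatic,n_local_recurrence group sizes.
#' @param n_probes total probes, spread over arms proportionally to length.
#' @param arm_table data.frame `chrom`, `arm`, `start`, `end`.
#' @param driver_regions data.frame as [default_drivers()].
#' @param passenger_rate expected passenger aberrations per sample (Poisson).
#' @param probe_noise_sd i.i.d. Gaussian probe noise, log2 units.
#' @param segment_amplitude absolute log2 shift of a single-copy gain/loss.
#' @param hazard_ratio_driver multiplicative DFS hazard per driver carried.
#' @param base_hazard baseline DFS hazard per year.
#' @param censoring_rate fraction of samples randomly censored.
#' @param follow_up_years administrative censoring horizon.
#' @param n_datasets number of tumour expression batches.
#' @param samples_per_dataset tumour samples per batch.
#' @param n_expr_normal normal-tissue samples (one extra batch).
#' @param n_genes total simulated genes.
#' @param genes_per_driver dosage-coupled genes planted per driver region.
#' @param block_size genes per epithelial and per mesenchymal block.
#' @param batch_shift_sd,batch_scale_sd batch-effect magnitudes (additive
#'   shift SD; SD of log scale factor).
#' @param dosage_beta expression shift per copy-state unit.
#' @param emt_shift mesenchymal-program activation in metastatic samples.
#' @param expr_noise_sd residual expression noise SD.
#' @param met_fraction fraction of metastatic-like samples in the
#'   expression meta-cohort.
#' @param seed integer seed making every downstream draw reproducible.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_disease_free = 78L, n_metastatic = 11L,
                       n_local_recurrence = 7L, n_probes = 4000L,
                       arm_table = default_arm_table(),
                       driver_regions = default_drivers(),
                       passenger_rate = 3, probe_noise_sd = 0.15,
                       segment_amplitude = 0.6, hazard_ratio_driver = 3,
                       base_hazard = 1 / 9.5, censoring_rate = 0.3,
                       follow_up_years = 12,
                       n_datasets = 6L, samples_per_dataset = 60L,
                       n_expr_normal = 40L, n_genes = 420L,
                       genes_per_driver = 8L, block_size = 25L,
                       batch_shift_sd = 0.5, batch_scale_sd = 0.2,
                       dosage_beta = 1, emt_shift = 1.2,
                       expr_noise_sd = 1, met_fraction = 0.3,
                       seed = 20160428L) {
  cfg <- list(
    n_disease_free = as.integer(n_disease_free),
    n_metastatic = as.integer(n_metastatic),
    n_local_recurrence = as.integer(n_local_recurrence),
    n_probes = as.integer(n_probes), arm_table = arm_table,
    driver_regions = driver_regions, passenger_rate = passenger_rate,
    probe_noise_sd = probe_noise_sd, segment_amplitude = segment_amplitude,
    hazard_ratio_driver = hazard_ratio_driver, base_hazard = base_hazard,
    censoring_rate = censoring_rate, follow_up_years = follow_up_years,
    n_datasets = as.integer(n_datasets),
    samples_per_dataset = as.integer(samples_per_dataset),
    n_expr_normal = as.integer(n_expr_normal), n_genes = as.integer(n_genes),
    genes_per_driver = as.integer(genes_per_driver),
    block_size = as.integer(block_size),
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    dosage_beta = dosage_beta, emt_shift = emt_shift,
    expr_noise_sd = expr_noise_sd, met_fraction = met_fraction,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_disease_free > 0, n_metastatic > 0, n_local_recurrence >= 0,
      n_probes > 0, all(c("chrom", "arm", "start", "end") %in% names(arm_table)),
      all(arm_table$end > arm_table$start),
      passenger_rate >= 0, probe_noise_sd >= 0, segment_amplitude > 0,
      hazard_ratio_driver > 0, base_hazard > 0,
      censoring_rate >= 0, censoring_rate <= 1,
      n_datasets > 0, samples_per_dataset > 0, n_genes > 0
    )
    stopifnot(all(driver_regions$penetrance >= 0 & driver_regions$penetrance <= 1),
              all(driver_regions$background >= 0 & driver_regions$background <= 1))
  })
  # drivers must lie within a declared arm
  for (i in seq_len(nrow(cfg$driver_regions))) {
    d <- cfg$driver_regions[i, ]
    arm <- cfg$arm_table[cfg$arm_table$chrom == d$chrom & cfg$arm_table$arm == d$arm, ]
    if (nrow(arm) != 1L || d$start < arm$start || d$end > arm$end) {
      stop(sprintf("driver %s:%g-%g outside declared arm %s%s",
                   d$chrom, d$start, d$end, d$chrom, d$arm))
    }
  }
  # opposite-direction drivers may not overlap on the same arm
  dr <- cfg$driver_regions
  if (nrow(dr) > 1L) {
    for (i in seq_len(nrow(dr) - 1L)) {
      for (j in (i + 1L):nrow(dr)) {
        if (dr$chrom[i] == dr$chrom[j] && dr$arm[i] == dr$arm[j] &&
            dr$direction[i] != dr$direction[j] &&
            dr$start[i] < dr$end[j] && dr$end[i] > dr$start[j]) {
          stop(sprintf("overlapping drivers of opposite direction on %s%s",
                       dr$chrom[i], dr$arm[i]))
        }
      }
    }
  }
  structure(cfg, class = "sim_config")
}

# uniformly spaced probe grid, probes allocated to arms by length
probe_grid <- function(arm_table, n_probes) {
  lens <- as.numeric(arm_table$end - arm_table$start)
  n_arm <- pmax(3L, round(as.numeric(n_probes) * lens / sum(lens)))
  rows <- lapply(seq_len(nrow(arm_table)), function(a) {
    pos <- round(seq(arm_table$start[a], arm_table$end[a],
                     length.out = n_arm[a] + 1L)[-(n_arm[a] + 1L)])
    data.frame(chrom = arm_table$chrom[a], arm = arm_table$arm[a],
               pos = pos, stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, rows)
  g <- g[order(match(g$chrom, unique(arm_table$chrom)), g$pos), ]
  g$probe_id <- sprintf("P%05d", seq_len(nrow(g)))
  rownames(g) <- NULL
  g
}

#' Simulate an aCGH cohort with survival outcomes
#'
#' Each sample's profile is a zero baseline plus planted segment amplitudes
#' (drivers and Poisson passengers) plus i.i.d. Gaussian probe noise.
#' Metastatic samples carry each driver with its penetrance; disease-free
#' and local-recurrence samples with its background rate. Disease-free
#' survival is exponential with hazard
#' `base_hazard * hazard_ratio_driver^(drivers carried)`; a
#' `censoring_rate` fraction of samples is randomly censored and follow-up
#' is administratively cut at `follow_up_years`. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `probes` (grid data.frame), `ratios`
#'   (probes x samples matrix), `clinical` (per-sample table) and `truth`
#'   (planted drivers, per-sample carriage matrix, passenger list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- probe_grid(config$arm_table, config$n_probes)
  np <- nrow(grid)
  groups <- rep(c("disease_free", "metastatic", "local_recurrence"),
                c(config$n_disease_free, config$n_metastatic, config$n_local_recurrence))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  dr <- config$driver_regions
  nd <- nrow(dr)
  carried <- matrix(FALSE, nrow = n, ncol = nd,
                    dimnames = list(ids, sprintf("driver_%d", seq_len(nd))))
  ratios <- matrix(0, nrow = np, ncol = n, dimnames = list(grid$probe_id, ids))
  amp <- config$segment_amplitude
  passengers <- list()
  arm_len <- config$arm_table$end - config$arm_table$start
  for (s in seq_len(n)) {
    signal <- numeric(np)
    for (d in seq_len(nd)) {
      pr <- if (groups[s] == "metastatic") dr$penetrance[d] else dr$background[d]
      if (stats::runif(1) < pr) {
        carried[s, d] <- TRUE
        idx <- grid$chrom == dr$chrom[d] & grid$pos >= dr$start[d] & grid$pos < dr$end[d]
        signal[idx] <- signal[idx] + if (dr$direction[d] == "gain") amp else -amp
      }
    }
    n_pass <- stats::rpois(1, config$passenger_rate)
    for (k in seq_len(n_pass)) {
      a <- sample.int(nrow(config$arm_table), 1L, prob = arm_len)
      len <- stats::runif(1, 2e6, 2e7)
      len <- min(len, arm_len[a])
      st <- stats::runif(1, config$arm_table$start[a], config$arm_table$end[a] - len)
      dirn <- sample(c("gain", "loss"), 1L)
      idx <- grid$chrom == config$arm_table$chrom[a] &
        grid$pos >= st & grid$pos < st + len
      signal[idx] <- signal[idx] + if (dirn == "gain") amp else -amp
      passengers[[length(passengers) + 1L]] <- data.frame(
        sample_id = ids[s], chrom = config$arm_table$chrom[a],
        start = round(st), end = round(st + len), direction = dirn,
        stringsAsFactors = FALSE
      )
    }
    ratios[, s] <- signal + stats::rnorm(np, 0, config$probe_noise_sd)
  }
  n_carried <- rowSums(carried)
  haz_dfs <- config$base_hazard * config$hazard_ratio_driver^n_carried
  dfs_time <- stats::rexp(n, haz_dfs)
  dfs_event <- rep(1L, n)
  cens <- stats::runif(n) < config$censoring_rate
  dfs_time[cens] <- dfs_time[cens] * stats::runif(sum(cens))
  dfs_event[cens] <- 0L
  over <- dfs_time > config$follow_up_years
  dfs_time[over] <- config$follow_up_years
  dfs_event[over] <- 0L
  haz_os <- 0.7 * haz_dfs
  os_time <- dfs_time + stats::rexp(n, haz_os)
  os_event <- as.integer(stats::runif(n) > config$censoring_rate)
  os_over <- os_time > 1.5 * config$follow_up_years
  os_time[os_over] <- 1.5 * config$follow_up_years
  os_event[os_over] <- 0L
  clinical <- data.frame(
    sample_id = ids,
    dfs_time = dfs_time, dfs_event = dfs_event,
    os_time = os_time, os_event = os_event,
    group = groups,
    msi = sample(c("MSI", "MSS"), n, replace = TRUE, prob = c(0.16, 0.84)),
    stage = "II",
    grade = sample(c("well", "moderate", "poor"), n, replace = TRUE,
                   prob = c(0.13, 0.73, 0.14)),
    stringsAsFactors = FALSE
  )
  truth <- list(
    drivers = dr, carried = carried,
    passengers = if (length(passengers)) do.call(rbind, passengers) else NULL,
    n_carried = n_carried
  )
  structure(list(probes = grid, ratios = ratios, clinical = clinical,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' Extract one sample's probe profile from a simulated cohort
#'
#' @param cohort a `sim_cohort`.
#' @param sample_id column of the ratio matrix to extract.
#' @return data.frame `chrom`, `pos`, `log2` suitable for [compute_dlrs()]
#'   and [segment_profile()].
#' @export
cohort_profile <- function(cohort, sample_id) {
  stopifnot(sample_id %in% colnames(cohort$ratios))
  data.frame(chrom = cohort$probes$chrom, pos = cohort$probes$pos,
             log2 = cohort$ratios[, sample_id], stringsAsFactors = FALSE)
}

#' Simulate the multi-batch expression meta-cohort
#'
#' Generates a genes x samples matrix across `n_datasets` tumour batches
#' plus one normal-tissue batch. Gene annotation is created alongside:
#' `genes_per_driver` dosage-coupled genes inside each planted driver
#' region, an epithelial and a mesenchymal block, and background genes.
#' Tumour samples carry each driver with its penetrance (metastatic-like
#' samples) or background rate; dosage-coupled genes shift by
#' `dosage_beta * (copy state - 2)`; the mesenchymal block is up-shifted
#' and the epithelial block down-shifted by `emt_shift` in metastatic-like
#' samples; batch b adds a N(0, batch_shift_sd) location shift and a
#' log-normal scale factor. Survival follows the same proportional-hazards
#' model as the aCGH cohort, so low expression of a loss-coupled gene marks
#' high-hazard carriers.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_cohort()] (driver table
#'   reused so the two cohorts share ground truth); may be NULL to use
#'   `config$driver_regions`.
#' @return list of class `sim_expression`: `expr` (genes x samples),
#'   `samples` (metadata with batch, tissue, survival), `genes`
#'   (annotation with roles), `gene_sets` (curated epithelial/mesenchymal
#'   lists including decoys), `truth` (per-sample carriage and phenotype).
#' @export
simulate_expression <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dr <- if (!is.null(truth)) truth$drivers else config$driver_regions
  nd <- nrow(dr)
  if (config$genes_per_driver * nd > config$n_genes - 2L * config$block_size) {
    stop("more dosage-coupled genes requested than the gene space allows")
  }
  set.seed(config$seed + 1L)
  # --- gene annotation -------------------------------------------------
  n_driver_genes <- config$genes_per_driver * nd
  n_block <- config$block_size
  n_bg <- config$n_genes - n_driver_genes - 2L * n_block
  if (n_bg < 0L) stop("n_genes too small for the requested blocks")
  gene_rows <- list()
  gi <- 0L
  for (d in seq_len(nd)) {
    pos <- seq(dr$start[d], dr$end[d], length.out = config$genes_per_driver + 2L)
    pos <- pos[-c(1L, length(pos))]
    for (p in pos) {
      gi <- gi + 1L
      gene_rows[[gi]] <- data.frame(
        symbol = sprintf("DRV%d_%02d", d, which(pos == p)),
        chrom = dr$chrom[d], start = round(p), end = round(p) + 2e4,
        strand = "+", role = "driver", driver = d,
        direction = dr$direction[d], stringsAsFactors = FALSE
      )
    }
  }
  arm_tab <- config$arm_table
  free_arms <- which(!(paste0(arm_tab$chrom, arm_tab$arm) %in% paste0(dr$chrom, dr$arm)))
  place_bg <- function(n, prefix, role) {
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      a <- free_arms[1L + (k %% length(free_arms))]
      st <- round(arm_tab$start[a] +
                    (k %/% length(free_arms) + 1L) * 1e5 +
                    (arm_tab$end[a] - arm_tab$start[a]) * ((k %% 97) / 100))
      st <- min(st, arm_tab$end[a] - 3e4)
      rows[[k]] <- data.frame(symbol = sprintf("%s%03d", prefix, k),
                              chrom = arm_tab$chrom[a], start = st, end = st + 2e4,
                              strand = "+", role = role, driver = NA_integer_,
                              direction = NA_character_, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  genes <- rbind(
    do.call(rbind, gene_rows),
    place_bg(n_block, "EPI", "epithelial"),
    place_bg(n_block, "MES", "mesenchymal"),
    place_bg(n_bg, "BG", "background")
  )
  rownames(genes) <- NULL
  # --- samples ---------------------------------------------------------
  n_tum <- config$n_datasets * config$samples_per_dataset
  n_norm <- config$n_expr_normal
  ids <- c(sprintf("T%04d", seq_len(n_tum)), sprintf("N%04d", seq_len(n_norm)))
  batch <- c(rep(sprintf("DS%02d", seq_len(config$n_datasets)),
                 each = config$samples_per_dataset),
             rep("NORM", n_norm))
  tissue <- rep(c("tumor", "normal"), c(n_tum, n_norm))
  met <- c(stats::runif(n_tum) < config$met_fraction, rep(FALSE, n_norm))
  carried <- matrix(FALSE, nrow = n_tum + n_norm, ncol = nd,
                    dimnames = list(ids, sprintf("driver_%d", seq_len(nd))))
  for (d in seq_len(nd)) {
    pr <- ifelse(met[seq_len(n_tum)], dr$penetrance[d], dr$background[d])
    carried[seq_len(n_tum), d] <- stats::runif(n_tum) < pr
  }
  # --- expression ------------------------------------------------------
  ng <- nrow(genes)
  nS <- n_tum + n_norm
  mu <- stats::rnorm(ng, 6, 1)  # gene-specific baseline, log-like scale
  signal <- matrix(0, nrow = ng, ncol = nS, dimnames = list(genes$symbol, ids))
  for (d in seq_len(nd)) {
    gidx <- which(genes$role == "driver" & genes$driver == d)
    shift <- config$dosage_beta * (if (dr$direction[d] == "gain") 1 else -1)
    signal[gidx, carried[, d]] <- signal[gidx, carried[, d]] + shift
  }
  eidx <- which(genes$role == "epithelial")
  midx <- which(genes$role == "mesenchymal")
  # latent EMT phenotype: metastatic-like samples sit at the mesenchymal
  # end of a continuous axis rather than forming a detached binary class
  phenotype <- config$emt_shift * met + stats::rnorm(nS, 0, 0.25 * config$emt_shift)
  phenotype[tissue == "normal"] <- 0
  signal[midx, ] <- sweep(signal[midx, , drop = FALSE], 2L, phenotype, `+`)
  signal[eidx, ] <- sweep(signal[eidx, , drop = FALSE], 2L, phenotype, `-`)
  batches <- unique(batch)
  shift_b <- stats::rnorm(length(batches), 0, config$batch_shift_sd)
  scale_b <- exp(stats::rnorm(length(batches), 0, config$batch_scale_sd))
  names(shift_b) <- names(scale_b) <- batches
  noise <- matrix(stats::rnorm(ng * nS, 0, config$expr_noise_sd), ng, nS)
  expr <- sweep(sweep(mu + signal + noise, 2L, scale_b[batch], `*`),
                2L, shift_b[batch], `+`)
  dimnames(expr) <- list(genes$symbol, ids)
  # --- survival for tumour samples ------------------------------------
  n_carried <- rowSums(carried)
  haz <- config$base_hazard * config$hazard_ratio_driver^n_carried
  dfs_time <- stats::rexp(nS, haz)
  dfs_event <- rep(1L, nS)
  cens <- stats::runif(nS) < config$censoring_rate
  dfs_time[cens] <- dfs_time[cens] * stats::runif(sum(cens))
  dfs_event[cens] <- 0L
  over <- dfs_time > config$follow_up_years
  dfs_time[over] <- config$follow_up_years
  dfs_event[over] <- 0L
  os_time <- dfs_time + stats::rexp(nS, 0.7 * haz)
  os_event <- as.integer(stats::runif(nS) > config$censoring_rate)
  os_over <- os_time > 1.5 * config$follow_up_years
  os_time[os_over] <- 1.5 * config$follow_up_years
  os_event[os_over] <- 0L
  dfs_time[tissue == "normal"] <- NA_real_
  dfs_event[tissue == "normal"] <- NA_integer_
  os_time[tissue == "normal"] <- NA_real_
  os_event[tissue == "normal"] <- NA_integer_
  samples <- data.frame(
    sample_id = ids, dataset = batch, tissue = tissue, metastatic = met,
    dfs_time = dfs_time, dfs_event = dfs_event,
    os_time = os_time, os_event = os_event,
    msi = sample(c("MSI", "MSS"), nS, replace = TRUE, prob = c(0.16, 0.84)),
    stage = sample(c("I", "II", "III", "IV"), nS, replace = TRUE,
                   prob = c(0.1, 0.45, 0.3, 0.15)),
    grade = sample(c("well", "moderate", "poor"), nS, replace = TRUE,
                   prob = c(0.13, 0.73, 0.14)),
    stringsAsFactors = FALSE
  )
  gene_sets <- list(
    epithelial = c(genes$symbol[eidx], sprintf("BG%03d", 1:3)),
    mesenchymal = c(genes$symbol[midx], sprintf("BG%03d", 4:6))
  )
  structure(list(expr = expr, samples = samples, genes = genes,
                 gene_sets = gene_sets,
                 truth = list(drivers = dr, carried = carried, metastatic = met,
                              phenotype = phenotype)),
            class = "sim_expression")
}
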