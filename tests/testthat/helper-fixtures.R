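# Shared fixtures, built in code at test time.

# one small arm for toy binarization / STAC cases
toy_arm_table <- function(nbins = 20L, bin = 1e6) {
  data.frame(chrom = "chrA", arm = "p", start = 0, end = nbins * bin,
             stringsAsFactors = FALSE)
}

# occupancy matrix -> aberration_matrix with a single arm
toy_matrix <- function(occ, direction = "loss", bin = 1e6) {
  nb <- ncol(occ)
  if (is.null(rownames(occ))) rownames(occ) <- sprintf("S%02d", seq_len(nrow(occ)))
  structure(list(direction = direction, bin_size = bin,
                 arms = list("chrA:p" = list(chrom = "chrA", arm = "p",
                                             edges = seq(0, nb * bin, by = bin),
                                             occ = occ))),
            class = "aberration_matrix")
}

# flat profile with an optional planted segment, single chromosome
toy_profile <- function(n = 200L, seg = NULL, noise = 0, spacing = 1000L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- seq(0L, by = spacing, length.out = n)
  x <- rnorm(n, 0, noise)
  if (!is.null(seg)) x[seg$from:seg$to] <- x[seg$from:seg$to] + seg$amp
  data.frame(chrom = "chr1", pos = pos, log2 = x, stringsAsFactors = FALSE)
}

# small but complete simulation config for fast end-to-end tests
small_sim_config <- function(seed = 11L, ...) {
  sim_config(n_probes = 1500L, n_datasets = 3L, samples_per_dataset = 40L,
             n_expr_normal = 20L, n_genes = 160L, genes_per_driver = 4L,
             block_size = 15L, seed = seed, ...)
}

# the default pipeline run is expensive; compute once and share
.pipeline_cache <- new.env(parent = emptyenv())
get_default_pipeline <- function() {
  if (is.null(.pipeline_cache$res)) {
    .pipeline_cache$res <- suppressWarnings(run_pipeline(pipeline_config()))
  }
  .pipeline_cache$res
}
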