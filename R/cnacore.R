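#' Derivative log-ratio spread (DLRS) of a probe profile
#'
#' Robust per-sample noise estimate for aCGH quality control: the IQR of
#' log2-ratio differences between consecutive probes, taken within
#' chromosomes only, rescaled so that for i.i.d. Gaussian probe noise the
#' statistic estimates the probe-level standard deviation
#' (IQR/1.349 estimates the SD of the differences, which is sigma*sqrt(2)).
#' Samples with DLRS >= 0.5 are conventionally considered too noisy to call.
#'
#' @param profile data.frame with columns `chrom`, `pos`, `log2` (one sample).
#' @return Non-negative scalar DLRS value.
#' @export
compute_dlrs <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("chrom", "pos", "log2") %in% names(profile)))
  if (nrow(profile) < 3L) stop("DLRS requires at least 3 probes")
  if (any(!is.finite(profile$log2))) stop("log2 ratios must be finite")
  d <- unlist(lapply(split(profile$log2, profile$chrom), diff), use.names = FALSE)
  if (!length(d)) stop("no within-chromosome probe pairs")
  stats::IQR(d) / (1.349 * sqrt(2))
}

#' QC gate on DLRS
#'
#' @param dlrs numeric vector of DLRS values.
#' @param cutoff samples with DLRS >= cutoff are ineligible (default 0.5).
#' @return logical vector, TRUE = passes QC.
#' @export
dlrs_pass <- function(dlrs, cutoff = 0.5) {
  is.finite(dlrs) & dlrs < cutoff
}

# Recursive binary segmentation on one chromosome's probe values.
# Returns integer breakpoints (last index of each segment).
binseg_chrom <- function(x, threshold) {
  n <- length(x)
  out <- integer(0)
  recurse <- function(lo, hi) {
    n_seg <- hi - lo + 1L
    if (n_seg < 2L) return(invisible(NULL))
    seg <- x[lo:hi]
    cs <- cumsum(seg)
    tot <- cs[n_seg]
    k <- seq_len(n_seg - 1L)
    # SSE reduction of splitting after position k (within-segment means model)
    gain <- cs[k]^2 / k + (tot - cs[k])^2 / (n_seg - k) - tot^2 / n_seg
    kbest <- which.max(gain)
    if (gain[kbest] > threshold) {
      split_at <- lo + kbest - 1L
      out[[length(out) + 1L]] <<- split_at
      recurse(lo, split_at)
      recurse(split_at + 1L, hi)
    }
    invisible(NULL)
  }
  recurse(1L, n)
  sort(out)
}

#' Segment a probe profile and call copy-number gains and losses
#'
#' Per chromosome, recursive binary segmentation minimising within-segment
#' squared error: a split is accepted when it reduces the SSE by more than
#' `penalty * sigma^2 * log(n)` (a BIC-style cost, sigma estimated robustly
#' from consecutive-probe differences). Segments whose mean log2 ratio
#' reaches `+gain_threshold` are called gains, `-loss_threshold` losses;
#' adjacent same-direction calls are merged. The default +/-0.25 thresholds
#' reflect a single-copy change (~0.58 in a pure diploid) attenuated by
#' tumour-cell fraction.
#'
#' @param profile data.frame `chrom`, `pos`, `log2`, probes ordered by
#'   position within chromosome.
#' @param penalty multiplier of the BIC-style split cost (default 6).
#' @param gain_threshold,loss_threshold calling thresholds in log2 units.
#' @param sample_id label attached to the calls.
#' @return data.frame of calls: `sample_id`, `chrom`, `start`, `end`
#'   (bp, 0-based half-open at probe resolution), `direction`, `mean_log2`,
#'   `n_probes`.
#' @export
segment_profile <- function(profile, penalty = 6, gain_threshold = 0.25,
                            loss_threshold = 0.25, sample_id = "sample") {
  stopifnot(all(c("chrom", "pos", "log2") %in% names(profile)))
  if (any(!is.finite(profile$log2))) stop("log2 ratios must be finite")
  d <- unlist(lapply(split(profile$log2, profile$chrom), diff), use.names = FALSE)
  sigma <- stats::mad(d) / sqrt(2)
  calls <- list()
  for (chr in unique(profile$chrom)) {
    p <- profile[profile$chrom == chr, , drop = FALSE]
    if (is.unsorted(p$pos, strictly = TRUE)) stop("probe positions must be strictly increasing within ", chr)
    x <- p$log2
    n <- length(x)
    threshold <- max(penalty * sigma^2 * log(max(n, 2L)), 1e-10)
    bp <- binseg_chrom(x, threshold)
    starts <- c(1L, bp + 1L)
    ends <- c(bp, n)
    means <- vapply(seq_along(starts), function(i) mean(x[starts[i]:ends[i]]), 0)
    dir <- ifelse(means >= gain_threshold, "gain",
      ifelse(means <= -loss_threshold, "loss", NA_character_))
    keep <- which(!is.na(dir))
    if (!length(keep)) next
    # merge runs of probe-adjacent same-direction called segments
    si <- starts[keep]; ei <- ends[keep]; dk <- dir[keep]
    grp <- cumsum(c(1L, as.integer(si[-1] != ei[-length(ei)] + 1L |
                                     dk[-1] != dk[-length(dk)])))
    m_start <- tapply(si, grp, min)
    m_end <- tapply(ei, grp, max)
    m_dir <- tapply(dk, grp, `[`, 1L)
    m_mean <- vapply(seq_along(m_start), function(i) mean(x[m_start[i]:m_end[i]]), 0)
    calls[[chr]] <- data.frame(
      sample_id = sample_id, chrom = chr,
      start = p$pos[m_start], end = p$pos[m_end] + 1L,
      direction = as.character(m_dir), mean_log2 = m_mean,
      n_probes = as.integer(m_end - m_start + 1L),
      stringsAsFactors = FALSE
    )
  }
  if (!length(calls)) {
    return(data.frame(
      sample_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), direction = character(0), mean_log2 = numeric(0),
      n_probes = integer(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Bin edges tiling an arm
#'
#' Deterministic tiling of `[start, end)` into `bin_size` bins; the last bin
#' may be short.
#' @keywords internal
arm_bins <- function(start, end, bin_size) {
  stopifnot(end > start, bin_size > 0)
  edges <- seq(start, end, by = bin_size)
  if (edges[length(edges)] < end) edges <- c(edges, end)
  edges
}

#' Binarize aberration calls onto per-arm bin grids
#'
#' Projects gain or loss calls onto a fixed per-arm grid: entry (sample, bin)
#' is 1 iff a same-direction call of that sample overlaps the bin by at least
#' one base. Calls spanning an arm boundary contribute to every arm they
#' overlap; a call overlapping no declared arm is an error.
#'
#' @param calls data.frame of calls (see [segment_profile()]).
#' @param arm_table data.frame `chrom`, `arm`, `start`, `end`.
#' @param bin_size bin width in bp.
#' @param direction "gain" or "loss".
#' @param samples character vector of sample ids to include as rows (so
#'   samples without calls appear as all-zero rows). Defaults to the samples
#'   present in `calls`.
#' @return object of class `aberration_matrix`: list with `direction`,
#'   `bin_size`, and `arms`, a named list (key "chrom:arm") of entries
#'   holding `chrom`, `arm`, `edges`, and the samples x bins 0/1 matrix `occ`.
#' @export
binarize_calls <- function(calls, arm_table, bin_size, direction,
                           samples = unique(calls$sample_id)) {
  stopifnot(direction %in% c("gain", "loss"))
  dcalls <- calls[calls$direction == direction, , drop = FALSE]
  if (nrow(dcalls)) {
    hit <- vapply(seq_len(nrow(dcalls)), function(i) {
      any(arm_table$chrom == dcalls$chrom[i] &
            arm_table$start < dcalls$end[i] & arm_table$end > dcalls$start[i])
    }, TRUE)
    if (any(!hit)) {
      bad <- dcalls[which(!hit)[1], ]
      stop(sprintf("call %s:%d-%d (%s) of sample %s overlaps no declared arm",
                   bad$chrom, bad$start, bad$end, bad$direction, bad$sample_id))
    }
  }
  arms <- vector("list", nrow(arm_table))
  names(arms) <- paste0(arm_table$chrom, ":", arm_table$arm)
  for (a in seq_len(nrow(arm_table))) {
    edges <- arm_bins(arm_table$start[a], arm_table$end[a], bin_size)
    nb <- length(edges) - 1L
    occ <- matrix(0L, nrow = length(samples), ncol = nb, dimnames = list(samples, NULL))
    sel <- dcalls[dcalls$chrom == arm_table$chrom[a] &
                    dcalls$start < arm_table$end[a] &
                    dcalls$end > arm_table$start[a], , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      # bins overlapped by [start, end): half-open on both sides
      b1 <- findInterval(sel$start[i], edges, rightmost.closed = FALSE)
      b2 <- findInterval(sel$end[i] - 1L, edges, rightmost.closed = TRUE)
      b1 <- max(b1, 1L); b2 <- min(b2, nb)
      if (b2 >= b1) occ[sel$sample_id[i], b1:b2] <- 1L
    }
    arms[[a]] <- list(chrom = arm_table$chrom[a], arm = arm_table$arm[a],
                      edges = edges, occ = occ)
  }
  structure(list(direction = direction, bin_size = bin_size, arms = arms),
            class = "aberration_matrix")
}

#' @export
print.aberration_matrix <- function(x, ...) {
  n_occ <- sum(vapply(x$arms, function(a) sum(a$occ), 0))
  cat(sprintf("aberration_matrix: %s, %d arms, bin size %g bp, %d occupied cells\n",
              x$direction, length(x$arms), x$bin_size, n_occ))
  invisible(x)
}
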