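# STAC-style permutation calibration of recurrent aberrations.
#
# Null model: within an arm, each sample's maximal aberrant runs keep their
# number and lengths but are relocated independently to uniformly random
# start bins (no wraparound); runs of the same sample that collide after
# relocation merge into plain occupancy. The calibrated statistic is the
# arm-wide maximum stacking frequency, giving family-wise valid per-bin
# p-values.

# maximal runs of 1s in a 0/1 vector -> integer lengths
occupancy_runs <- function(row) {
  r <- rle(as.integer(row))
  r$lengths[r$values == 1L]
}

# one permuted occupancy count vector for an arm (counts over samples)
permute_arm_counts <- function(run_list, nb) {
  counts <- integer(nb)
  for (runs in run_list) {
    if (!length(runs)) next
    if (length(runs) == 1L) {
      s <- sample.int(nb - runs + 1L, 1L)
      counts[s:(s + runs - 1L)] <- counts[s:(s + runs - 1L)] + 1L
    } else {
      cov <- logical(nb)
      for (L in runs) {
        s <- sample.int(nb - L + 1L, 1L)
        cov[s:(s + L - 1L)] <- TRUE
      }
      counts[cov] <- counts[cov] + 1L
    }
  }
  counts
}

#' STAC-style permutation test for stacked aberrations
#'
#' For every arm of an [binarize_calls()] matrix, computes the per-bin
#' stacking frequency f(b) (fraction of samples occupying bin b) and a
#' permutation p-value: each sample's aberrant runs are relocated uniformly
#' at random within the arm, and p(b) is the fraction of permutations whose
#' arm-wide maximum frequency reaches f(b), with the +1 correction
#' `p = (1 + #{max >= f}) / (1 + n_perm)` so p-values are strictly positive
#' and valid. Bins with larger f never receive larger p within an arm.
#'
#' @param matrix an `aberration_matrix`.
#' @param n_perm number of permutations (>= 100; default 999).
#' @param seed integer seed for the permutation stream.
#' @return object of class `stac_result`: list with `direction`, `n_perm`,
#'   `seed` and `arms`, a named list of entries holding `chrom`, `arm`,
#'   `edges`, `freq`, `p`.
#' @export
stac_test <- function(matrix, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(matrix, "aberration_matrix"))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  n_samp <- nrow(matrix$arms[[1]]$occ)
  if (n_samp < 2L) stop("need at least 2 samples")
  set.seed(seed)
  arms <- lapply(matrix$arms, function(a) {
    nb <- ncol(a$occ)
    f <- colSums(a$occ) / n_samp
    run_list <- apply(a$occ, 1L, occupancy_runs, simplify = FALSE)
    too_long <- vapply(run_list, function(r) any(r > nb), TRUE)
    if (any(too_long)) {
      stop(sprintf("sample %s carries a run longer than arm %s:%s",
                   rownames(a$occ)[which(too_long)[1]], a$chrom, a$arm))
    }
    if (all(f == 0)) {
      return(list(chrom = a$chrom, arm = a$arm, edges = a$edges,
                  freq = f, p = rep(1, nb)))
    }
    perm_max <- vapply(seq_len(n_perm), function(i) {
      max(permute_arm_counts(run_list, nb))
    }, 0L) / n_samp
    p <- vapply(f, function(fb) (1 + sum(perm_max >= fb)) / (1 + n_perm), 0)
    list(chrom = a$chrom, arm = a$arm, edges = a$edges, freq = f, p = p)
  })
  structure(list(direction = matrix$direction, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), arms = arms),
            class = "stac_result")
}

#' Extract significant recurrent regions from a STAC result
#'
#' Maximal runs of contiguous bins with frequency >= `freq_min` and
#' permutation p < `alpha`, emitted as bp regions carrying the direction.
#' Defaults are the conventional stringent settings: 35% frequency and
#' p < 0.05.
#'
#' @param result a `stac_result`.
#' @param freq_min minimum stacking frequency (default 0.35).
#' @param alpha significance level on the permutation p-value (default 0.05).
#' @return data.frame `chrom`, `arm`, `start`, `end`, `direction`,
#'   `max_freq`, `min_p`.
#' @export
significant_regions <- function(result, freq_min = 0.35, alpha = 0.05) {
  stopifnot(inherits(result, "stac_result"))
  out <- list()
  for (a in result$arms) {
    sig <- a$freq >= freq_min & a$p < alpha
    if (!any(sig)) next
    r <- rle(sig)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values)) {
      b1 <- idx_start[j]; b2 <- idx_end[j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = a$chrom, arm = a$arm,
        start = a$edges[b1], end = a$edges[b2 + 1L],
        direction = result$direction,
        max_freq = max(a$freq[b1:b2]), min_p = min(a$p[b1:b2]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), arm = character(0),
                      start = numeric(0), end = numeric(0),
                      direction = character(0), max_freq = numeric(0),
                      min_p = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
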