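# Plain-text readers/writers for the pipeline's interchange formats:
# probe tables, clinical tables, expression matrices, SEG, BED, GMT, and a
# JSON ground-truth round-trip.

#' Write a cohort's probe log2 ratios as TSV
#'
#' Columns: chrom, start, end, probe_id, then one log2-ratio column per
#' sample (probe interval = position to next-probe position, half-open).
#' @param cohort a `sim_cohort`.
#' @param path output file.
#' @export
write_probe_tsv <- function(cohort, path) {
  g <- cohort$probes
  endp <- unlist(lapply(split(g$pos, g$chrom)[unique(g$chrom)], function(p) c(p[-1], p[length(p)] + 1)),
                 use.names = FALSE)
  df <- data.frame(chrom = g$chrom, start = g$pos, end = endp,
                   probe_id = g$probe_id, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(signif(cohort$ratios, 7)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe TSV into per-sample profiles
#'
#' @param path file written by [write_probe_tsv()].
#' @return list: `probes` data.frame and `ratios` matrix (probes x samples).
#' @export
read_probe_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- df[, c("chrom", "start", "end", "probe_id")]
  rat <- as.matrix(df[, setdiff(names(df), c("chrom", "start", "end", "probe_id")), drop = FALSE])
  rownames(rat) <- meta$probe_id
  list(probes = data.frame(chrom = meta$chrom, pos = meta$start,
                           probe_id = meta$probe_id, stringsAsFactors = FALSE),
       ratios = rat)
}

#' Write aberration calls in SEG format
#'
#' Standard columns: sample, chrom, start, end, n_probes, seg_mean.
#' @param calls data.frame from [segment_profile()].
#' @param path output file.
#' @export
write_seg <- function(calls, path) {
  seg <- data.frame(sample = calls$sample_id, chrom = calls$chrom,
                    start = calls$start, end = calls$end,
                    n_probes = calls$n_probes, seg_mean = signif(calls$mean_log2, 6),
                    stringsAsFactors = FALSE)
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SEG-format segments as aberration calls
#'
#' Segment means at or beyond the calling thresholds become gain/loss calls;
#' neutral segments are dropped, which lets pre-segmented input bypass
#' [segment_profile()] entirely.
#'
#' @param path SEG file (sample, chrom, start, end, n_probes, seg_mean).
#' @param gain_threshold,loss_threshold calling thresholds (default 0.25).
#' @return calls data.frame in [segment_profile()] format.
#' @export
read_seg <- function(path, gain_threshold = 0.25, loss_threshold = 0.25) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(seg) <- tolower(names(seg))
  dir <- ifelse(seg$seg_mean >= gain_threshold, "gain",
                ifelse(seg$seg_mean <= -loss_threshold, "loss", NA_character_))
  keep <- !is.na(dir)
  data.frame(sample_id = seg$sample[keep], chrom = seg$chrom[keep],
             start = seg$start[keep], end = seg$end[keep],
             direction = dir[keep], mean_log2 = seg$seg_mean[keep],
             n_probes = seg$n_probes[keep], stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional further
#'   columns (written as BED extra fields, in order).
#' @param path output file.
#' @param extra character vector of extra column names to append.
#' @export
write_bed <- function(df, path, extra = setdiff(names(df), c("chrom", "start", "end"))) {
  out <- df[, c("chrom", "start", "end", extra), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED file (no header).
#' @param extra names for columns beyond chrom/start/end.
#' @return data.frame with `chrom`, `start`, `end` (+ extras).
#' @export
read_bed <- function(path, extra = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end")
  n_extra <- ncol(df) - 3L
  nm <- c(base, if (n_extra > 0) {
    if (!is.null(extra) && length(extra) == n_extra) extra else paste0("V", seq_len(n_extra))
  })
  names(df) <- nm
  df
}

#' Write an expression matrix as TSV (genes x samples)
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output file.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), signif(expr, 7),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-x-samples expression TSV
#' @param path file written by [write_expression_tsv()].
#' @return numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' Uses fgsea's reader when available, else a plain parser of the same
#' format (name, description, genes...).
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1L))
}

#' Round-trip the simulation ground truth through JSON
#' @param truth the `truth` element of a `sim_cohort`.
#' @param path output file.
#' @export
write_ground_truth_json <- function(truth, path) {
  obj <- list(
    drivers = truth$drivers,
    carried = lapply(seq_len(nrow(truth$carried)), function(i) unname(truth$carried[i, ])),
    sample_ids = rownames(truth$carried),
    passengers = truth$passengers
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @return `read_ground_truth_json()` returns the truth list.
#' @export
read_ground_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  carried <- if (is.matrix(obj$carried)) obj$carried else
    do.call(rbind, lapply(obj$carried, as.logical))
  storage.mode(carried) <- "logical"
  rownames(carried) <- obj$sample_ids
  colnames(carried) <- sprintf("driver_%d", seq_len(ncol(carried)))
  list(drivers = as.data.frame(obj$drivers, stringsAsFactors = FALSE),
       carried = carried,
       passengers = if (!is.null(obj$passengers) && length(obj$passengers))
         as.data.frame(obj$passengers, stringsAsFactors = FALSE) else NULL,
       n_carried = rowSums(carried))
}
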