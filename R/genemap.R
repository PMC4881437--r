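# Integration of the two CNA maps, gene mapping, and exclusion of common
# germline copy-number variants. All coordinates are 0-based half-open
# (BED convention); conversion to IRanges' 1-based closed form happens only
# inside these helpers.

iranges_of <- function(start, end) {
  IRanges::IRanges(start = start + 1, end = end)
}

#' Intersect two region maps
#'
#' Base-pair intersection of same-direction regions from two analyses
#' (typically the permutation-significant STAC map and the
#' survival-predictive SPPS map). Each output region carries provenance
#' "both" and the p-values of its two parents.
#'
#' @param stac_regions,spps_regions data.frames with `chrom`, `start`,
#'   `end`, `direction` and a p-value column (`min_p` or `p`).
#' @return data.frame `chrom`, `start`, `end`, `direction`, `provenance`,
#'   `p_stac`, `p_spps`.
#' @export
intersect_maps <- function(stac_regions, spps_regions) {
  pcol <- function(df) {
    if ("min_p" %in% names(df)) df$min_p
    else if ("p" %in% names(df)) df$p
    else rep(NA_real_, nrow(df))
  }
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      direction = character(0), provenance = character(0),
                      p_stac = numeric(0), p_spps = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(stac_regions) || !nrow(spps_regions)) return(empty)
  out <- list()
  for (dir in c("gain", "loss")) {
    a <- stac_regions[stac_regions$direction == dir, , drop = FALSE]
    b <- spps_regions[spps_regions$direction == dir, , drop = FALSE]
    pa <- pcol(a); pb <- pcol(b)
    for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
      ai <- which(a$chrom == chr); bi <- which(b$chrom == chr)
      ira <- iranges_of(a$start[ai], a$end[ai])
      irb <- iranges_of(b$start[bi], b$end[bi])
      hits <- IRanges::findOverlaps(ira, irb)
      if (!length(hits)) next
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      inter <- IRanges::pintersect(ira[qi], irb[si])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = IRanges::start(inter) - 1,
        end = IRanges::end(inter),
        direction = dir, provenance = "both",
        p_stac = pa[ai][qi],
        p_spps = pb[bi][si],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map regions to overlapping genes
#'
#' A gene maps to a region when their spans overlap by at least one base
#' (half-open convention: a gene ending exactly where a region starts does
#' not map). Genes overlapping regions of both directions are mapped to
#' each and flagged ambiguous.
#'
#' @param regions data.frame `chrom`, `start`, `end`, `direction` (+ extras
#'   carried through with a `region_` prefix on coordinates).
#' @param genes data.frame `chrom`, `start`, `end`, `symbol` (optionally
#'   `entrez`, `strand`).
#' @return data.frame, one row per (gene, region) overlap: `symbol`,
#'   `chrom`, `gene_start`, `gene_end`, `region_start`, `region_end`,
#'   `direction`, `ambiguous`.
#' @export
map_genes <- function(regions, genes) {
  stopifnot(!anyDuplicated(paste(genes$symbol)))
  out <- list()
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (!length(gi)) next
    irr <- iranges_of(regions$start[ri], regions$end[ri])
    irg <- iranges_of(genes$start[gi], genes$end[gi])
    hits <- IRanges::findOverlaps(irg, irr)
    if (!length(hits)) next
    q <- gi[S4Vectors::queryHits(hits)]
    s <- ri[S4Vectors::subjectHits(hits)]
    out[[length(out) + 1L]] <- data.frame(
      symbol = genes$symbol[q], chrom = chr,
      gene_start = genes$start[q], gene_end = genes$end[q],
      region_start = regions$start[s], region_end = regions$end[s],
      direction = regions$direction[s],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(symbol = character(0), chrom = character(0),
                      gene_start = numeric(0), gene_end = numeric(0),
                      region_start = numeric(0), region_end = numeric(0),
                      direction = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  ndir <- tapply(res$direction, res$symbol, function(d) length(unique(d)))
  res$ambiguous <- unname(ndir[res$symbol] > 1L)
  rownames(res) <- NULL
  res
}

#' Fraction of a region covered by a normal-CNV catalog
#'
#' The catalog intervals are unioned first, so overlapping catalog entries
#' are never double-counted; the result is the covered fraction of the
#' region's length, in \[0, 1\].
#'
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param normal_cnvs data.frame `chrom`, `start`, `end` (BED-style).
#' @return scalar fraction in \[0, 1\].
#' @export
overlap_fraction <- function(region, normal_cnvs) {
  width <- region$end - region$start
  stopifnot(width > 0)
  cat_chr <- normal_cnvs[normal_cnvs$chrom == region$chrom &
                           normal_cnvs$start < region$end &
                           normal_cnvs$end > region$start, , drop = FALSE]
  if (!nrow(cat_chr)) return(0)
  u <- IRanges::reduce(iranges_of(pmax(cat_chr$start, region$start),
                                  pmin(cat_chr$end, region$end)))
  sum(IRanges::width(u)) / width
}

#' Exclude genes whose CNA regions overlap common germline CNVs
#'
#' Genes whose region-level normal-CNV overlap fraction is at or above
#' `threshold` are removed unless whitelisted; a removal log (gene, overlap,
#' decision) is attached as the `"removal_log"` attribute. The default 5%
#' threshold implements the "5%-100% overlap excluded" rule.
#'
#' @param mapped output of [map_genes()] with an added `region_overlap`
#'   column (see [annotate_normal_overlap()]).
#' @param threshold exclusion threshold on the overlap fraction (default 0.05).
#' @param whitelist gene symbols retained regardless of overlap.
#' @return filtered data.frame with attribute `removal_log`.
#' @export
filter_candidates <- function(mapped, threshold = 0.05, whitelist = character(0)) {
  stopifnot("region_overlap" %in% names(mapped))
  excl <- mapped$region_overlap >= threshold & !(mapped$symbol %in% whitelist)
  log <- data.frame(
    symbol = mapped$symbol, region_overlap = mapped$region_overlap,
    decision = ifelse(excl, "excluded",
                      ifelse(mapped$region_overlap >= threshold, "whitelisted", "retained")),
    stringsAsFactors = FALSE
  )
  out <- mapped[!excl, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_log") <- log
  out
}

#' Annotate mapped genes with normal-CNV overlap fractions
#'
#' Adds `region_overlap` (fraction of the CNA region covered by the catalog,
#' the quantity the exclusion rule applies to) and `gene_overlap` (same for
#' the gene body, reported for the candidate table).
#'
#' @param mapped output of [map_genes()].
#' @param normal_cnvs BED-style data.frame `chrom`, `start`, `end`.
#' @return `mapped` with the two overlap columns added.
#' @export
annotate_normal_overlap <- function(mapped, normal_cnvs) {
  mapped$region_overlap <- vapply(seq_len(nrow(mapped)), function(i) {
    overlap_fraction(list(chrom = mapped$chrom[i], start = mapped$region_start[i],
                          end = mapped$region_end[i]), normal_cnvs)
  }, 0)
  mapped$gene_overlap <- vapply(seq_len(nrow(mapped)), function(i) {
    overlap_fraction(list(chrom = mapped$chrom[i], start = mapped$gene_start[i],
                          end = mapped$gene_end[i]), normal_cnvs)
  }, 0)
  mapped
}
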