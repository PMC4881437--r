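# Map intersection, gene mapping and the normal-CNV exclusion.

mk_regions <- function(chrom, start, end, direction, p = 0.01) {
  data.frame(chrom = chrom, start = start, end = end, direction = direction,
             p = p, stringsAsFactors = FALSE)
}

test_that("intersect_maps: disjoint, identical and partial overlaps", {
  a <- mk_regions("chr1", 100, 300, "loss")
  b <- mk_regions("chr1", 400, 500, "loss")
  expect_equal(nrow(intersect_maps(a, b)), 0L)
  # identical sets intersect to themselves
  self <- intersect_maps(a, a)
  expect_equal(self$start, 100)
  expect_equal(self$end, 300)
  expect_equal(self$provenance, "both")
  # partial overlap: [100,300) with [200,400) -> [200,300)
  ovl <- intersect_maps(a, mk_regions("chr1", 200, 400, "loss"))
  expect_equal(ovl$start, 200)
  expect_equal(ovl$end, 300)
  # same interval, opposite direction: no intersection
  expect_equal(nrow(intersect_maps(a, mk_regions("chr1", 100, 300, "gain"))), 0L)
})

test_that("intersect_maps is commutative and idempotent on coordinates", {
  a <- rbind(mk_regions("chr1", 0, 1000, "loss"),
             mk_regions("chr2", 500, 900, "gain"))
  b <- rbind(mk_regions("chr1", 400, 1400, "loss"),
             mk_regions("chr2", 0, 700, "gain"))
  ab <- intersect_maps(a, b)
  ba <- intersect_maps(b, a)
  key <- function(df) df[order(df$chrom, df$start), c("chrom", "start", "end", "direction")]
  expect_equal(key(ab), key(ba), ignore_attr = TRUE)
  expect_equal(key(intersect_maps(ab, ab)), key(ab), ignore_attr = TRUE)
})

test_that("map_genes applies the >=1 bp half-open overlap rule", {
  regions <- mk_regions("chr1", 1000, 2000, "loss")
  genes <- data.frame(
    symbol = c("inside", "adjacent", "spanning", "outside"),
    chrom = "chr1",
    start = c(1200, 500, 900, 5000),
    end = c(1400, 1000, 2500, 6000),  # "adjacent" ends exactly at region start
    stringsAsFactors = FALSE
  )
  m <- map_genes(regions, genes)
  expect_setequal(m$symbol, c("inside", "spanning"))
  expect_true(all(!m$ambiguous))
})

test_that("map_genes agrees with a brute-force all-pairs overlap scan", {
  set.seed(601)
  regions <- data.frame(chrom = sample(c("chr1", "chr2"), 3, TRUE),
                        start = c(1e4, 5e4, 2e4), end = c(3e4, 9e4, 6e4),
                        direction = c("loss", "gain", "loss"),
                        stringsAsFactors = FALSE)
  st <- sample.int(1e5, 50)
  genes <- data.frame(symbol = sprintf("g%02d", 1:50),
                      chrom = sample(c("chr1", "chr2"), 50, TRUE),
                      start = st, end = st + sample.int(2e4, 50),
                      stringsAsFactors = FALSE)
  m <- map_genes(regions, genes)
  brute <- unlist(lapply(seq_len(nrow(genes)), function(g) {
    hits <- sum(regions$chrom == genes$chrom[g] &
                  regions$start < genes$end[g] & regions$end > genes$start[g])
    rep(genes$symbol[g], hits)
  }))
  expect_equal(sort(m$symbol), sort(brute))
})

test_that("a gene under both a gain and a loss region is flagged ambiguous", {
  regions <- rbind(mk_regions("chr1", 0, 5000, "loss"),
                   mk_regions("chr1", 3000, 9000, "gain"))
  genes <- data.frame(symbol = "g", chrom = "chr1", start = 3500, end = 4000,
                      stringsAsFactors = FALSE)
  m <- map_genes(regions, genes)
  expect_equal(nrow(m), 2L)
  expect_true(all(m$ambiguous))
})

test_that("overlap_fraction unions the catalog before measuring", {
  region <- list(chrom = "chr1", start = 0, end = 1000)
  none <- data.frame(chrom = "chr2", start = 0, end = 1e6)
  expect_equal(overlap_fraction(region, none), 0)
  containing <- data.frame(chrom = "chr1", start = -500, end = 2000)
  expect_equal(overlap_fraction(region, containing), 1)
  # two abutting halves cover exactly once; a duplicated interval must not
  # double-count
  halves <- data.frame(chrom = "chr1", start = c(0, 500, 0), end = c(500, 750, 500))
  expect_equal(overlap_fraction(region, halves), 0.75)
  # splitting an interval into abutting pieces leaves the fraction unchanged
  whole <- data.frame(chrom = "chr1", start = 100, end = 900)
  split2 <- data.frame(chrom = "chr1", start = c(100, 400), end = c(400, 900))
  expect_equal(overlap_fraction(region, whole), overlap_fraction(region, split2))
})

test_that("filter_candidates excludes at the threshold boundary with strict >=", {
  mapped <- data.frame(symbol = c("keep", "edge", "drop", "saved"),
                       region_overlap = c(0.0465, 0.05, 0.30, 0.70),
                       stringsAsFactors = FALSE)
  out <- filter_candidates(mapped, threshold = 0.05, whitelist = "saved")
  expect_setequal(out$symbol, c("keep", "saved"))
  log <- attr(out, "removal_log")
  expect_equal(log$decision[log$symbol == "edge"], "excluded")
  expect_equal(log$decision[log$symbol == "saved"], "whitelisted")
  # all-zero overlaps pass through untouched
  clean <- data.frame(symbol = letters[1:3], region_overlap = 0)
  expect_equal(nrow(filter_candidates(clean)), 3L)
})

test_that("genes planted inside catalog CNVs are exactly the ones removed", {
  set.seed(602)
  n <- 50
  st <- seq(0, by = 1e5, length.out = n)
  genes <- data.frame(symbol = sprintf("g%02d", 1:n), chrom = "chr1",
                      start = st, end = st + 2e4, stringsAsFactors = FALSE)
  inside <- sample.int(n, 5)
  regions <- data.frame(chrom = "chr1", start = genes$start,
                        end = genes$end, direction = "loss",
                        stringsAsFactors = FALSE)
  mapped <- map_genes(regions, genes)
  catalog <- data.frame(chrom = "chr1", start = genes$start[inside] - 1000,
                        end = genes$end[inside] + 1000)
  mapped <- annotate_normal_overlap(mapped, catalog)
  out <- filter_candidates(mapped, threshold = 0.05)
  expect_setequal(setdiff(genes$symbol, out$symbol), genes$symbol[inside])
})
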