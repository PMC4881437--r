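# Meta-cohort assembly, the expression screen and the quartile machinery.

mk_dataset <- function(expr, tissue = rep("tumor", ncol(expr))) {
  list(expr = expr,
       samples = data.frame(sample_id = colnames(expr), tissue = tissue,
                            stringsAsFactors = FALSE))
}

test_that("meta-cohort assembly standardises every gene within every batch", {
  set.seed(701)
  m1 <- matrix(rnorm(50 * 12, 5), 50, 12,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("a%02d", 1:12)))
  m2 <- matrix(rnorm(50 * 15, 8, 3), 50, 15,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("b%02d", 1:15)))
  meta <- assemble_meta_cohort(list(A = mk_dataset(m1), B = mk_dataset(m2)))
  for (b in c("A", "B")) {
    sub <- meta$expr[, meta$samples$dataset == b]
    expect_true(all(abs(rowMeans(sub)) < 1e-8))
    expect_true(all(abs(apply(sub, 1, var) - 1) < 1e-6))
  }
  expect_error(assemble_meta_cohort(list(mk_dataset(m1))), "at least two")
  m3 <- m2; rownames(m3) <- sprintf("x%02d", 1:50)
  expect_error(assemble_meta_cohort(list(mk_dataset(m1), mk_dataset(m3))),
               "share no genes")
})

test_that("the published per-series counts sum to the reported meta-cohort", {
  sc <- load_series_counts()
  expect_equal(nrow(sc), 20L)
  expect_equal(sum(sc$n_tumor), 1820L)
  expect_equal(sum(sc$n_normal), 167L)
  expect_equal(sum(sc$n_normal > 0), 7L)
})

test_that("Mann-Whitney handles ties, small exact samples and errors", {
  expect_error(mannwhitney_test(numeric(0), 1:3), "non-empty")
  expect_equal(mannwhitney_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  mw <- mannwhitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
})

test_that("screen_gene enforces the direction-consistency sign rule", {
  # construct a cohort where low expression of gene LOW marks short survival
  set.seed(702)
  n <- 120
  x <- rnorm(n)
  t <- rexp(n, exp(-0.8 * x))     # high x -> low hazard
  expr <- rbind(LOW = x, OTHER = rnorm(n))
  colnames(expr) <- sprintf("s%03d", 1:n)
  cohort <- structure(list(
    expr = expr,
    samples = data.frame(sample_id = colnames(expr), tissue = "tumor",
                         dataset = "D", dfs_time = t, dfs_event = 1L,
                         os_time = t, os_event = 1L, msi = "MSS",
                         stage = "II", grade = "moderate",
                         stringsAsFactors = FALSE)
  ), class = "meta_cohort")
  rec <- screen_gene("LOW", cohort, direction = "loss")
  expect_true(rec$primary_pass)
  expect_lt(rec$cox_dfs_coef, 0)
  # flipping the stored direction flips the verdict for a sign-significant gene
  rec_flip <- screen_gene("LOW", cohort, direction = "gain")
  expect_false(rec_flip$primary_pass)
  # a non-informative gene does not pass
  expect_false(screen_gene("OTHER", cohort, direction = "loss")$primary_pass)
})

test_that("the stringent filter reproduces the published 19-gene subset", {
  t2 <- load_table2()
  kept <- stringent_filter(t2, alpha = 0.005)
  expect_equal(nrow(kept), 19L)
  expect_equal(sum(kept$cna_event == "Loss"), 12L)
  expect_equal(sum(kept$cna_event == "Gain"), 7L)
  expect_equal(nrow(stringent_filter(t2, alpha = 1)), 42L)
  expect_equal(nrow(stringent_filter(t2, alpha = 0)), 0L)
})

test_that("quartile stratification cuts at interpolated percentiles with ties down", {
  q <- quartile_stratify(1:8)
  expect_equal(as.character(q), rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
  expect_error(quartile_stratify(rep(2, 10)), "constant")
  expect_error(quartile_stratify(1:3), "at least 4")
  set.seed(703)
  q1000 <- quartile_stratify(rnorm(1000))
  expect_true(all(abs(table(q1000) - 250) <= 1))
})

test_that("combination analysis sharpens a planted two-gene deletion signal", {
  set.seed(704)
  sim_cohort_2gene <- function() {
    n <- 150
    g1 <- rnorm(n); g2 <- rnorm(n)
    risk <- (g1 < quantile(g1, 0.25)) & (g2 < quantile(g2, 0.25))
    t <- rexp(n, 0.1 * ifelse(risk, 6, 1))
    expr <- rbind(G1 = g1, G2 = g2, BGX = rnorm(n))
    colnames(expr) <- sprintf("s%03d", 1:n)
    structure(list(expr = expr,
                   samples = data.frame(sample_id = colnames(expr),
                                        tissue = "tumor", dataset = "D",
                                        dfs_time = t, dfs_event = 1L,
                                        os_time = t, os_event = 1L,
                                        stringsAsFactors = FALSE)),
              class = "meta_cohort")
  }
  wins <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    co <- sim_cohort_2gene()
    combo <- combo_survival(c("G1", "G2"), co)
    single <- combo_survival("G1", co)
    wins <- wins + (combo$p < single$p)
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("a single-gene combo reduces to its Q1-vs-rest comparison", {
  set.seed(705)
  n <- 80
  x <- rnorm(n)
  t <- rexp(n)
  expr <- rbind(G = x)
  colnames(expr) <- sprintf("s%02d", 1:n)
  co <- structure(list(expr = expr,
                       samples = data.frame(sample_id = colnames(expr),
                                            tissue = "tumor", dataset = "D",
                                            dfs_time = t, dfs_event = 1L,
                                            os_time = t, os_event = 1L,
                                            stringsAsFactors = FALSE)),
                  class = "meta_cohort")
  combo <- combo_survival(c("G", "G"), co)
  q <- quartile_stratify(x)
  lr <- logrank_test(t[q == "Q1"], rep(1, sum(q == "Q1")),
                     t[q != "Q1"], rep(1, sum(q != "Q1")))
  expect_equal(combo$p, lr$p)
  expect_equal(combo$n_a, sum(q == "Q1"))
})

test_that("combination analysis keeps its nominal size for independent genes", {
  set.seed(706)
  rej <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    n <- 100
    expr <- rbind(A = rnorm(n), B = rnorm(n))
    colnames(expr) <- sprintf("s%03d", 1:n)
    co <- structure(list(expr = expr,
                         samples = data.frame(sample_id = colnames(expr),
                                              tissue = "tumor", dataset = "D",
                                              dfs_time = rexp(n), dfs_event = 1L,
                                              os_time = rexp(n), os_event = 1L,
                                              stringsAsFactors = FALSE)),
                    class = "meta_cohort")
    rej <- rej + (combo_survival(c("A", "B"), co)$p < 0.05)
  }
  expect_equal(rej / n_rep, 0.05, tolerance = 0.8)
})
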