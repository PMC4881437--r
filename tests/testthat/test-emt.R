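# ssGSEA enrichment, signature refinement and the EMT score.

toy_sample <- function(n = 10, seed = 801) {
  set.seed(seed)
  v <- sort(runif(n, 1, 10), decreasing = TRUE)
  names(v) <- sprintf("g%02d", seq_len(n))
  v
}

test_that("ssgsea_es validates its gene set", {
  v <- toy_sample()
  expect_error(ssgsea_es(v, c("absent1", "absent2")), "empty intersection")
  expect_error(ssgsea_es(v, names(v)), "out-of-set ECDF undefined")
})

test_that("unit-weight ES equals the hand-summed running difference", {
  v <- toy_sample()
  set <- c("g01", "g04", "g07")  # ranks 1, 4, 7 by construction
  # hand computation: P_in steps 1/3 at in-set ranks, P_out 1/7 at the rest
  in_ind <- names(sort(v, decreasing = TRUE)) %in% set
  p_in <- cumsum(in_ind) / 3
  p_out <- cumsum(!in_ind) / 7
  expect_equal(ssgsea_es(v, set, weight_exponent = 0), sum(p_in - p_out))
})

test_that("with unit weights the ES is affine and decreasing in the in-set rank sum", {
  v <- toy_sample()
  placements <- utils::combn(10, 3)
  es <- apply(placements, 2, function(idx) {
    ssgsea_es(v, names(sort(v, decreasing = TRUE))[idx], weight_exponent = 0)
  })
  rank_sum <- colSums(placements)
  expect_equal(abs(stats::cor(es, rank_sum)), 1, tolerance = 1e-10)
  expect_lt(stats::cor(es, rank_sum), 0)
  # the top placement attains the maximum
  expect_equal(max(es), es[which(rank_sum == 6)])
})

test_that("top-ranked set attains the closed-form maximum under weighting", {
  v <- toy_sample()
  m <- 3; G <- 10; alpha <- 0.25
  top_set <- names(sort(v, decreasing = TRUE))[1:m]
  es <- ssgsea_es(v, top_set, weight_exponent = alpha)
  # closed form for the extreme ordering: in-set genes occupy ranks 1..m
  w <- ((G - (1:G) + 1) / G)^alpha
  p_in <- cumsum(c(w[1:m], rep(0, G - m))) / sum(w[1:m])
  p_out <- cumsum(c(rep(0, m), rep(1, G - m))) / (G - m)
  expect_equal(es, sum(p_in - p_out))
  # and no other placement beats it
  others <- replicate(50, ssgsea_es(v, sample(names(v), m), weight_exponent = alpha))
  expect_true(all(others <= es + 1e-12))
})

test_that("ES with unit weights is invariant to monotone transforms", {
  v <- toy_sample()
  set <- c("g02", "g05")
  expect_equal(ssgsea_es(exp(v), set, 0), ssgsea_es(v, set, 0))
  expect_equal(ssgsea_es(rank(v), set, 0), ssgsea_es(v, set, 0))
})

test_that("prescore ranks mesenchymal-shifted samples high and is rank-uniform", {
  set.seed(802)
  ng <- 60; ns <- 40
  expr <- matrix(rnorm(ng * ns), ng, ns,
                 dimnames = list(sprintf("g%02d", 1:ng), sprintf("s%02d", 1:ns)))
  curated <- list(epithelial = sprintf("g%02d", 1:10),
                  mesenchymal = sprintf("g%02d", 11:20))
  shifted <- 1:10  # first ten samples: mesenchymal program on
  expr[curated$mesenchymal, shifted] <- expr[curated$mesenchymal, shifted] + 2
  expr[curated$epithelial, shifted] <- expr[curated$epithelial, shifted] - 2
  pre <- phenotype_prescore(expr, curated)
  expect_gt(median(pre[shifted]), 0.5)
  expect_equal(range(pre), c(0, 1))
  # duplicated sample gets the identical prescore
  expr2 <- cbind(expr, dup = expr[, 1])
  pre2 <- phenotype_prescore(expr2, curated)
  expect_equal(unname(pre2["s01"]), unname(pre2["dup"]))
})

test_that("signature refinement keeps planted blocks and drops flat genes", {
  set.seed(803)
  ng <- 80; ns <- 64
  expr <- matrix(rnorm(ng * ns), ng, ns,
                 dimnames = list(sprintf("g%02d", 1:ng), sprintf("s%02d", 1:ns)))
  mes_genes <- sprintf("g%02d", 1:8)
  epi_genes <- sprintf("g%02d", 9:16)
  phenotype <- rnorm(ns) + rep(c(3, 0), c(16, ns - 16))
  expr[mes_genes, ] <- expr[mes_genes, ] + rep(phenotype, each = 8)
  expr[epi_genes, ] <- expr[epi_genes, ] - rep(phenotype, each = 8)
  pres <- (rank(phenotype) - 1) / (ns - 1)
  sigs <- refine_signatures(expr, pres, extreme_fraction = 0.25,
                            roc_min = 0.85, n_perm = 300, seed = 2)
  expect_setequal(sigs$mesenchymal, mes_genes)
  expect_setequal(sigs$epithelial, epi_genes)
})

test_that("refinement on pure noise finds essentially nothing", {
  set.seed(804)
  for (s in 1:3) {
    ng <- 60; ns <- 64
    expr <- matrix(rnorm(ng * ns), ng, ns,
                   dimnames = list(sprintf("g%02d", 1:ng), sprintf("s%02d", 1:ns)))
    pres <- (rank(rnorm(ns)) - 1) / (ns - 1)
    got <- tryCatch(refine_signatures(expr, pres, n_perm = 300, seed = s),
                    error = function(e) list(epithelial = character(0),
                                             mesenchymal = character(0)))
    expect_lte(length(got$epithelial) + length(got$mesenchymal), 2)
  }
})

test_that("EMT scores are bounded, antisymmetric and separate planted phenotypes", {
  ex <- simulate_expression(small_sim_config(seed = 23))
  tum <- ex$samples$tissue == "tumor"
  sigs <- list(epithelial = ex$genes$symbol[ex$genes$role == "epithelial"],
               mesenchymal = ex$genes$symbol[ex$genes$role == "mesenchymal"])
  emt <- emt_score(ex$expr[, tum], sigs)
  expect_true(all(emt$emt_score >= -1 & emt$emt_score <= 1))
  swapped <- emt_score(ex$expr[, tum],
                       list(epithelial = sigs$mesenchymal,
                            mesenchymal = sigs$epithelial))
  expect_equal(swapped$emt_score, -emt$emt_score)
  met <- ex$truth$metastatic[tum]
  auc <- {
    r <- rank(emt$emt_score); n1 <- sum(met)
    (sum(r[met]) - n1 * (n1 + 1) / 2) / (n1 * sum(!met))
  }
  expect_gt(auc, 0.9)
  expect_error(emt_score(ex$expr[, 1, drop = FALSE], sigs), "at least two")
})

test_that("gene-EMT association recovers monotone coupling and stays null-calibrated", {
  set.seed(805)
  ns <- 60
  emt <- data.frame(sample_id = sprintf("s%02d", 1:ns),
                    emt_score = runif(ns, -1, 1), stringsAsFactors = FALSE)
  expr <- rbind(MONO = emt$emt_score^3 + 2,  # monotone transform of the score
                FLAT = rep(1, ns),
                NOISE = rnorm(ns))
  colnames(expr) <- emt$sample_id
  a <- gene_emt_association("MONO", expr, emt)
  expect_equal(a$rho, 1)
  expect_lt(a$p, 1e-10)
  expect_error(gene_emt_association("FLAT", expr, emt), "constant")
  # null calibration across replicates
  rej <- mean(replicate(400, {
    e2 <- expr
    e2["NOISE", ] <- rnorm(ns)
    gene_emt_association("NOISE", e2, emt)$p < 0.05
  }))
  expect_equal(rej, 0.05, tolerance = 0.6)
})
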