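ct_from_matrix <- function(m, groups = NULL) {
  colnames(m) <- sprintf("rg%02d", seq_len(ncol(m)))
  tbl <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(nrow(m))),
    group = groups %||% rep(c("g1", "g2"), length.out = nrow(m))
  )
  dplyr::bind_cols(tbl, tibble::as_tibble(m))
}

test_that("geNorm M is zero for perfectly co-regulated genes", {
  ct <- ct_from_matrix(cbind(c(20, 22, 24, 21), c(23, 25, 27, 24)))
  expect_equal(genorm(ct)$genorm_m, c(0, 0), tolerance = 1e-12)
})

test_that("for two genes, geNorm M equals the SD of the Ct difference", {
  set.seed(5)
  m <- cbind(rnorm(10, 20), rnorm(10, 25))
  ct <- ct_from_matrix(m)
  expect_equal(genorm(ct)$genorm_m, rep(sd1(m[, 2] - m[, 1]), 2),
               tolerance = 1e-12)
})

test_that("an added-noise gene gets the largest geNorm M", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    base <- rnorm(12, 22, 0.1)
    m <- cbind(base + rnorm(12, 0, 0.1), base + rnorm(12, 0, 0.1),
               base + rnorm(12, 0, 2))
    which.max(genorm(ct_from_matrix(m))$genorm_m) == 3L
  }, logical(1))
  expect_true(all(hits))
})

test_that("delta-Ct score is zero for constant offsets and flags noisy genes", {
  ct <- ct_from_matrix(cbind(c(20, 21, 22), c(25, 26, 27)))
  expect_equal(delta_ct(ct)$deltact_mean_sd, c(0, 0), tolerance = 1e-12)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    a <- rnorm(12, 20, 0.2)
    m <- cbind(a, rnorm(12, 24, 0.2), a + rnorm(12, 0, 1))
    which.max(delta_ct(ct_from_matrix(m))$deltact_mean_sd) == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("on two genes the geNorm and delta-Ct scores coincide exactly", {
  set.seed(8)
  for (i in 1:5) {
    m <- cbind(rnorm(8, 20 + i), rnorm(8, 26))
    ct <- ct_from_matrix(m)
    expect_equal(genorm(ct)$genorm_m, delta_ct(ct)$deltact_mean_sd,
                 tolerance = 1e-12)
  }
})

test_that("BestKeeper reports Ct SD, the geometric-mean index and r", {
  ct <- ct_from_matrix(cbind(c(20, 20), c(30, 30)))
  bk <- bestkeeper(ct)
  expect_equal(bk$bestkeeper_sd, c(0, 0))
  # index is the per-sample geometric mean: sqrt(20 * 30) = sqrt(600)
  index <- exp(rowMeans(log(cbind(c(20, 20), c(30, 30)))))
  expect_equal(unique(round(index, 3)), round(sqrt(600), 3))
  expect_true(all(is.na(bk$bestkeeper_r))) # zero-variance index

  set.seed(3)
  g1 <- rnorm(10, 22, 1)
  ct2 <- ct_from_matrix(cbind(g1, g1)) # each gene equals the index
  expect_equal(bestkeeper(ct2)$bestkeeper_r, c(1, 1), tolerance = 1e-12)
})

test_that("NormFinder is zero for identical data and symmetric under swaps", {
  m <- matrix(21, nrow = 8, ncol = 3)
  nf <- normfinder(ct_from_matrix(m))
  expect_equal(nf$normfinder_stability, c(0, 0, 0), tolerance = 1e-12)

  # two groups, two genes, data symmetric under swapping both
  m2 <- rbind(
    cbind(c(20, 20.4), c(22, 22.4)), # group 1
    cbind(c(22, 22.4), c(20, 20.4))  # group 2
  )
  nf2 <- normfinder(ct_from_matrix(m2, groups = rep(c("a", "b"), each = 2)))
  expect_equal(nf2$normfinder_stability[1], nf2$normfinder_stability[2],
               tolerance = 1e-10)
})

test_that("NormFinder penalizes a group-shifted gene most", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    grp <- rep(c("a", "b"), each = 6)
    m <- sapply(1:4, function(g) rnorm(12, 20 + g, 0.3))
    m[grp == "b", 4] <- m[grp == "b", 4] + 2
    nf <- normfinder(ct_from_matrix(m, groups = grp))
    which.max(nf$normfinder_stability) == 4L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("RefFinder takes the geometric mean of per-method ranks", {
  scores <- tibble::tibble(
    gene_id = sprintf("g%d", 1:8),
    genorm_m = 1:8 / 10,
    normfinder_stability = c(2, 1, 3:8) / 10,
    bestkeeper_sd = c(2, 3, 4, 1, 5:8) / 10,
    deltact_mean_sd = c(2:8, 1) / 10
  )
  rf <- reffinder(scores)
  # gene 1 holds ranks 1, 2, 2, 4... construct the documented case directly:
  g1 <- rf[rf$gene_id == "g1", ]
  ranks_g1 <- unlist(g1[paste0("rank_", c("genorm", "normfinder", "bestkeeper", "deltact"))])
  expect_equal(unname(exp(mean(log(ranks_g1)))), unname(g1$reffinder_score),
               tolerance = 1e-12)
  expect_equal(unname(exp(mean(log(c(1, 2, 4, 8))))), 2.828, tolerance = 1e-3)

  all_first <- tibble::tibble(
    gene_id = c("best", "worst"),
    genorm_m = c(0.1, 1), normfinder_stability = c(0.1, 1),
    bestkeeper_sd = c(0.1, 1), deltact_mean_sd = c(0.1, 1)
  )
  rf2 <- reffinder(all_first)
  expect_equal(rf2$reffinder_score, c(1, 2))

  tied <- tibble::tibble(
    gene_id = c("a", "b"),
    genorm_m = c(1, 1), normfinder_stability = c(2, 2),
    bestkeeper_sd = c(3, 3), deltact_mean_sd = c(4, 4)
  )
  expect_equal(reffinder(tied)$reffinder_score, c(1.5, 1.5))
})

test_that("RefFinder omits a missing method for that gene and stays in bounds", {
  scores <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    genorm_m = c(0.1, 0.2, 0.3),
    normfinder_stability = c(0.3, NA, 0.1),
    bestkeeper_sd = c(0.2, 0.1, 0.3),
    deltact_mean_sd = c(0.1, 0.2, 0.3)
  )
  rf <- reffinder(scores)
  expect_equal(rf$n_methods, c(4L, 3L, 4L))
  expect_true(all(rf$reffinder_score >= 1 & rf$reffinder_score <= 3))
})

test_that("stability scores ignore a global Ct shift", {
  sim <- simulate_ct_table(seed = 13L)
  shifted <- sim$ct
  gene_cols <- setdiff(names(shifted), c("sample_id", "group"))
  for (g in gene_cols) shifted[[g]] <- shifted[[g]] + 5
  a <- rank_stability(sim$ct)
  b <- rank_stability(shifted)
  for (col in c("genorm_m", "deltact_mean_sd", "bestkeeper_sd",
                "normfinder_stability", "reffinder_score")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-9)
  }
})

test_that("every method separates well-spaced stable from unstable genes", {
  sim <- simulate_ct_table(
    stable_sd = 0.1, unstable_sd = 1, group_shift = 2, reps = 3L, seed = 1L
  )
  st <- rank_stability(sim$ct)
  cls <- sim$truth$class_label[match(st$gene_id, sim$truth$gene_id)]
  for (col in c("genorm_m", "deltact_mean_sd", "bestkeeper_sd",
                "normfinder_stability", "reffinder_score")) {
    expect_lt(max(st[[col]][cls == "stable"]), min(st[[col]][cls == "unstable"]))
  }
})

test_that("tidy and glance summarise a stability table", {
  sim <- simulate_ct_table(seed = 4L)
  st <- rank_stability(sim$ct)
  td <- generics::tidy(st)
  expect_identical(nrow(td), nrow(st) * 4L)
  gl <- generics::glance(st)
  expect_identical(gl$n_genes, nrow(st))
  expect_identical(gl$best_gene, st$gene_id[which.min(st$reffinder_score)])
})

test_that("degenerate stability inputs are rejected", {
  one_gene <- tibble::tibble(sample_id = c("s1", "s2"), group = "g",
                             a = c(20, 21))
  expect_error(genorm(one_gene), "2 genes")
  sim <- simulate_ct_table(seed = 1L)
  expect_error(normfinder(sim$ct, group = "nope"), "grouping column")
  expect_error(genorm(sim$ct, efficiency = 0.9), "exceed 1")
})
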