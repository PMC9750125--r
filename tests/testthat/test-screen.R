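ref <- default_reference()
clock <- clock_gene_defaults()

test_that("ltm_heat yields ordered groups with non-decreasing driver means", {
  sim <- small_sim(seed = 3, n_samples = 120, n_genes = 80)
  heat <- ltm_heat(sim$expression, "coupler", k = 4, clock$gene, ref)
  expect_identical(heat$group, 1:4)
  expect_identical(heat$n_samples, partition_sizes(120, 4))
  expect_true(all(diff(heat$mean_driver) >= 0))
  expect_true(all(heat$n_genes_used == 17))
  expect_false(attr(heat, "degenerate"))
})

test_that("ltm_heat flags a constant driver as degenerate", {
  sim <- small_sim(seed = 3, n_samples = 60, n_genes = 50)
  m <- sim$expression
  m["decoy_0001", ] <- 7
  expect_warning(heat <- ltm_heat(m, "decoy_0001", 4, clock$gene, ref),
                 "degenerate")
  expect_true(attr(heat, "degenerate"))
  expect_equal(heat$mean_driver, rep(7, 4))
})

test_that("ltm_heat is invariant to permuting sample columns", {
  sim <- small_sim(seed = 12, n_samples = 80, n_genes = 60)
  m <- sim$expression
  withr::with_seed(5, perm <- sample(ncol(m)))
  h1 <- ltm_heat(m, "coupler", 4, clock$gene, ref)
  h2 <- ltm_heat(m[, perm], "coupler", 4, clock$gene, ref)
  expect_equal(tibble::as_tibble(h1), tibble::as_tibble(h2),
               tolerance = 1e-12)
})

test_that("ltm_cook correlates group summaries and flags degeneracy", {
  g <- tibble::tibble(mean_driver = c(1, 2, 3, 4),
                      mean_ncv = c(0.1, 0.2, 0.3, 0.4),
                      zstat = c(5, 3, 4, 1))
  cook <- ltm_cook(g)
  expect_equal(cook$r_ncv, 1)
  expect_equal(cook$r_zstat, stats::cor(c(1, 2, 3, 4), c(5, 3, 4, 1)),
               tolerance = 1e-12)
  expect_true(cook$r_ncv_defined && cook$r_zstat_defined)

  g$mean_ncv <- rep(0.2, 4)  # zero variance: undefined, not 0
  cook2 <- ltm_cook(g)
  expect_true(is.na(cook2$r_ncv))
  expect_false(cook2$r_ncv_defined)
  expect_true(cook2$r_zstat_defined)

  cook3 <- ltm_cook(g[1:2, ])  # < 3 groups
  expect_true(is.na(cook3$r_ncv) && is.na(cook3$r_zstat))
})

test_that("ltm_dish averages defined LTMpre values with the sign kept", {
  per_k <- tibble::tibble(k = c(4, 7, 10), r_ncv = c(1, 1, 1),
                          r_zstat = c(1, 1, 1))
  d <- ltm_dish(per_k)
  expect_equal(d$ltm_ori, 1)
  expect_equal(d$ltm_abs, 1)
  expect_identical(d$n_k_used, 3L)

  per_k2 <- tibble::tibble(k = 4, r_ncv = 0.8, r_zstat = 0.6)
  expect_equal(ltm_dish(per_k2)$ltm_pre_k4, 0.7)

  per_k3 <- tibble::tibble(k = c(4, 7), r_ncv = c(-0.5, NA),
                           r_zstat = c(-0.3, 0.9))
  d3 <- ltm_dish(per_k3)
  expect_equal(d3$ltm_ori, -0.4)  # only the defined k contributes
  expect_equal(d3$ltm_abs, 0.4)
  expect_identical(d3$n_k_used, 1L)
})

test_that("compiled and pure-R screen engines agree exactly", {
  sim <- small_sim(seed = 7, n_samples = 80, n_genes = 50)
  cand <- rownames(sim$expression)[c(1, 5, 18, 19, 40)]
  a <- ltm_screen(sim$expression, clock, ref, k_settings = c(4, 6),
                  candidates = cand, min_group_size = 5)
  b <- ltm_screen(sim$expression, clock, ref, k_settings = c(4, 6),
                  candidates = cand, min_group_size = 5, engine = "r")
  expect_equal(a$scores, b$scores, tolerance = 1e-10)

  # spearman flavor too
  a2 <- ltm_screen(sim$expression, clock, ref, k_settings = 4,
                   candidates = cand, min_group_size = 5,
                   method = "pearson", flavor = "spearman")
  b2 <- ltm_screen(sim$expression, clock, ref, k_settings = 4,
                   candidates = cand, min_group_size = 5,
                   method = "pearson", flavor = "spearman", engine = "r")
  expect_equal(a2$scores, b2$scores, tolerance = 1e-10)
})

test_that("screen scores respect their ranges and flag clock genes", {
  sim <- small_sim(seed = 9, n_samples = 100, n_genes = 80)
  res <- ltm_screen(sim$expression, clock, ref, k_settings = c(4, 7),
                    min_group_size = 10)
  s <- res$scores
  for (col in grep("^(r_ncv|r_zstat|ltm_pre)_k", names(s), value = TRUE)) {
    expect_true(all(abs(s[[col]]) <= 1 + 1e-12, na.rm = TRUE))
  }
  expect_true(all(s$ltm_abs >= 0 & s$ltm_abs <= 1 + 1e-12, na.rm = TRUE))
  expect_identical(s$is_clock_gene, s$gene %in% clock$gene)
  expect_identical(nrow(s), nrow(sim$expression))

  # LTMpre/LTMori consistency with the per-k columns
  pre <- as.matrix(s[, c("ltm_pre_k4", "ltm_pre_k7")])
  expect_equal(s$ltm_ori, rowMeans(pre, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(s$ltm_abs, abs(s$ltm_ori), tolerance = 1e-12)
})

test_that("monotone relabeling of the driver preserves partition and rank scores", {
  sim <- small_sim(seed = 16, n_samples = 80, n_genes = 60)
  m <- sim$expression
  m2 <- m
  m2["coupler", ] <- m["coupler", ]^1.7 / 50  # strictly increasing on >= 0

  # the partition itself is invariant
  expect_identical(partition_samples(m["coupler", ], 4),
                   partition_samples(m2["coupler", ], 4))

  # with rank-based across-group correlations the scores are unchanged
  # (the transformed driver also perturbs the all-gene nCV denominator, a
  # 1/G effect that cannot reorder the group summaries here)
  a <- ltm_screen(m, clock, ref, k_settings = c(4, 7),
                  candidates = "coupler", min_group_size = 5,
                  flavor = "spearman")
  b <- ltm_screen(m2, clock, ref, k_settings = c(4, 7),
                  candidates = "coupler", min_group_size = 5,
                  flavor = "spearman")
  expect_equal(a$scores$ltm_pre_k4, b$scores$ltm_pre_k4, tolerance = 1e-9)
  expect_equal(a$scores$ltm_pre_k7, b$scores$ltm_pre_k7, tolerance = 1e-9)
})

test_that("screen validates candidates and group sizes", {
  sim <- small_sim(seed = 1, n_samples = 60, n_genes = 40)
  expect_error(ltm_screen(sim$expression, clock, ref, k_settings = 4,
                          candidates = character(0), min_group_size = 5),
               "empty candidate")
  expect_error(ltm_screen(sim$expression, clock, ref,
                          candidates = "nope", min_group_size = 5),
               "not in matrix")
  expect_error(ltm_screen(sim$expression, clock, ref, k_settings = 10),
               "min_group_size")
})

test_that("gene filter retains genes by Q1 level and Q4/Q1 fold change", {
  # all retained at vacuous thresholds: Q4 mean >= Q1 mean by construction
  m <- rand_matrix(20, 40, seed = 19)
  expect_identical(ltm_gene_filter(m, 4, 0, 1), rownames(m))

  # constant gene has fold change exactly 1
  mc <- make_matrix(rbind(rep(5, 8), c(1, 1, 1, 1, 9, 9, 9, 9),
                          c(0, 0, 0, 0, 4, 4, 4, 4)),
                    genes = c("const", "fold9", "zeroq1"))
  expect_identical(ltm_gene_filter(mc, 4, 0, 1.2), c("fold9", "zeroq1"))
  expect_identical(ltm_gene_filter(mc, 4, 0.5, 1.2), "fold9")

  # five-gene fixture against per-gene hand evaluation
  mf <- make_matrix(rbind(c(2, 2, 4, 8),    # q1 2, fold 4
                          c(1, 1, 1, 1.5),  # q1 1, fold 1.5
                          c(0.1, 0.2, 0.3, 0.4),
                          c(10, 10, 10, 10),
                          c(0, 5, 5, 5)),
                    genes = paste0("g", 1:5), samples = paste0("s", 1:4))
  got <- ltm_gene_filter(mf, k = 2, min_q1_expression = 0.5,
                         min_fold_change = 1.4)
  # k=2 halves: g1 q1=2 q2=6 fold 3 keep; g2 q1=1 q2=1.25 fold 1.25 drop;
  # g3 q1=0.15 drop (q1 < 0.5); g4 fold 1 drop; g5 q1=2.5 q2=5 fold 2 keep
  expect_identical(got, c("g1", "g5"))
})

test_that("meta-integration averages LTMori across datasets", {
  t1 <- tibble::tibble(gene = c("a", "b"), ltm_ori = c(0.6, 0.3))
  t2 <- tibble::tibble(gene = c("a", "b"), ltm_ori = c(-0.6, 0.5))
  t3 <- tibble::tibble(gene = c("a", "b"), ltm_ori = c(0, 0.7))
  out <- ltm_meta(list(t1, t2, t3))
  expect_equal(out$ltm_abs_integrated[out$gene == "a"], 0)
  expect_equal(out$ltm_ori_integrated[out$gene == "b"], 0.5)

  # identical tables integrate to themselves
  same <- ltm_meta(list(t1, t1))
  expect_equal(same$ltm_ori_integrated[match(t1$gene, same$gene)],
               t1$ltm_ori)

  # disjoint gene universes
  t4 <- tibble::tibble(gene = c("x", "y"), ltm_ori = c(0.1, 0.2))
  expect_error(ltm_meta(list(t1, t4)), "no gene")
  # but allowed when min_datasets relaxes the intersection
  relaxed <- ltm_meta(list(t1, t4), min_datasets = 1)
  expect_setequal(relaxed$gene, c("a", "b", "x", "y"))

  expect_error(ltm_meta(list(t1)), ">= 2")
})

test_that("background normalization is seeded and centers on 1", {
  tbl <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                        ltm_abs = rep(0.37, 200))
  out <- background_normalize(tbl, c("g001", "g100"), n_rounds = 50, seed = 2)
  expect_equal(out$normalized, c(1, 1))

  withr::with_seed(77, tbl$ltm_abs <- stats::runif(200))
  a <- background_normalize(tbl, tbl$gene[1:10], n_rounds = 100, seed = 9)
  b <- background_normalize(tbl, tbl$gene[1:10], n_rounds = 100, seed = 9)
  expect_identical(a, b)

  # many rounds: normalizer converges to the all-gene mean LTMabs
  big <- background_normalize(tbl, tbl$gene[1:10], n_rounds = 4000, seed = 3)
  pop_mean <- mean(tbl$ltm_abs)
  se <- stats::sd(tbl$ltm_abs) / sqrt(10) / sqrt(4000)
  expect_lt(abs(attr(big, "background") - pop_mean), 4 * se)

  expect_error(background_normalize(tbl, "g001", n_rounds = 0), ">= 1")
})

test_that("tidy, glance and autoplot work on screen results", {
  sim <- small_sim(seed = 21, n_samples = 60, n_genes = 40)
  res <- ltm_screen(sim$expression, clock, ref, k_settings = c(4, 6),
                    min_group_size = 5)
  td <- tidy(res)
  expect_identical(nrow(td), nrow(res$scores) * 2L)
  expect_setequal(unique(td$k), c(4L, 6L))
  # long form matches the wide columns
  k4 <- td[td$k == 4L, ]
  expect_equal(k4$ltm_pre[match(res$scores$gene, k4$gene)],
               res$scores$ltm_pre_k4)

  gl <- glance(res)
  expect_identical(gl$n_candidates, nrow(res$scores))
  expect_true(gl$max_ltm_abs <= 1)

  expect_s3_class(autoplot(res, highlight = "coupler"), "ggplot")
  heat <- ltm_heat(sim$expression, "coupler", 4, clock$gene, ref)
  expect_s3_class(autoplot(heat), "ggplot")
})
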