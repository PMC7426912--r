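test_that("repeated selection is deterministic and composes with drpt_select", {
  D <- make_labelled_dataset(19)
  cfg <- eval_config(n_runs = 3, base_seed = 11)
  r1 <- run_repeated_selection(D, drpt_params(), cfg)
  r2 <- run_repeated_selection(D, drpt_params(), cfg)
  expect_identical(purrr::map(r1, "genes"), purrr::map(r2, "genes"))
  one <- run_repeated_selection(D, drpt_params(), eval_config(n_runs = 1, base_seed = 11))
  expect_identical(one$run1$genes, drpt_select(D, drpt_params(), seed = 11)$genes)
})

test_that("stratified folds balance both class and total counts", {
  y <- c(rep(1, 6), rep(0, 4))
  f <- stratified_kfold(y, 5, seed = 2)
  expect_true(all(table(f) == 2))
  pos_per_fold <- tapply(y, f, sum)
  expect_true(all(pos_per_fold %in% 1:2))
})

test_that("stratification bound holds across random label vectors", {
  withr::with_seed(27, {
    for (i in 1:25) {
      n1 <- sample(5:30, 1)
      n0 <- sample(5:30, 1)
      k <- sample(2:5, 1)
      y <- sample(c(rep(1, n1), rep(0, n0)))
      f <- stratified_kfold(y, k, seed = i)
      for (cls in 0:1) {
        per_fold <- tabulate(f[y == cls], nbins = k)
        share <- sum(y == cls) / k
        expect_true(all(abs(per_fold - share) < 1))
      }
    }
  })
})

test_that("folds are reproducible, degenerate to leave-one-out, and reject bad k", {
  y <- rep(0:1, each = 10)
  expect_identical(stratified_kfold(y, 5, seed = 3),
                   stratified_kfold(y, 5, seed = 3))
  loo <- stratified_kfold(rep(0:1, each = 5), 10, seed = 4)
  expect_true(all(table(loo) == 1))
  expect_error(stratified_kfold(y, 1, seed = 1), "at least 2")
  expect_error(stratified_kfold(c(0, 1), 3, seed = 1), "more folds")
})

test_that("average precision reproduces the hand-worked step sum", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               0.5 * 1 + 0 * 0.5 + 0.5 * (2 / 3), tolerance = 1e-12)
  # perfect separation
  expect_equal(average_precision(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  # all scores tied: one threshold, precision = prevalence
  expect_equal(average_precision(rep(1, 4), c(1, 0, 0, 1)), 0.5)
  expect_error(average_precision(1:3, c(0, 0, 0)), "no positive")
})

# Independent oracle: walk thresholds one by one and accumulate the step sum
# from explicitly counted confusion-matrix entries.
brute_force_ap <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  ap <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    p <- tp / sum(pred)
    r <- tp / sum(labels == 1)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

test_that("average precision equals exhaustive brute force on all labelings of 8 items", {
  withr::with_seed(33, {
    scores <- sample(seq(0.1, 0.8, by = 0.1))
    for (bits in 1:255) {
      labels <- as.integer(intToBits(bits))[1:8]
      expect_equal(average_precision(scores, labels),
                   brute_force_ap(scores, labels), tolerance = 1e-12)
    }
    # and on tied scores
    for (i in 1:20) {
      s <- sample(1:4, 8, replace = TRUE)
      l <- sample(c(0, 1), 8, replace = TRUE)
      if (sum(l) == 0) l[1] <- 1
      expect_equal(average_precision(s, l), brute_force_ap(s, l),
                   tolerance = 1e-12)
    }
  })
})

test_that("cross-validation scores an informative subset highly on separable data", {
  cfg <- sim_config(n_controls = c(15, 15), n_cases = c(15, 15),
                    n_genes = 100, n_informative = 8, effect_size = 3,
                    missing_rate = 0, gene_drop_rate = 0, seed = 40)
  sim <- simulate_multi_study(cfg)
  D <- preprocess_simulated(sim)
  panel <- intersect(sim$truth$informative, expr_genes(D))
  sc <- cross_validate_subset(D, panel, eval_config(base_seed = 8), id = "inf")
  expect_gte(sc$mean_ap, 0.95)
  expect_equal(length(sc$fold_aps), 15)
  expect_equal(sc$mean_ap, mean(sc$fold_aps))
  # determinism
  sc2 <- cross_validate_subset(D, panel, eval_config(base_seed = 8), id = "inf")
  expect_identical(sc$fold_aps, sc2$fold_aps)
})

test_that("a pure-noise subset scores near prevalence under cross-validation", {
  cfg <- sim_config(n_controls = c(25, 25), n_cases = c(25, 25),
                    n_genes = 100, n_informative = 0, effect_size = 0,
                    missing_rate = 0, gene_drop_rate = 0, seed = 41)
  D <- preprocess_simulated(simulate_multi_study(cfg))
  noise_panel <- head(sort(expr_genes(D)), 20)
  sc <- cross_validate_subset(D, noise_panel, eval_config(base_seed = 9))
  # null AP center for folds of 20 with 10 positives, derived by simulation
  null_center <- withr::with_seed(10, {
    mean(replicate(2000, average_precision(runif(20), rep(0:1, each = 10))))
  })
  expect_lt(abs(sc$mean_ap - null_center), 0.15)
})

test_that("subset ranking orders by AP then parsimony then id", {
  mk <- function(id, ap, size) {
    structure(list(id = id, genes = paste0("g", seq_len(size)), size = size,
                   mean_ap = ap, sd_ap = 0, fold_aps = ap),
              class = "subset_score")
  }
  scores <- list(mk("s1", 0.97, 40), mk("s2", 0.96, 30), mk("s3", 0.90, 10))
  expect_identical(rank_subsets_top_t(scores, 2), c("s1", "s2"))
  tied <- list(mk("a", 0.9, 20), mk("b", 0.9, 10), mk("c", 0.9, 30))
  expect_identical(rank_subsets_top_t(tied, 1), "b")
  expect_error(rank_subsets_top_t(scores, 4), "exceeds")
})

test_that("selection frequencies count genes across subsets", {
  subs <- list(structure(list(genes = c("A", "B")), class = "feature_subset"),
               structure(list(genes = c("B", "C")), class = "feature_subset"))
  freq <- selection_frequencies(subs)
  expect_equal(freq$count[match(c("A", "B", "C"), freq$gene)], c(1L, 2L, 1L))
  expect_equal(sum(freq$count), 4)
  one <- selection_frequencies(subs[1])
  expect_true(all(one$count == 1))
})

test_that("the QQ rule isolates a planted high-count tail exactly", {
  withr::with_seed(2, {
    freq <- tibble::tibble(gene = sprintf("g%03d", 1:205),
                           count = c(sample(1:5, 200, replace = TRUE),
                                     rep(40L, 5)))
  })
  c_star <- qq_frequency_threshold(freq)
  frequent <- frequent_gene_subset(freq, c_star)
  expect_setequal(frequent$genes, freq$gene[freq$count == 40])
})

test_that("normal-looking counts yield the maximum count (empty frequent set)", {
  withr::with_seed(3, {
    freq <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                           count = as.integer(pmax(1, round(rnorm(200, 20, 4)))))
  })
  expect_equal(qq_frequency_threshold(freq), max(freq$count))
})

test_that("equal counts require an override and overrides bypass the rule", {
  freq <- tibble::tibble(gene = letters[1:12], count = rep(5L, 12))
  expect_error(qq_frequency_threshold(freq), "override")
  expect_equal(qq_frequency_threshold(freq, override = 3), 3L)
})

test_that("frequent-gene subsets use strict inequality and tie-order by symbol", {
  freq <- tibble::tibble(gene = c("A", "B", "C"), count = c(40L, 31L, 10L))
  expect_identical(frequent_gene_subset(freq, 31)$genes, "A")
  expect_identical(frequent_gene_subset(freq, 0)$genes, c("A", "B", "C"))
  tie <- tibble::tibble(gene = c("B", "A"), count = c(32L, 32L))
  expect_identical(frequent_gene_subset(tie, 31)$genes, c("A", "B"))
  expect_error(frequent_gene_subset(freq, 40), "no gene")
})

test_that("frequent-subset size is non-increasing in the threshold", {
  withr::with_seed(44, {
    freq <- tibble::tibble(gene = sprintf("g%02d", 1:50),
                           count = sample(1:60, 50, replace = TRUE))
    sizes <- vapply(0:59, function(cs) {
      tryCatch(length(frequent_gene_subset(freq, cs)$genes),
               error = function(e) 0L)
    }, integer(1))
    expect_true(all(diff(sizes) <= 0))
  })
})

test_that("informative genes are selected more often than null genes across runs", {
  cfg <- sim_config(n_controls = c(12, 12), n_cases = c(12, 12),
                    n_genes = 300, n_informative = 10, effect_size = 2,
                    missing_rate = 0, gene_drop_rate = 0, seed = 50)
  sim <- simulate_multi_study(cfg)
  D <- preprocess_simulated(sim)
  subs <- run_repeated_selection(D, drpt_params(),
                                 eval_config(n_runs = 50, base_seed = 60))
  freq <- selection_frequencies(subs)
  counts <- setNames(rep(0L, length(expr_genes(D))), expr_genes(D))
  counts[freq$gene] <- freq$count
  inf <- names(counts) %in% sim$truth$informative
  wt <- wilcox.test(counts[inf], counts[!inf], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
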