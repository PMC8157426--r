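test_that("the balanced design produces the stated shape and labels", {
  sim <- simulate_counts(sim_config(seed = 1L))
  expect_equal(dim(sim$cm), c(1000L, 2500L))
  expect_equal(unname(table(sim$cm$labels)), rep(250L, 4L),
               ignore_attr = TRUE)
  expect_true(all(sim$cm$counts >= 0))
  expect_true(all(sim$cm$counts == round(sim$cm$counts)))
})

test_that("dropout vanishes at extreme negative midpoints and grows with mid", {
  base <- sim_config(n_genes = 800L, group_sizes = rep(60L, 4L), seed = 9L)
  rates <- vapply(c(-10, -1, 0, 1, 1.5), function(mid) {
    cfg <- base
    cfg$dropout_mid <- mid
    simulate_counts(cfg)$true_dropout_rate
  }, numeric(1))
  expect_lt(rates[1], 0.01)       # logistic limit: pi -> 0
  expect_true(all(diff(rates) > 0))  # strictly increasing in mid
})

test_that("simulation is byte-deterministic under seed", {
  cfg <- sim_config(n_genes = 300L, group_sizes = rep(25L, 2L), seed = 33L)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$true_dropout_rate, b$true_dropout_rate)
})

test_that("the balanced suite covers 12 designs with uniform groups", {
  suite <- make_balanced_suite(seed = 2L, n_genes = 200L,
                               cells_per_group = 20L)
  expect_length(suite, 12L)
  design <- attr(suite, "design")
  expect_setequal(unique(design$groups), c(4L, 8L, 16L))
  expect_setequal(unique(design$mid), c(-1, 0, 1, 1.5))
  for (i in seq_along(suite)) {
    tab <- table(suite[[i]]$cm$labels)
    expect_true(all(tab == 20L))
    expect_equal(length(tab), design$groups[i])
  }
  # realized dropout ordered by mid within each group count
  for (g in c(4L, 8L, 16L)) {
    idx <- order(design$mid[design$groups == g])
    rates <- vapply(suite[design$groups == g],
                    function(s) s$true_dropout_rate, numeric(1))[idx]
    expect_true(all(diff(rates) > 0))
  }
})

test_that("imbalanced sizes hit the totals, ratio band and floor", {
  for (g in c(4L, 8L, 16L)) {
    ratio <- c(`4` = 0.6, `8` = 0.08, `16` = 0.01)[[as.character(g)]]
    sizes <- contraclust:::imbalanced_sizes(3000L, g, ratio)
    expect_equal(sum(sizes), 3000L)
    expect_lte(min(sizes) / max(sizes), 0.6)
    expect_gte(min(sizes), 10L)
  }
  suite <- make_imbalanced_suite(seed = 3L, n_genes = 150L,
                                 total_cells = 400L)
  expect_length(suite, 12L)
  for (s in suite) expect_equal(nrow(s$cm$counts), 400L)
})

test_that("stratified downsampling preserves label proportions", {
  counts <- matrix(rpois(1000 * 5, 3), 1000, 5)
  cm <- count_matrix(counts, labels = rep(paste0("g", 1:4), each = 250L))

  expect_identical(stratified_downsample(cm, 1, seed = 1L)$cell_ids,
                   cm$cell_ids)

  half <- stratified_downsample(cm, 0.5, seed = 1L)
  expect_equal(nrow(half$counts), 500L)
  tab <- table(half$labels)
  expect_true(all(abs(tab - 125L) <= 1L))

  a <- stratified_downsample(cm, 0.5, seed = 1L)
  b <- stratified_downsample(cm, 0.5, seed = 2L)
  expect_false(identical(a$cell_ids, b$cell_ids))
  expect_identical(table(a$labels), table(b$labels))

  expect_error(stratified_downsample(cm, 0), "fraction")
  cm_nolab <- count_matrix(counts)
  expect_error(stratified_downsample(cm_nolab, 0.5), "labels")
})
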