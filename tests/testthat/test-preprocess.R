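test_that("gene filtering drops genes expressed in fewer cells than the threshold", {
  m <- cbind(c(0, 5, 0), c(0, 1, 2), c(1, 1, 1))
  colnames(m) <- c("one_cell", "two_cells", "all_cells")
  cm <- count_matrix(m, cell_ids = paste0("c", 1:3))
  filtered <- filter_genes(cm, min_cells_expressed = 2L)
  expect_identical(filtered$gene_ids, c("two_cells", "all_cells"))
  expect_identical(filtered$cell_ids, cm$cell_ids)
  # a dense matrix is untouched
  dense <- count_matrix(matrix(1:9, 3, 3))
  expect_identical(filter_genes(dense, 2L), dense)
  expect_error(filter_genes(cm, 10L), "removed all")
})

test_that("library-size normalization matches hand arithmetic and equalizes totals", {
  cm <- count_matrix(rbind(c(1, 3, 0), c(2, 2, 4)))
  out <- normalize_library_size(cm)
  expect_equal(out$size_factor_target, 6)
  expect_equal(out$values, rbind(c(1.5, 4.5, 0), c(1.5, 1.5, 3)),
               ignore_attr = TRUE)

  set.seed(4)
  m <- matrix(rpois(200, 5) + 1, 20, 10)
  res <- normalize_library_size(m)
  expect_equal(rowSums(res$values),
               rep(res$size_factor_target, 20),
               tolerance = 1e-9)
  # already-equal totals leave the matrix unchanged
  eq <- matrix(c(2, 3, 3, 2), 2, 2)
  expect_equal(normalize_library_size(eq)$values, eq, ignore_attr = TRUE)
  zero <- matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE)
  expect_error(normalize_library_size(zero), "zero total")
})

test_that("log transform is log1p: closed forms and order preservation", {
  expect_equal(log_transform(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(log_transform(matrix(exp(1) - 1, 2, 2)),
               matrix(1, 2, 2))
  set.seed(6)
  m <- matrix(rexp(100), 10, 10)
  lt <- log_transform(m)
  o1 <- order(m)
  expect_identical(order(lt), o1)  # entrywise monotone
  expect_error(log_transform(matrix(-1, 2, 2)), "non-negative")
})

test_that("HVG selection ranks by dispersion and recovers planted genes", {
  # identical means, different variances: higher variance ranks first
  m <- cbind(lowvar = c(1, 2, 3, 2, 2), highvar = c(0, 2, 4, 4, 0))
  expect_equal(mean(m[, 1]), mean(m[, 2]))
  sel <- select_hvg(m, n_top = 2L)
  expect_identical(sel$selected_genes[1L], "highvar")

  # n_top = d keeps all genes, permuted into rank order
  set.seed(8)
  m2 <- matrix(rexp(60), 10, 6, dimnames = list(NULL, paste0("g", 1:6)))
  sel2 <- select_hvg(m2, n_top = 6L)
  expect_setequal(sel2$selected_genes, colnames(m2))
  expect_error(select_hvg(m2, n_top = 7L), "exceeds")

  # planted group-structured genes surface in the top 50 of 2000
  set.seed(123)
  n <- 100L
  d <- 2000L
  bg <- matrix(rnorm(n * d, mean = 2, sd = 0.3), n, d)
  planted <- 1:10
  grp <- rep(c(0, 2), each = n / 2)
  for (g in planted) bg[, g] <- rnorm(n, mean = 1 + grp, sd = 0.3)
  colnames(bg) <- paste0("g", seq_len(d))
  top50 <- select_hvg(bg, n_top = 50L)$selected_genes
  expect_gte(sum(paste0("g", planted) %in% top50), 8L)
})

test_that("per-gene scaling centers, standardizes and zeroes constant genes", {
  sc <- scale_genes(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(mean(sc$values[, "a"]), 0)
  expect_equal(stats::sd(sc$values[, "a"]), 1)
  expect_equal(sc$values[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(sc$per_gene_std[["b"]], 0)

  set.seed(10)
  m <- matrix(rnorm(500), 25, 20)
  out <- scale_genes(m)$values
  expect_true(all(abs(colMeans(out)) < 1e-10))
  expect_true(all(abs(apply(out, 2, stats::sd) - 1) < 1e-4))
})

test_that("the full recipe composes, respects toggles, and is deterministic", {
  sim <- tiny_sim(cells = 50L, genes = 600L, seed = 21L)
  pm <- preprocess(sim$cm, preprocess_config(n_top_genes = 200L))
  expect_equal(ncol(pm$values), 200L)
  expect_true(all(abs(colMeans(pm$values)) < 1e-6))
  sds <- apply(pm$values, 2, stats::sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-4))

  # toggles: no log, no scaling, all genes -> filtering + normalization only
  raw_cfg <- preprocess_config(n_top_genes = "all", log = FALSE,
                               scale = FALSE)
  pm_raw <- preprocess(sim$cm, raw_cfg)
  filt <- filter_genes(sim$cm, 2L)
  norm <- normalize_library_size(filt)
  expect_equal(sort(pm_raw$selected_genes), sort(filt$gene_ids))
  expect_equal(rowSums(pm_raw$values), rowSums(norm$values))

  pm2 <- preprocess(sim$cm, preprocess_config(n_top_genes = 200L))
  expect_identical(pm$values, pm2$values)  # bit-identical rerun
})

test_that("HVG ranking is invariant to gene order up to ties", {
  set.seed(31)
  m <- matrix(rexp(400), 20, 20, dimnames = list(NULL, paste0("g", 1:20)))
  perm <- sample(20L)
  a <- select_hvg(m, n_top = 5L)$selected_genes
  b <- select_hvg(m[, perm], gene_ids = colnames(m)[perm],
                  n_top = 5L)$selected_genes
  expect_setequal(a, b)
})
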