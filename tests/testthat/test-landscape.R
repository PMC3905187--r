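test_that("sample vectors are the transpose view of codebook or input", {
  cb <- random_codebook(hex_map(1), 2)
  cb$prototypes <- matrix(1:6, 3, 2) # deliberately inconsistent with spec n
  sv <- sample_vectors(cb)
  expect_identical(dim(sv), c(2L, 3L))
  expect_identical(sv, t(cb$prototypes))
  x <- named_matrix(rnorm(12), 4, 3)
  expect_identical(sample_vectors(x), t(x))
  expect_identical(t(sample_vectors(x)), x)
})

test_that("similarity metrics satisfy their self-similarity and symmetry", {
  set.seed(43)
  v <- matrix(rnorm(60), 5, 12, dimnames = list(paste0("s", 1:5), NULL))
  for (metric in c("pearson", "spearman", "kendall", "cosine")) {
    sm <- similarity_matrix(v, metric)
    expect_equal(unname(diag(sm$values)), rep(1, 5))
    expect_lt(max(abs(sm$values - t(sm$values))), 1e-9)
    expect_true(all(sm$values <= 1 + 1e-12))
  }
  for (metric in c("euclidean", "cityblock")) {
    sm <- similarity_matrix(v, metric)
    expect_equal(unname(diag(sm$values)), rep(0, 5))
    expect_lt(max(abs(sm$values - t(sm$values))), 1e-9)
    expect_true(all(sm$values >= 0))
  }
  sm <- similarity_matrix(v, "mutual_information")
  expect_lt(max(abs(sm$values - t(sm$values))), 1e-9)
})

test_that("metric values match independent references", {
  set.seed(47)
  a <- rnorm(12); b <- rnorm(12)
  v <- rbind(s1 = a, s2 = b)
  expect_equal(similarity_matrix(v, "pearson")$values[1, 2], cor(a, b))
  expect_equal(similarity_matrix(v, "spearman")$values[1, 2],
               cor(a, b, method = "spearman"))
  expect_equal(similarity_matrix(v, "kendall")$values[1, 2],
               cor(a, b, method = "kendall"))
  expect_equal(similarity_matrix(v, "euclidean")$values[1, 2],
               sqrt(sum((a - b)^2)))
  expect_equal(similarity_matrix(v, "cityblock")$values[1, 2],
               sum(abs(a - b)))
  expect_equal(similarity_matrix(v, "cosine")$values[1, 2],
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)))

  # mutual information diagonal = plug-in entropy of the discretised vector
  bins <- ceiling(sqrt(12))
  width <- (max(a) - min(a)) / bins
  bin <- pmin(floor((a - min(a)) / width) + 1, bins)
  p <- as.vector(table(bin)) / 12
  h <- -sum(p * log2(p))
  expect_equal(similarity_matrix(v, "mutual_information")$values[1, 1], h)
})

test_that("zero-variance vectors under correlation metrics warn and yield 0", {
  v <- rbind(s1 = rep(2, 6), s2 = rnorm(6))
  expect_warning(sm <- similarity_matrix(v, "pearson"), "zero-variance")
  expect_equal(unname(sm$values[1, ]), c(0, 0))
  expect_equal(unname(sm$values[2, 2]), 1)
})

test_that("landscape places one sample per cell on a near-square lattice", {
  v1 <- matrix(rnorm(5), 1, 5, dimnames = list("only", NULL))
  ls1 <- train_landscape(v1)
  expect_identical(c(ls1$nx, ls1$ny), c(1L, 1L))
  expect_identical(ls1$placement$row, 1L)
  expect_identical(ls1$placement$col, 1L)
  expect_identical(ls1$order, "only")

  set.seed(53)
  v <- matrix(rnorm(7 * 20), 7, 20, dimnames = list(paste0("s", 1:7), NULL))
  ls <- train_landscape(v, seed = 1)
  expect_identical(c(ls$nx, ls$ny), c(3L, 3L))
  cells <- paste(ls$placement$row, ls$placement$col)
  expect_identical(anyDuplicated(cells), 0L)
  expect_true(all(ls$placement$row >= 1 & ls$placement$row <= 3))
  expect_true(all(ls$placement$col >= 1 & ls$placement$col <= 3))
  ls2 <- train_landscape(v, seed = 1)
  expect_identical(ls$placement, ls2$placement)
})

test_that("identical samples end up on neighbouring cells after collisions", {
  set.seed(59)
  base <- rnorm(30)
  others <- matrix(rnorm(7 * 30, sd = 4), 7, 30)
  rownames(others) <- paste0("o", 1:7)
  v <- rbind(a = base, b = base, others) # 9 samples -> 3 x 3 lattice
  ls <- train_landscape(v, seed = 2)
  p <- ls$placement
  da <- p[p$sample == "a", ]
  db <- p[p$sample == "b", ]
  expect_lte(max(abs(da$row - db$row), abs(da$col - db$col)), 1)
})

test_that("samples in correlated groups land closer than across groups", {
  set.seed(61)
  b1 <- rnorm(80, sd = 3); b2 <- rnorm(80, sd = 3)
  v <- rbind(
    a1 = b1 + rnorm(80, sd = 0.3), a2 = b1 + rnorm(80, sd = 0.3),
    a3 = b1 + rnorm(80, sd = 0.3),
    b1 = b2 + rnorm(80, sd = 0.3), b2 = b2 + rnorm(80, sd = 0.3),
    b3 = b2 + rnorm(80, sd = 0.3))
  cors <- cor(t(v))
  grp <- rep(1:2, each = 3)
  expect_gt(min(cors[1:3, 1:3]), 0.95)
  expect_lt(max(abs(cors[1:3, 4:6])), 0.2)
  ls <- train_landscape(v, seed = 3)
  p <- ls$placement[match(rownames(v), ls$placement$sample), ]
  d <- as.matrix(dist(cbind(p$row, p$col)))
  same <- outer(grp, grp, "==")
  ut <- upper.tri(d)
  expect_lt(mean(d[ut & same]), mean(d[ut & !same]))
})

test_that("component reordering is row-major and order-insensitive", {
  set.seed(67)
  feats <- matrix(rnorm(6 * 40), 6, 40,
                  dimnames = list(paste0("s", 1:6), NULL))
  ls <- train_landscape(feats, seed = 4)
  cb <- structure(list(prototypes = t(feats), spec = hex_map(1),
                       col_ids = rownames(feats)), class = "som_codebook")
  ord <- reorder_components(cb, ls)
  p <- ls$placement[match(ord, ls$placement$sample), ]
  expect_true(all(diff(p$row * 100 + p$col) > 0))

  # permuting input sample order leaves the display ordering unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  ls_p <- train_landscape(feats[perm, ], seed = 4)
  expect_identical(reorder_components(cb, ls_p), ord)

  cb_bad <- cb
  cb_bad$col_ids <- paste0("x", 1:6)
  expect_error(reorder_components(cb_bad, ls), "do not match")
})
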