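test_that("neighbourhood kernels match their closed forms", {
  expect_equal(kernel_value("gaussian", 0, 1), 1)
  expect_equal(kernel_value("gaussian", 2, 2), exp(-1 / 2))
  expect_equal(kernel_value("bubble", c(0, 1, 1.0001), 1), c(1, 1, 0))
  expect_equal(kernel_value("cutgaussian", c(0.5, 1.5), 1),
               c(exp(-0.125), 0))
  expect_equal(kernel_value("epanechnikov", c(0, 0.5, 1, 2), 1),
               c(1, 0.75, 0, 0))
  expect_error(kernel_value("gaussian", 1, 0), "positive")
  expect_error(kernel_value("gaussian", 1, -1), "positive")
})

test_that("BMU search agrees with a brute-force scan, including ties", {
  spec <- hex_map(3)
  proto <- named_matrix(0, 19, 2)
  proto[5, ] <- c(1, 1)
  cb <- random_codebook(spec, 2)
  cb$prototypes <- proto
  got <- find_bmu(cb, c(1, 1))
  expect_identical(got$winner, 5L)
  expect_identical(got$ties, 5L)

  proto2 <- matrix(seq_len(38), 19, 2)
  proto2[9, ] <- proto2[3, ] # exact duplicates closest to their own value
  cb$prototypes <- proto2
  got2 <- find_bmu(cb, proto2[3, ])
  expect_identical(got2$winner, 3L)
  expect_identical(got2$ties, c(3L, 9L))

  expect_error(find_bmu(cb, c(1, 2, 3)), "length")

  set.seed(42)
  for (trial in 1:50) {
    cb <- random_codebook(spec, 3)
    v <- rnorm(3)
    expect_identical(find_bmu(cb, v)$winner, oracle_bmu(cb$prototypes, v)$winner)
  }
})

test_that("uniform init respects component ranges and is seed-reproducible", {
  spec <- hex_map(2)
  x <- named_matrix(rep(c(2, -1, 0.5), each = 4), 4, 3)
  cb <- som_init(x, spec, "uniform", seed = 1)
  # degenerate ranges: every prototype is a copy of the single row value
  expect_true(all(abs(sweep(cb$prototypes, 2, x[1, ])) < 1e-12))
  x2 <- named_matrix(rnorm(12), 4, 3)
  a <- som_init(x2, spec, "uniform", seed = 9)
  b <- som_init(x2, spec, "uniform", seed = 9)
  expect_identical(a$prototypes, b$prototypes)
  for (d in seq_len(3)) {
    expect_true(all(a$prototypes[, d] >= min(x2[, d])))
    expect_true(all(a$prototypes[, d] <= max(x2[, d])))
  }
  expect_error(som_init(matrix(numeric(0), 0, 0), spec), "non-empty")
})

test_that("linear init lays prototypes in the principal plane of the data", {
  set.seed(3)
  u <- rnorm(5); w <- rnorm(5)
  a <- rnorm(40); b <- rnorm(40)
  x <- named_matrix(0, 40, 5)
  x[] <- outer(a, u) + outer(b, w)
  spec <- hex_map(3)
  cb <- som_init(x, spec, "linear")
  # residual of prototypes outside the affine span of the rank-2 data
  mu <- colMeans(x)
  base <- svd(sweep(x, 2, mu))$v[, 1:2]
  centred <- sweep(cb$prototypes, 2, mu)
  resid <- centred - centred %*% base %*% t(base)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("one batch epoch on identical rows pulls updated prototypes to the row", {
  spec <- hex_map(2)
  v <- c(3, -1, 2)
  x <- named_matrix(rep(v, each = 8), 8, 3)
  ph <- data.frame(epochs = 1L, sigma_start = 2, sigma_end = 2,
                   alpha_start = 0.5, alpha_end = 0.5)
  fit <- som_train(x, spec = spec,
                   config = som_config(phases = ph, init = "uniform",
                                       seed = 2))
  # gaussian sigma=2 gives every node nonzero weight on a radius-2 map
  expect_true(all(abs(sweep(fit$codebook$prototypes, 2, v)) < 1e-9))
})

test_that("sequential updates follow the learning rule exactly", {
  spec <- hex_map(1)
  x <- named_matrix(c(2, -3), 1, 2)
  # alpha = 1 at distance 0: prototype jumps exactly onto the input row
  ph <- data.frame(epochs = 1L, sigma_start = 1, sigma_end = 1,
                   alpha_start = 1, alpha_end = 1)
  fit <- som_train(x, spec = spec,
                   config = som_config(algorithm = "sequential", phases = ph,
                                       init = "uniform", seed = 5))
  expect_equal(unname(fit$codebook$prototypes[1, ]), c(2, -3))
  # alpha = 0 leaves the codebook untouched
  ph0 <- data.frame(epochs = 2L, sigma_start = 1, sigma_end = 1,
                    alpha_start = 0, alpha_end = 0)
  x2 <- named_matrix(rnorm(20), 10, 2)
  cb0 <- som_init(x2, hex_map(2), "uniform", seed = 11)
  fit0 <- som_train(x2, spec = hex_map(2),
                    config = som_config(algorithm = "sequential",
                                        phases = ph0, init = "uniform",
                                        seed = 11))
  expect_equal(fit0$codebook$prototypes, cb0$prototypes)
})

test_that("training is bit-reproducible under a fixed seed", {
  x <- named_matrix(rnorm(60), 20, 3)
  for (alg in c("batch", "sequential")) {
    f1 <- som_train(x, radius = 2, config = som_config(algorithm = alg,
                                                       init = "uniform",
                                                       seed = 4))
    f2 <- som_train(x, radius = 2, config = som_config(algorithm = alg,
                                                       init = "uniform",
                                                       seed = 4))
    expect_identical(f1$codebook$prototypes, f2$codebook$prototypes)
    expect_identical(f1$qe_trace, f2$qe_trace)
    expect_identical(f1$mapping$bmu, f2$mapping$bmu)
  }
})

test_that("quantization error matches a brute-force computation", {
  spec <- hex_map(2)
  cb <- random_codebook(spec, 2)
  x <- cb$prototypes[c(2, 5, 7), ]
  rownames(x) <- paste0("g", 1:3)
  expect_equal(quantization_error(x, cb), 0)
  x1 <- named_matrix(c(1, 2), 1, 2)
  cb1 <- random_codebook(hex_map(1), 2)
  expect_equal(quantization_error(x1, cb1),
               sqrt(sum((x1[1, ] - cb1$prototypes[1, ])^2)))
  set.seed(8)
  x10 <- named_matrix(rnorm(20), 10, 2)
  cb10 <- random_codebook(spec, 2)
  oracle <- mean(vapply(seq_len(10), function(i) {
    min(vapply(seq_len(spec$n), function(j)
      sqrt(sum((x10[i, ] - cb10$prototypes[j, ])^2)), numeric(1)))
  }, numeric(1)))
  expect_equal(quantization_error(x10, cb10), oracle, tolerance = 1e-12)
})

test_that("batch training keeps prototypes in the affine span of the data", {
  set.seed(13)
  u <- rnorm(4); w <- rnorm(4)
  x <- named_matrix(0, 30, 4)
  x[] <- outer(rnorm(30), u) + outer(rnorm(30), w) + 1
  fit <- som_train(x, radius = 3, config = som_config(seed = 1))
  mu <- colMeans(x)
  base <- svd(sweep(x, 2, mu))$v[, 1:2]
  centred <- sweep(fit$codebook$prototypes, 2, mu)
  resid <- centred - centred %*% base %*% t(base)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("sign-symmetric data trains to a sign-symmetric codebook", {
  set.seed(21)
  z <- matrix(rnorm(150, sd = 2), 50, 3)
  x <- rbind(z, -z)
  dimnames(x) <- list(paste0("g", 1:100), paste0("s", 1:3))
  fit <- som_train(x, radius = 4, config = som_config(seed = 2))
  proto <- fit$codebook$prototypes
  expect_lt(abs(mean(proto)), 0.15 * sd(proto))
})

test_that("quantization error does not increase over the fine-tune phase", {
  sim <- simulate_genes(200, 4, 3, 0.2, 4, 0.2, seed = 5)
  fit <- som_train(sim$matrix, radius = 4, config = som_config(seed = 5))
  fine <- fit$qe_trace[11:50]
  expect_true(all(diff(fine) <= 1e-6))
})

test_that("genes from the same planted cluster land on nearby nodes", {
  sim <- simulate_genes(300, 5, 4, 0.3, 3, 0.3, seed = 3)
  fit <- som_train(sim$matrix, config = som_config(seed = 3))
  xy <- fit$codebook$spec$xy[fit$mapping$bmu, ]
  lab <- sim$labels
  keep <- lab > 0
  d <- as.matrix(dist(xy[keep, ]))
  same <- outer(lab[keep], lab[keep], "==")
  ut <- upper.tri(d)
  expect_lt(mean(d[ut & same]), mean(d[ut & !same]))
})
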