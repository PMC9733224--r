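clr_of <- function(counts_by_taxon) {
  # counts_by_taxon: taxa x samples integer matrix
  clr_transform(count_table(counts_by_taxon))
}

test_that("CLR matches the direct formula and centers every sample", {
  m <- matrix(c(5L, 5L, 5L, 5L), 4, 1,
              dimnames = list(paste0("t", 1:4), "s1"))
  m <- cbind(m, s2 = c(1L, 3L, 9L, 1L))
  z <- clr_transform(count_table(m), pseudocount = 1)
  expect_equal(unname(z["s1", ]), rep(0, 4), tolerance = 1e-12)
  lg <- log(c(2, 4, 10, 2))
  expect_equal(unname(z["s2", ]), lg - mean(lg), tolerance = 1e-12)
  withr::with_seed(3, {
    r <- matrix(rpois(50 * 10, 20), 50, 10,
                dimnames = list(paste0("t", 1:50), paste0("s", 1:10)))
    zz <- clr_transform(count_table(t(r)))
    expect_true(all(abs(rowSums(zz)) < 1e-9))
  })
  expect_error(clr_transform(count_table(matrix(0:3, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y")))), pseudocount = 0),
    "pseudocount")
})

test_that("the three-part CLR example reproduces its derived values", {
  m <- matrix(c(1L, 3L, 9L, 1L, 3L, 9L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  z <- clr_transform(count_table(m))
  expect_equal(unname(z["s1", ]), c(-0.7676, -0.0744, 0.8419),
               tolerance = 1e-4)
})

test_that("the lambda path spans max correlation down to the ratio", {
  withr::with_seed(5, {
    x <- matrix(rnorm(200), 50, 4)
    x[, 2] <- 0.8 * x[, 1] + 0.2 * x[, 2]
  })
  colnames(x) <- paste0("t", 1:4)
  class(x) <- c("clr_matrix", "matrix")
  C <- suppressWarnings(cor(unclass(x)))
  lambda_max <- max(abs(C[upper.tri(C)]))
  path <- make_lambda_path(x, n_lambda = 2, min_ratio = 0.1)
  expect_equal(path[1], lambda_max, tolerance = 1e-10)
  expect_equal(path[2], lambda_max * 0.1, tolerance = 1e-10)
  long <- make_lambda_path(x, n_lambda = 20, min_ratio = 1e-2)
  expect_true(all(diff(long) < 0))
  # at lambda_max the fitted graph is empty
  B <- mb_fit(x, path[1] * (1 + 1e-10))
  expect_true(all(B == 0))
})

test_that("mb_fit recovers the closed-form two-variable lasso", {
  withr::with_seed(8, {
    u <- rnorm(500)
    x <- cbind(a = u, b = u + rnorm(500, sd = 1e-6), c = rnorm(500))
  })
  B <- mb_fit(x, 0.05)
  # near-duplicate columns select each other with coefficient ~ rho-lambda
  expect_gt(B["a", "b"], 0.9)
  expect_gt(B["b", "a"], 0.9)
  expect_equal(B["a", "b"], 1 - 0.05, tolerance = 1e-3)
  expect_error(mb_fit(matrix(c(1, NA, 2, 3), 2), 0.1), "finite")
})

test_that("independent columns yield near-empty neighborhoods", {
  withr::with_seed(13, {
    x <- matrix(rnorm(1000 * 8), 1000, 8)
  })
  B <- mb_fit(x, 0.5)
  expect_lt(mean(B != 0), 0.01)
})

test_that("mb_fit matches the exhaustive active-set lasso oracle", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      p <- sample(2:4, 1)
      n <- sample(20:60, 1)
      x <- matrix(rnorm(n * p), n, p)
      if (p >= 3) x[, 2] <- 0.6 * x[, 1] + 0.8 * x[, 2]
      lambda <- runif(1, 0.02, 0.6)
      B <- mb_fit(x, lambda)
      O <- oracle_mb(x, lambda)
      expect_lt(max(abs(B - O)), 1e-5)
    }
  })
})

test_that("mb_fit agrees with glmnet on standardized data", {
  skip_if_not_installed("glmnet")
  withr::with_seed(31, {
    n <- 200; p <- 6
    x <- matrix(rnorm(n * p), n, p)
    x[, 2] <- 0.5 * x[, 1] + x[, 2]
  })
  mu <- colMeans(x); sd_pop <- sqrt(colMeans(x^2) - mu^2)
  z <- sweep(sweep(x, 2, mu), 2, sd_pop, "/")
  lambda <- 0.1
  B <- mb_fit(x, lambda)
  for (i in seq_len(p)) {
    fit <- glmnet::glmnet(z[, -i], z[, i], lambda = lambda,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
    expect_equal(unname(B[-i, i]), unname(as.numeric(fit$beta)),
                 tolerance = 1e-4)
  }
})

test_that("edge sets shrink along the path (numerical violations < 1%)", {
  withr::with_seed(17, {
    om <- make_precision(15, "chain", strength = 0.35, seed = 2)
    ct <- sample_counts(om, 150, seed = 3)
  })
  z <- clr_transform(ct)
  path <- make_lambda_path(z, 15, 1e-2)
  cube <- mb_fit(z, path)
  sizes <- vapply(seq_along(path), function(k) sum(cube[, , k] != 0), 0L)
  violations <- sum(pmax(0, -diff(sizes)))
  expect_lte(violations, 0.01 * max(sum(cube[, , length(path)] != 0), 1))
})

test_that("StARS frequencies are symmetric in [0,1], D in [0, 0.5]", {
  withr::with_seed(23, {
    om <- make_precision(12, "chain", strength = 0.35, seed = 5)
    ct <- sample_counts(om, 80, seed = 6)
  })
  z <- clr_transform(ct)
  path <- make_lambda_path(z, 10, 0.05)
  st <- stars_select(z, path, n_subsamples = 20, seed = 9)
  expect_true(all(st$freq >= 0 & st$freq <= 1))
  for (k in seq_along(path)) {
    expect_identical(st$freq[, , k], t(st$freq[, , k]))
    expect_true(all(diag(st$freq[, , k]) == 0))
  }
  expect_true(all(st$instability >= 0 & st$instability <= 0.5))
  expect_true(all(diff(st$monotone_instability) >= 0))
  # reproducible given the seed
  st2 <- stars_select(z, path, n_subsamples = 20, seed = 9)
  expect_identical(st$freq, st2$freq)
  expect_identical(st$lambda_star, st2$lambda_star)
})

test_that("StARS on a planted chain selects a non-empty graph", {
  withr::with_seed(29, {
    om <- make_precision(15, "chain", strength = 0.35, seed = 4)
    ct <- sample_counts(om, 400, seed = 8)
  })
  z <- clr_transform(ct)
  path <- make_lambda_path(z, 15, 1e-2)
  st <- stars_select(z, path, n_subsamples = 30, seed = 10)
  expect_true(is.finite(st$lambda_star))
  B <- mb_fit(z, st$lambda_star)
  net <- assemble_network(B, "or")
  expect_gt(nrow(net$edges), 0)
})

test_that("symmetrization rules and sign conventions are honoured", {
  coef <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  coef["B", "A"] <- 0.3            # A's regression selects B
  or_net <- assemble_network(coef, "or")
  expect_identical(nrow(or_net$edges), 1L)
  expect_identical(or_net$edges$sign, 1)
  expect_identical(or_net$edges$weight, 0.3)
  and_net <- assemble_network(coef, "and")
  expect_identical(nrow(and_net$edges), 0L)
  # larger-magnitude coefficient wins the sign
  coef["B", "A"] <- 0.2
  coef["A", "B"] <- -0.5
  net <- assemble_network(coef, "or")
  expect_identical(net$edges$sign, -1)
  expect_identical(net$edges$weight, -0.5)
})

test_that("stratum inference is deterministic and handles degenerate input", {
  withr::with_seed(37, {
    om <- make_precision(10, "chain", strength = 0.35, seed = 3)
    ct <- sample_counts(om, 12, seed = 4)
  })
  strat <- stratum(8L, "CL", sample_ids(ct))
  cfg <- inference_config(seed = 5)
  n1 <- infer_stratum_network(ct, strat, config = cfg)
  n2 <- infer_stratum_network(ct, strat, config = cfg)
  expect_identical(n1$edges, n2$edges)
  # all-sparse table: too few surviving taxa gives an empty network
  zeros <- count_table(matrix(0L, 5, 6,
                              dimnames = list(paste0("t", 1:5),
                                              paste0("s", 1:6))))
  expect_warning(
    empty <- infer_stratum_network(zeros, stratum(0L, "CL", paste0("s", 1:6))),
    "fewer than 2 taxa|no taxa")
  expect_identical(nrow(empty$edges), 0L)
  expect_error(infer_stratum_network(ct, stratum(8L, "CL",
                                                 sample_ids(ct)[1:3])),
               "at least 4")
})
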