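test_that("pearson matches a brute-force computation and the t-distribution p", {
  set.seed(4)
  x <- stats::rnorm(30); y <- 0.5 * x + stats::rnorm(30)
  res <- pearson(x, y)
  # brute-force oracle: covariance over the product of standard deviations
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
})

test_that("perfect and orthogonal relationships hit the boundary values", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, 2 * x + 1)$p, 0)
  # construct y orthogonal to centered x
  xc <- scale(stats::rnorm(12), scale = FALSE)[, 1]
  y0 <- stats::rnorm(12)
  y <- y0 - sum(y0 * xc) / sum(xc^2) * xc
  expect_equal(pearson(xc, y)$r, 0, tolerance = 1e-12)
  expect_error(pearson(rep(1, 10), stats::rnorm(10)), "variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("partial correlation matches the textbook one-covariate formula", {
  set.seed(10)
  for (rep in 1:5) {
    x <- stats::rnorm(25); z <- stats::rnorm(25)
    y <- 0.4 * x + 0.6 * z + stats::rnorm(25)
    res <- partial_pearson(x, y, cbind(z))
    rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
    oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(res$r, oracle, tolerance = 1e-10)
    expect_equal(res$df, 25 - 3)
  }
  # no covariates: identical to plain pearson
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  expect_equal(partial_pearson(x, y, NULL)[c("r", "p")],
               pearson(x, y)[c("r", "p")])
})

test_that("trivariate Gaussians reproduce the closed-form partial correlation", {
  # population check: with known covariance, the sample partial correlation
  # converges to the closed-form population value
  S <- matrix(c(1, 0.6, 0.5,
                0.6, 1, 0.7,
                0.5, 0.7, 1), 3, 3)
  L <- chol(S)
  set.seed(17)
  Z <- matrix(stats::rnorm(3 * 20000), ncol = 3) %*% L
  pop <- (0.6 - 0.5 * 0.7) / sqrt((1 - 0.25) * (1 - 0.49))
  res <- partial_pearson(Z[, 1], Z[, 2], Z[, 3, drop = FALSE])
  expect_lt(abs(res$r - pop), 0.02)
})

test_that("degenerate residuals after adjustment raise an error", {
  z <- stats::rnorm(20)
  x <- stats::rnorm(20)
  expect_error(partial_pearson(x, z, cbind(z)), "zero residual variance")
  expect_error(partial_pearson(stats::rnorm(4), stats::rnorm(4),
                               cbind(stats::rnorm(4), stats::rnorm(4))),
               "at least")
})

test_that("paired region comparisons handle identical, degenerate and planted offsets", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(paired_region_test(a, a)$p, 1)
  expect_equal(paired_region_test(a, a)$mean_difference, 0)
  deg <- paired_region_test(a + 2, a)
  expect_true(deg$degenerate)
  expect_equal(deg$mean_difference, 2)
  expect_equal(deg$p, 0)
  # agreement with the reference implementation on regular data
  set.seed(3)
  b <- a + stats::rnorm(4, 0.5, 0.3)
  expect_equal(paired_region_test(b, a)$p, stats::t.test(b, a, paired = TRUE)$p.value)
  expect_error(paired_region_test(1:2, 2:3), "at least 3")
})

test_that("a planted acetabulum-femur offset is detected in nearly all replicates", {
  set.seed(19)
  hits <- replicate(200, {
    femur <- stats::rnorm(10, 0.007, 0.002)
    acet <- femur + 0.008 + stats::rnorm(10, 0, 0.003)
    res <- paired_region_test(acet, femur)
    res$mean_difference > 0 && res$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the association screen batches pairs and flags unknown variables", {
  set.seed(21)
  rec <- data.frame(a = stats::rnorm(40))
  rec$b <- 0.9 * rec$a + stats::rnorm(40, sd = 0.3)
  rec$c <- stats::rnorm(40)
  rec$z <- stats::rnorm(40)
  single <- association_screen(rec, data.frame(x = "a", y = "b"))
  expect_equal(single$r, pearson(rec$a, rec$b)$r)
  expect_equal(single$p, pearson(rec$a, rec$b)$p)
  out <- association_screen(rec, data.frame(x = c("a", "a"), y = c("b", "c")),
                            covariate_map = list("a|c" = "z"))
  expect_equal(nrow(out), 2)
  expect_gt(abs(out$r[1]), abs(out$r[2]))   # planted pair ranks first
  expect_equal(out$covariates, c("", "z"))
  adj <- association_screen(rec, data.frame(x = c("a", "a"), y = c("b", "c")),
                            p_adjust = "BH")
  expect_true(all(adj$p_adj >= adj$p - 1e-15))
  expect_error(association_screen(rec, data.frame(x = "a", y = "missing_var")),
               "missing_var")
})

test_that("r stays in [-1, 1] and p in [0, 1] across random inputs", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n); z <- stats::rnorm(n)
    res <- partial_pearson(x, y, cbind(z))
    expect_true(res$r >= -1 && res$r <= 1)
    expect_true(res$p >= 0 && res$p <= 1)
  }
})
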