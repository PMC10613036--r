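test_that("descriptive statistics use sample SD and CV = SD/mean", {
  set.seed(1)
  z <- rnorm(50)
  x <- 9.22 + 0.70 * (z - mean(z)) / sd(z)
  d <- describe(data.frame(seed_length = x))
  expect_equal(d$mean, 9.22, tolerance = 1e-9)
  expect_equal(d$sd, 0.70, tolerance = 1e-9)
  expect_equal(d$cv, 0.70 / 9.22, tolerance = 1e-9)
  expect_equal(round(d$cv, 2), 0.08)

  const <- describe(data.frame(a = rep(2, 5)))
  expect_identical(const$sd, 0)
  expect_identical(const$cv, 0)

  # two-pass oracle on random data
  set.seed(3)
  y <- runif(10) * 40
  d2 <- describe(data.frame(y = y))
  expect_equal(d2$sd, sqrt(sum((y - sum(y) / 10)^2) / 9), tolerance = 1e-12)
  expect_equal(d2$cv, d2$sd / d2$mean, tolerance = 1e-12)
  expect_identical(c(d2$min, d2$max), range(y))
  expect_error(describe(data.frame(a = 1)), "at least 2")
})

test_that("Pearson matrix matches the covariance-formula oracle", {
  t5 <- data.frame(x = c(1, 2, 4, 7, 11), y = c(2.2, 2.8, 4.5, 6.1, 9.7),
                   z = c(5, 3, 4, 1, 2))
  pm <- pearson_matrix(t5)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- t5[[i]]; b <- t5[[j]]
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pm$r[i, j], r_oracle, tolerance = 1e-12)
  }
  expect_identical(pm$r, t(pm$r))
  expect_true(all(diag(pm$r) == 1))

  lin <- data.frame(x = 1:10, y = 2 * (1:10) + 1, w = rnorm(10))
  expect_equal(pearson_matrix(lin)$r["x", "y"], 1, tolerance = 1e-12)

  set.seed(8)
  ind <- data.frame(x = rnorm(400), y = rnorm(400))
  pmi <- pearson_matrix(ind)
  expect_lt(abs(pmi$r["x", "y"]), 0.1)
  expect_gt(pmi$p["x", "y"], 0.05)
})

test_that("z-scoring standardises, is idempotent, and rejects degenerate input", {
  set.seed(4)
  t0 <- data.frame(a = rnorm(20, 5, 2), b = runif(20, 0, 100))
  z1 <- zscore(t0)
  for (nm in names(z1)) {
    expect_lt(abs(mean(z1[[nm]])), 1e-12)
    expect_equal(sd(z1[[nm]]), 1, tolerance = 1e-12)
  }
  z2 <- zscore(z1)
  expect_equal(as.matrix(z2), as.matrix(z1), tolerance = 1e-12)
  expect_equal(zscore(data.frame(v = c(1, 2, 3)))$v, c(-1, 0, 1))
  expect_error(zscore(data.frame(a = 1)), "at least 2")
  expect_error(zscore(data.frame(a = rep(1, 5))), "constant column")
})

test_that("Ward clustering minimises the SSE increase like the brute-force oracle", {
  # two tight groups in 2D are recovered exactly
  g <- rbind(matrix(rnorm(6, 0, 0.05), 3, 2),
             matrix(rnorm(6, 5, 0.05), 3, 2))
  res <- ward_cluster(as.data.frame(g), k = 2)
  expect_true(all(res$labels[1:3] == res$labels[1]) &&
                all(res$labels[4:6] == res$labels[4]) &&
                res$labels[1] != res$labels[4])

  resn <- ward_cluster(as.data.frame(g), k = 6)
  expect_identical(sort(unique(resn$labels)), 1:6)
  expect_equal(resn$sse, 0)

  set.seed(10)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    res <- ward_cluster(as.data.frame(x), k = 1)
    expect_equal(res$delta_sse, ward_oracle(x), tolerance = 1e-8)
  }
})

test_that("group comparison applies LSD or Bonferroni with letter displays", {
  base <- c(-1.2, -0.5, 0.1, 0.6, 1.0)
  same <- data.frame(y = rep(base, 3))
  g3 <- rep(c("a", "b", "c"), each = 5)
  r0 <- group_compare(same, g3)$y
  expect_lt(r0$F, 1e-9)
  expect_identical(unname(r0$letters), rep("a", 3))

  far <- data.frame(y = c(base, base + 10 * sd(base)))
  r1 <- group_compare(far, rep(c("lo", "hi"), each = 5))$y
  expect_false(r1$letters[["lo"]] == r1$letters[["hi"]])

  # contrived 3 x 5 table against textbook formulas
  y <- c(12.1, 13.4, 12.8, 13.0, 12.5,
         15.2, 14.8, 15.9, 15.1, 14.6,
         15.5, 15.0, 16.1, 15.3, 14.9)
  g <- factor(rep(c("g1", "g2", "g3"), each = 5))
  r <- group_compare(data.frame(y = y), g)$y
  gm <- tapply(y, g, mean)
  sst <- 5 * sum((gm - mean(y))^2)
  sse <- sum((y - gm[g])^2)
  F_oracle <- (sst / 2) / (sse / 12)
  expect_equal(r$F, F_oracle, tolerance = 1e-10)
  mse <- sse / 12
  t12 <- abs(gm[1] - gm[2]) / sqrt(mse * (2 / 5))
  p12 <- 2 * pt(-t12, 12)
  if (r$method == "LSD")
    expect_equal(r$pairwise["g1", "g2"], unname(p12), tolerance = 1e-10)
  # letters respect the significance pattern
  sig <- r$pairwise < 0.05
  for (i in 1:2) for (j in (i + 1):3) {
    share <- any(strsplit(r$letters[[i]], "")[[1]] %in%
                   strsplit(r$letters[[j]], "")[[1]])
    expect_identical(share, !sig[i, j])
  }
  expect_error(group_compare(data.frame(y = 1:3), c("a", "a", "b")),
               "at least 2 rows")
})

test_that("Bonferroni never declares more significant pairs than LSD", {
  set.seed(21)
  y <- c(rexp(8, 1), rexp(8, 0.7), rexp(8, 0.4), rexp(8, 0.3))
  g <- rep(paste0("p", 1:4), each = 8)
  r <- group_compare(data.frame(y = y), g)$y
  # recompute both adjustments directly from the pooled comparison
  fit <- aov(y ~ factor(g))
  mse <- summary(fit)[[1]]$`Mean Sq`[2]
  dfe <- summary(fit)[[1]]$Df[2]
  gm <- tapply(y, g, mean)
  p_raw <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    tv <- abs(gm[i] - gm[j]) / sqrt(mse * (2 / 8))
    p_raw <- c(p_raw, 2 * pt(-tv, dfe))
  }
  expect_lte(sum(pmin(1, p_raw * 6) < 0.05), sum(p_raw < 0.05))
  if (r$method == "Bonferroni") {
    expect_equal(sum(r$pairwise < 0.05, na.rm = TRUE) / 2,
                 sum(pmin(1, p_raw * 6) < 0.05))
  }
})

test_that("trend fits report slope, R2 and percent change", {
  r <- trend_fit(1:4, c(2, 4, 6, 8))
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  expect_equal(r$pct_change, 300)
  rc <- trend_fit(1:4, rep(3, 4))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  # 4-point hand data against the normal equations
  x <- c(1, 2, 3, 4); y <- c(2.3, 2.9, 4.1, 4.4)
  r2 <- trend_fit(x, y)
  b_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(r2$slope, b_oracle, tolerance = 1e-12)
  expect_equal(r2$intercept, mean(y) - b_oracle * mean(x), tolerance = 1e-12)
  expect_error(trend_fit(1:2, 1:2), "at least 3")
})

test_that("agreement is the coefficient of determination", {
  expect_equal(agreement(1:10, 1:10), 1)
  set.seed(33)
  expect_lt(agreement(rnorm(200), rnorm(200)), 0.05)
  expect_error(agreement(1:3, 1:4), "length mismatch")
})

test_that("pipeline dimensions agree with generator dimensions across a population", {
  res <- acceptance_population()
  gt <- res$ground_truth
  tr <- res$traits
  gt <- gt[gt$seed_id %in% tr$seed_id, ]
  for (nm in c("seed_length_mm", "seed_width_mm", "seed_thickness_mm"))
    expect_gte(agreement(gt[[nm]], tr[[nm]]), 0.95)
})
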