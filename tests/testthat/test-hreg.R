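# brute-force nested least squares via explicit normal equations
oracle_steps <- function(y, blocks_X) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  prev_r2 <- 0; prev_p <- 0
  out <- NULL
  Xcum <- matrix(1, n, 1)
  for (b in seq_along(blocks_X)) {
    Xcum <- cbind(Xcum, blocks_X[[b]])
    beta <- solve(t(Xcum) %*% Xcum, t(Xcum) %*% y)
    rss <- sum((y - Xcum %*% beta)^2)
    r2 <- 1 - rss / tss
    p_cum <- ncol(Xcum) - 1
    q <- p_cum - prev_p
    df2 <- n - p_cum - 1
    dr2 <- r2 - prev_r2
    f <- (dr2 / q) / ((1 - r2) / df2)
    out <- rbind(out, c(r2 = r2, delta_r2 = dr2, delta_f = f,
                        df1 = q, df2 = df2,
                        p = pf(f, q, df2, lower.tail = FALSE)))
    prev_r2 <- r2; prev_p <- p_cum
  }
  out
}

test_that("hierarchical fits match the normal-equations oracle to 1e-10", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(15:30, 1)
    nb <- sample(1:3, 1)
    sizes <- sample(1:2, nb, replace = TRUE)
    Xs <- lapply(sizes, function(k) matrix(rnorm(n * k), n, k))
    y <- rnorm(n) + rowSums(do.call(cbind, Xs)) * 0.4
    d <- data.frame(y = y, do.call(cbind, Xs))
    vars <- names(d)[-1]
    blocks <- split(vars, rep(seq_len(nb), sizes))
    f <- as.formula(paste("y ~", paste(vars, collapse = " + ")))
    fit <- hreg(f, d, blocks = unname(blocks))
    oracle <- oracle_steps(y, Xs)
    expect_equal(fit$steps$r2, unname(oracle[, "r2"]), tolerance = 1e-10)
    expect_equal(fit$steps$delta_r2, unname(oracle[, "delta_r2"]),
                 tolerance = 1e-10)
    expect_equal(fit$steps$delta_f, unname(oracle[, "delta_f"]),
                 tolerance = 1e-8)
    expect_equal(fit$steps$p, unname(oracle[, "p"]), tolerance = 1e-10)
    expect_equal(fit$steps$df2, unname(oracle[, "df2"]))
  }
})

test_that("degrees of freedom follow the n - p - 1 bookkeeping", {
  set.seed(1)
  d73 <- data.frame(y = rnorm(73), PC1 = rnorm(73), PC2 = rnorm(73),
                    grs = rnorm(73))
  f73 <- hreg(y ~ PC1 + PC2 + grs, d73, blocks = list(c("PC1", "PC2"), "grs"))
  expect_equal(f73$steps$df1[2], 1)
  expect_equal(f73$steps$df2[2], 69)
  d62 <- d73[1:62, ]
  f62 <- hreg(y ~ PC1 + PC2 + grs, d62, blocks = list(c("PC1", "PC2"), "grs"))
  expect_equal(f62$steps$df2[2], 58)
  # delta-R2 additivity across steps
  expect_equal(sum(f73$steps$delta_r2), f73$steps$r2[2], tolerance = 1e-12)
})

test_that("a response already explained by step 1 leaves nothing for step 2", {
  set.seed(2)
  d <- data.frame(PC1 = rnorm(40), PC2 = rnorm(40), grs = rnorm(40))
  d$y <- 1 + 2 * d$PC1 - d$PC2
  w <- capture_warnings(
    fit <- hreg(y ~ PC1 + PC2 + grs, d, blocks = list(c("PC1", "PC2"), "grs"))
  )
  expect_true(all(grepl("zero residual", w)))
  expect_equal(fit$steps$delta_r2[2], 0, tolerance = 1e-12)
})

test_that("rank deficiency and missing data are handled explicitly", {
  set.seed(3)
  d <- data.frame(y = rnorm(20), a = rnorm(20))
  d$b <- 2 * d$a
  expect_error(hreg(y ~ a + b, d), "collinear")
  d2 <- data.frame(y = rnorm(30), a = rnorm(30), g = rnorm(30))
  d2$y[1:5] <- NA
  fit <- hreg(y ~ a + g, d2, blocks = list("a", "g"))
  expect_equal(fit$n_used, 25)
})

test_that("hreg methods are coherent with the stored fit", {
  set.seed(4)
  d <- data.frame(y = rnorm(50), a = rnorm(50), g = rnorm(50))
  fit <- hreg(y ~ a + g, d, blocks = list("a", "g"))
  expect_equal(fitted(fit) + residuals(fit), d$y, ignore_attr = TRUE)
  expect_equal(unname(predict(fit, d)), unname(fitted(fit)))
  expect_length(coef(fit), 3)
  expect_equal(nobs(fit), 50)
  expect_output(print(fit), "Hierarchical regression")
  expect_output(print(summary(fit)), "coefficients")
  pl <- NULL
  pdf(NULL)
  pl <- plot(fit)
  dev.off()
  expect_equal(cor(pl$x, residualize(d$g, d$a)), 1, tolerance = 1e-10)
})

test_that("affine changes of predictors move no incremental statistic", {
  set.seed(5)
  d <- data.frame(y = rnorm(60), PC1 = rnorm(60), PC2 = rnorm(60),
                  grs = rnorm(60))
  f1 <- hreg(y ~ PC1 + PC2 + grs, d, blocks = list(c("PC1", "PC2"), "grs"))
  d2 <- transform(d, PC1 = 3 * PC1 - 1, PC2 = PC2 / 10, grs = 100 * grs + 5)
  f2 <- hreg(y ~ PC1 + PC2 + grs, d2, blocks = list(c("PC1", "PC2"), "grs"))
  for (col in c("r2", "delta_r2", "delta_f", "p")) {
    expect_equal(f1$steps[[col]], f2$steps[[col]], tolerance = 1e-9)
  }
})

test_that("F tail probabilities agree with the t-distribution identity", {
  expect_equal(f_tail_p(0, 1, 10), 1)
  f <- c(0.3, 2.2, 5.14, 9.7)
  expect_equal(f_tail_p(f, 1, 58),
               2 * pt(sqrt(f), 58, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(f_tail_p(-1, 1, 10), "non-negative")
  expect_error(f_tail_p(1, 0, 10), "degrees of freedom")
})

test_that("residualize projects out covariates exactly", {
  set.seed(6)
  X <- matrix(rnorm(80), 40, 2)
  y <- rnorm(40)
  r <- residualize(y, X)
  expect_lt(max(abs(crossprod(cbind(1, X), r))), 1e-10)
  # y in the span of X leaves nothing
  y2 <- 2 + X %*% c(1, -3)
  expect_lt(max(abs(residualize(drop(y2), X))), 1e-10)
  # orthogonal X only removes the mean
  Xo <- matrix(rep(c(1, -1), 20), 40)
  yc <- rep(c(2, 2, 4, 4), 10)
  expect_equal(residualize(yc, Xo[, 1, drop = FALSE]), yc - mean(yc),
               ignore_attr = TRUE)
  expect_error(residualize(y, cbind(X, X[, 1])), "rank deficient")
})

test_that("ICV adjustment removes head-size variance and nothing else", {
  set.seed(7)
  icv <- rnorm(500, 1.45e6, 1.2e5)
  vol <- 1000 + 0.001 * icv + rnorm(500, 0, 30)
  adj <- adjust_icv(vol, icv)
  expect_lt(abs(cor(adj, icv)), 1e-10)
  expect_equal(mean(adj), mean(vol))
  # strictly proportional volumes collapse to the mean
  prop <- 0.002 * icv
  expect_equal(adjust_icv(prop, icv), rep(mean(prop), 500), tolerance = 1e-9)
  # ICV-independent volumes are nearly untouched
  vol2 <- rnorm(500, 1200, 100)
  expect_gt(cor(adjust_icv(vol2, icv), vol2), 0.99)
  # ratio mode exists and differs when the relation is not proportional
  expect_false(isTRUE(all.equal(adjust_icv(vol, icv, "ratio"), adj)))
  expect_error(adjust_icv(vol, rep(1.4e6, 500)), "zero variance")
})

test_that("Bonferroni thresholds divide the level by the test count", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})
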