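test_that("weight-table generation is deterministic and respects its contract", {
  w <- gen_weight_table(22, seed = 1)
  expect_equal(nrow(w), 22)
  expect_equal(sum(!w$qc_fail), 14)
  expect_false(any(w$effect_allele == w$other_allele))
  expect_false(anyDuplicated(w$snv_id) > 0)
  expect_identical(w, gen_weight_table(22, seed = 1))
  expect_equal(nrow(gen_weight_table(1, n_qc_fail = 0, seed = 2)), 1)
  expect_error(gen_weight_table(0), "positive count")
})

test_that("genotype dosages live in {0,1,2,NA} and track the panel frequency", {
  w <- gen_weight_table(10, n_qc_fail = 0, seed = 3)
  w$eaf <- 0.3
  g <- gen_genotypes(w, n_individuals = 4000, n_populations = 1,
                     pop_weights = 1, fst = 0, missing_rate = 0.02, seed = 4)
  expect_true(all(g$dosage %in% c(0, 1, 2, NA)))
  expect_equal(sum(is.na(g$dosage[, 1])), round(0.02 * 4000))
  al <- align_effect_alleles(g, w)   # orient to the effect allele
  freq <- colMeans(al$dosage, na.rm = TRUE) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 4000))
  expect_true(all(abs(freq - 0.3) < 3.5 * se))
})

test_that("population divergence separates allele frequencies", {
  w <- gen_weight_table(40, n_qc_fail = 0, seed = 5)
  g <- gen_genotypes(w, n_individuals = 50, n_populations = 2,
                     fst = 0.2, seed = 6)
  pf <- attr(g, "truth")$pop_freq
  expect_gt(mean(abs(pf[1, ] - pf[2, ])), 0.05)
  g0 <- gen_genotypes(w, n_individuals = 50, n_populations = 2,
                      fst = 0, seed = 7)
  expect_equal(max(abs(attr(g0, "truth")$pop_freq[1, ] -
                       attr(g0, "truth")$pop_freq[2, ])), 0)
})

test_that("within-population genotypes are in Hardy-Weinberg proportions", {
  w <- gen_weight_table(6, n_qc_fail = 0, seed = 8)
  g <- gen_genotypes(w, n_individuals = 5000, n_populations = 1,
                     pop_weights = 1, fst = 0, seed = 9)
  al <- align_effect_alleles(g, w)
  pvals <- vapply(seq_len(6), function(j) {
    d <- al$dosage[, j]
    p <- mean(d) / 2
    obs <- tabulate(d + 1, 3)
    expct <- 5000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    suppressWarnings(chisq.test(obs, p = expct / sum(expct))$p.value)
  }, 0)
  expect_true(all(pvals > 0.01))
})

test_that("phenotype calibration hits the target incremental variance at large n", {
  w <- gen_weight_table(22, seed = 10)
  g <- gen_genotypes(w, n_individuals = 50000, fst = 0.1, seed = 11)
  wt <- transform_weights(w, "identity")
  al <- align_effect_alleles(apply_qc(g), wt)
  grs <- compute_grs(al, wt)
  pcs <- ancestry_pcs(al, 2)
  targets <- c(shaps = 0.095, prt = 0, nac_rpe = 0.02, put_rpe = 0.02,
               nac_vol = 0.02, put_vol = 0.02)
  ph <- gen_phenotypes(setNames(grs$score, grs$individual), pcs$scores,
                       targets = targets, seed = 12)
  d <- data.frame(y = ph$shaps, grs = grs$score, pcs$scores)
  fit <- hreg(y ~ PC1 + PC2 + grs, d, blocks = list(c("PC1", "PC2"), "grs"))
  expect_equal(fit$steps$delta_r2[2], 0.095, tolerance = 0.005 / 0.095)
  # null unit: the GRS adds essentially nothing
  d0 <- data.frame(y = ph$prt_stress_change, grs = grs$score, pcs$scores)
  fit0 <- hreg(y ~ PC1 + PC2 + grs, d0, blocks = list(c("PC1", "PC2"), "grs"))
  expect_lt(fit0$steps$delta_r2[2], 0.001)
})

test_that("the generated GRS-phenotype association is negative by default", {
  co <- make_scored_cohort(n = 200, m = 16, seed = 13)
  ph <- gen_phenotypes(setNames(co$grs$score, co$grs$individual),
                       co$pcs$scores, seed = 14)
  ry <- residualize(ph$shaps, co$pcs$scores)
  rg <- residualize(co$grs$score, co$pcs$scores)
  expect_lt(cor(ry, rg), 0)
})

test_that("phenotype generation validates its inputs", {
  expect_error(gen_phenotypes(rnorm(10), matrix(rnorm(22), 11, 2)),
               "not aligned")
  expect_error(
    gen_phenotypes(rnorm(10), matrix(rnorm(20), 10, 2),
                   targets = c(shaps = 0.97, prt = 0, nac_rpe = 0,
                               put_rpe = 0, nac_vol = 0, put_vol = 0)),
    "variance budget")
})

test_that("the PRT reward controller delivers the 3:1 quota when possible", {
  s <- gen_prt_session(subject_bias = list(bias = c(0, 0), discrim = 50),
                       seed = 15)  # accuracy ~ 1: all responses correct
  expect_true(all(s$correct))
  for (b in 1:2) {
    blk <- s[s$block == b, ]
    expect_equal(sum(blk$rewarded[blk$stimulus == "rich"]), 24)
    expect_equal(sum(blk$rewarded[blk$stimulus == "lean"]), 8)
  }
  expect_null(attr(s, "shortfall"))
})

test_that("PRT block structure, null schedules and shortfalls behave", {
  s <- gen_prt_session(n_trials = 160, seed = 16)
  expect_equal(as.integer(table(s$block)), c(80L, 80L))
  expect_true(all(table(s$block, s$stimulus) == 40L))
  s0 <- gen_prt_session(rich_reward_target = 0, lean_reward_target = 0,
                        seed = 17)
  expect_equal(sum(s0$rewarded), 0)
  # hopeless accuracy: every correct response is rewarded, shortfall logged
  s_bad <- gen_prt_session(subject_bias = list(bias = c(0, 0), discrim = -3),
                           seed = 18)
  expect_false(is.null(attr(s_bad, "shortfall")))
  agg <- tapply(s_bad$rewarded, list(s_bad$block, s_bad$stimulus), sum)
  cor_agg <- tapply(s_bad$correct, list(s_bad$block, s_bad$stimulus), sum)
  short <- attr(s_bad, "shortfall")
  for (k in seq_len(nrow(short))) {
    expect_equal(agg[short$block[k], short$stimulus[k]],
                 cor_agg[short$block[k], short$stimulus[k]])
  }
  expect_error(gen_prt_session(rich_reward_target = 41), "reward targets")
  expect_error(gen_prt_session(n_trials = 100), "multiple of 80")
})

test_that("rewarded-correct counts never exceed correct counts", {
  for (seed in 1:5) {
    s <- gen_prt_session(subject_bias = list(bias = c(0.2, 0.5), discrim = 0.8),
                         seed = seed)
    for (b in 1:2) for (st in c("rich", "lean")) {
      blk <- s[s$block == b & s$stimulus == st, ]
      expect_lte(sum(blk$rewarded), sum(blk$correct))
    }
  }
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_individuals = 30, unit_n = NULL, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$prt_trials, b$prt_trials)
  expect_identical(a$rl_choices, b$rl_choices)
})
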