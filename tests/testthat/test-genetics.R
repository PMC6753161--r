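test_that("weight transforms populate the scoring weight correctly", {
  w <- make_weights("rs1", "A", "G", beta = 0.5)
  expect_equal(transform_weights(w, "identity")$weight, 0.5)
  w$beta <- 1.2
  expect_equal(transform_weights(w, "log")$weight, log(1.2), tolerance = 1e-12)
  w$beta <- -0.1
  expect_error(transform_weights(w, "log"), "rs1")
})

test_that("QC applies the strict missingness and INFO rules", {
  n <- 100
  dos <- matrix(1, n, 4, dimnames = list(NULL, paste0("s", 1:4)))
  dos[sample(n, 6), 1] <- NA          # 6% missing -> removed
  dos[sample(n, 5), 2] <- NA          # exactly 5% -> retained
  g <- make_geno(dos, info = c(0.95, 0.95, 0.79, 0.81))
  dos[, 4] <- rbinom(n, 2, 0.4)       # keep SNV 4 polymorphic & complete
  g <- make_geno(dos, info = c(0.95, 0.95, 0.79, 0.81))
  qc <- apply_qc(g)
  kept <- qc$snv$snv_id
  expect_false("s1" %in% kept)   # missingness 0.06 > 0.05
  expect_true("s2" %in% kept)    # missingness exactly 0.05 retained
  expect_false("s3" %in% kept)   # INFO 0.79 <= 0.8
  expect_true("s4" %in% kept)    # INFO 0.81 > 0.8
  log <- attr(qc, "qc_log")
  expect_setequal(log$snv_removed$snv_id, c("s1", "s3"))
})

test_that("individual-level QC runs after SNV-level QC and drops high-missing rows", {
  dos <- matrix(1, 10, 3, dimnames = list(NULL, paste0("s", 1:3)))
  dos[1, 2] <- NA   # individual 1 misses 1/3 of the surviving SNVs
  g <- make_geno(dos)
  qc <- apply_qc(g, snv_missing_max = 0.5)
  expect_equal(nrow(qc$dosage), 9)
  expect_equal(attr(qc, "qc_log")$individuals_removed, "I001")
})

test_that("QC is idempotent and retains 14 of 22 default synthetic SNVs", {
  w <- gen_weight_table(22, seed = 5)
  g <- gen_genotypes(w, n_individuals = 83, seed = 6)
  once <- apply_qc(g)
  twice <- apply_qc(once)
  expect_equal(ncol(once$dosage), 14)
  expect_identical(once$dosage, twice$dosage)
  expect_identical(once$snv, twice$snv)
})

test_that("allele alignment re-orients dosages and catches mismatches", {
  dos <- cbind(s1 = c(0, 1, 2), s2 = c(2, 1, 0))
  g <- make_geno(dos, counted = c("A", "G"), other = c("G", "A"))
  w <- make_weights(c("s1", "s2"), effect = c("A", "A"), other = c("G", "G"),
                    beta = c(0.1, 0.2))
  al <- align_effect_alleles(g, w)
  expect_equal(unname(al$dosage[, "s1"]), c(0, 1, 2))   # already oriented
  expect_equal(unname(al$dosage[, "s2"]), c(0, 1, 2))   # complemented
  expect_equal(unique(al$snv$counted_allele), "A")
  w_bad <- make_weights(c("s1", "s2"), effect = c("A", "C"),
                        other = c("G", "T"), beta = c(0.1, 0.2))
  expect_error(align_effect_alleles(g, w_bad), "s2")
})

test_that("GRS arithmetic matches hand-computed values", {
  g1 <- make_geno(cbind(s1 = c(2, 0)))
  w1 <- make_weights("s1", "A", "G", beta = 0.5)
  res <- compute_grs(g1, w1)
  expect_equal(res$score, c(1.0, 0))
  # mean imputation: observed dosages (1, 0) -> eaf_hat 0.25,
  # missing contributes 2 * 0.25 * 0.4 = 0.2
  g2 <- make_geno(cbind(s1 = c(NA, 1, 0)))
  w2 <- make_weights("s1", "A", "G", beta = 0.4)
  res2 <- compute_grs(g2, w2, missing_policy = "mean_impute")
  expect_equal(res2$score[1], 0.2)
  expect_equal(res2$n_imputed_missing, c(1L, 0L, 0L))
  res2s <- compute_grs(g2, w2, missing_policy = "skip")
  expect_equal(res2s$score[1], 0)
  expect_equal(res2s$n_snvs_used, c(0L, 1L, 1L))
})

test_that("mean-impute and skip policies agree exactly on complete data", {
  co <- make_scored_cohort(n = 40, m = 8, seed = 21)
  a <- compute_grs(co$geno, co$weights, "mean_impute")
  b <- compute_grs(co$geno, co$weights, "skip")
  expect_equal(a$score, b$score, tolerance = 1e-12)
})

test_that("allele recoding shifts the raw score by 2w and leaves association stats unchanged", {
  co <- make_scored_cohort(n = 70, m = 10, seed = 31)
  set.seed(1)
  y <- rnorm(70)
  d1 <- data.frame(y = y, grs = co$grs$score, co$pcs$scores)
  j <- co$geno$snv$snv_id[3]
  flipped_dos <- co$geno$dosage
  flipped_dos[, j] <- 2 - flipped_dos[, j]
  snv2 <- co$geno$snv
  tmp <- snv2$counted_allele[3]
  snv2$counted_allele[3] <- snv2$other_allele[3]
  snv2$other_allele[3] <- tmp
  flipped <- geno_matrix(flipped_dos, snv2)
  # route 1: re-alignment undoes the recode exactly
  al <- align_effect_alleles(flipped, co$weights)
  grs2 <- compute_grs(al, co$weights)
  expect_equal(grs2$score, co$grs$score, tolerance = 1e-12)
  # route 2: recoding the weight record too (effect/other swapped, beta
  # negated) shifts every score by exactly -2 * w_j and nothing else
  w_recode <- co$weights
  w_recode$effect_allele[w_recode$snv_id == j] <- snv2$counted_allele[3]
  w_recode$other_allele[w_recode$snv_id == j] <- snv2$other_allele[3]
  wj <- co$weights$weight[co$weights$snv_id == j]
  w_recode$beta[w_recode$snv_id == j] <- -wj
  w_recode$weight[w_recode$snv_id == j] <- -wj
  grs3 <- compute_grs(flipped, w_recode)
  expect_equal(grs3$score, co$grs$score - 2 * wj, tolerance = 1e-12)
  d2 <- d1
  d2$grs <- grs3$score
  f1 <- hreg(y ~ PC1 + PC2 + grs, d1, blocks = list(c("PC1", "PC2"), "grs"))
  f2 <- hreg(y ~ PC1 + PC2 + grs, d2, blocks = list(c("PC1", "PC2"), "grs"))
  expect_equal(f1$steps$delta_r2, f2$steps$delta_r2, tolerance = 1e-10)
  expect_equal(f1$steps$delta_f, f2$steps$delta_f, tolerance = 1e-8)
  expect_equal(f1$steps$p, f2$steps$p, tolerance = 1e-10)
})

test_that("ancestry PCs recover population structure and are orthogonal", {
  w <- gen_weight_table(250, n_qc_fail = 0, seed = 41)
  g <- gen_genotypes(w, n_individuals = 150, n_populations = 2,
                     pop_weights = c(0.5, 0.5), fst = 0.2, seed = 42)
  pcs <- ancestry_pcs(g, 2)
  pop <- attr(g, "truth")$population
  expect_gt(abs(cor(pcs$scores[, 1], pop)), 0.9)
  expect_lt(abs(sum(pcs$scores[, 1] * pcs$scores[, 2])), 1e-6)
  expect_equal(apply(pcs$scores, 2, sd), c(PC1 = 1, PC2 = 1), tolerance = 1e-12)
})

test_that("a single-population cohort shows no PC-label structure", {
  w <- gen_weight_table(200, n_qc_fail = 0, seed = 51)
  g <- gen_genotypes(w, n_individuals = 150, n_populations = 1,
                     pop_weights = 1, fst = 0, seed = 52)
  fake_label <- rep(1:2, length.out = 150)
  pcs <- ancestry_pcs(g, 2)
  expect_lt(abs(cor(pcs$scores[, 1], fake_label)), 0.25)
})

test_that("PC computation rejects under-determined inputs", {
  dos <- cbind(s1 = c(0, 0, 0, 0), s2 = c(1, 0, 2, 1))
  g <- make_geno(dos)
  expect_error(ancestry_pcs(g, 2), "polymorphic")
  expect_silent(ancestry_pcs(g, 1))
})
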