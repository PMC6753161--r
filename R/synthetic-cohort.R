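#' Generate a GWAS summary-weight table
#'
#' Draws a panel of independent SNVs with risk (effect) and other alleles,
#' small linear-scale effect sizes, and effect-allele frequencies.  A
#' configurable subset is designated to fail downstream imputation QC (their
#' genotypes are later generated with sub-threshold INFO scores), emulating
#' a score panel in which only part of the published SNV list survives
#' quality control — by default 8 of 22 fail so that 14 survive.
#'
#' @param n_snvs number of SNVs in the published panel (default 22).
#' @param n_qc_fail how many of them are flagged to fail QC downstream
#'   (default 8).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param seed optional integer seed.
#' @return data frame with columns `snv_id`, `effect_allele`, `other_allele`,
#'   `beta`, `eaf`, `qc_fail`.
#' @examples
#' gen_weight_table(22, seed = 1)
#' @export
gen_weight_table <- function(n_snvs = 22, n_qc_fail = 8,
                             maf_range = c(0.05, 0.5), seed = NULL) {
  if (!is.numeric(n_snvs) || length(n_snvs) != 1L || n_snvs < 1) {
    stop("'n_snvs' must be a positive count")
  }
  stopifnot(n_qc_fail >= 0, n_qc_fail <= n_snvs,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(seed)) set.seed(seed)
  n_snvs <- as.integer(n_snvs)
  alleles <- t(vapply(seq_len(n_snvs),
                      function(i) sample(c("A", "C", "G", "T"), 2L),
                      character(2)))
  maf <- stats::runif(n_snvs, maf_range[1], maf_range[2])
  # the effect allele is the minor or the major allele with equal chance
  eaf <- ifelse(stats::runif(n_snvs) < 0.5, maf, 1 - maf)
  beta <- abs(stats::rnorm(n_snvs, mean = 0.02, sd = 0.008)) + 0.002
  fail <- rep(FALSE, n_snvs)
  if (n_qc_fail > 0) fail[sample.int(n_snvs, n_qc_fail)] <- TRUE
  data.frame(
    snv_id = sprintf("rs%07d", sample.int(9999999L, n_snvs)),
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    beta = beta,
    eaf = eaf,
    qc_fail = fail,
    stringsAsFactors = FALSE
  )
}

#' Generate genotype dosages with population structure
#'
#' Individuals are assigned to `n_populations` ancestry components; each
#' population's allele frequency at each SNV is a Balding–Nichols
#' perturbation of the panel frequency (`Beta(p(1-F)/F, (1-p)(1-F)/F)` with
#' `F = fst`), and genotypes are drawn as `Binomial(2, p_pop)` so
#' Hardy–Weinberg holds within population.  The counted allele of each SNV
#' is chosen at random between the effect and the other allele, so that
#' [align_effect_alleles()] has real work to do.  SNVs flagged `qc_fail` in
#' the weight table receive sub-threshold INFO scores.  Missing entries are
#' injected at a fixed per-SNV count of `round(missing_rate * n)` so the
#' marker-level QC rule binds predictably.
#'
#' @param weights weight table from [gen_weight_table()].
#' @param n_individuals cohort size (default 83).
#' @param n_populations number of ancestry components (default 2).
#' @param pop_weights population mixing proportions (default `c(0.7, 0.3)`),
#'   recycled/renormalized to `n_populations`.
#' @param fst Balding–Nichols divergence in \[0, 1) (default 0.1).
#' @param missing_rate per-SNV missing proportion (default 0; see Details).
#' @param seed optional integer seed.
#' @return a [geno_matrix()] whose `"truth"` attribute records the population
#'   labels and per-population allele frequencies (generator bookkeeping,
#'   never consumed by analysis stages).
#' @export
gen_genotypes <- function(weights, n_individuals = 83, n_populations = 2,
                          pop_weights = c(0.7, 0.3), fst = 0.1,
                          missing_rate = 0, seed = NULL) {
  if (!is.data.frame(weights) || nrow(weights) == 0L) {
    stop("'weights' must be a non-empty weight table")
  }
  stopifnot(n_individuals >= 2, n_populations >= 1,
            fst >= 0, fst < 1, missing_rate >= 0, missing_rate < 1)
  if (any(weights$eaf <= 0 | weights$eaf >= 1)) {
    stop("effect-allele frequencies must lie strictly in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(weights)
  n <- as.integer(n_individuals)
  pw <- rep_len(pop_weights, n_populations)
  pw <- pw / sum(pw)
  pop <- sample(rep(seq_len(n_populations),
                    times = diff(round(c(0, cumsum(pw * n))))))
  # population-specific frequencies (Balding-Nichols)
  pmat <- matrix(0, n_populations, m)
  for (k in seq_len(n_populations)) {
    pmat[k, ] <- if (fst == 0) weights$eaf else
      stats::rbeta(m, weights$eaf * (1 - fst) / fst,
                   (1 - weights$eaf) * (1 - fst) / fst)
  }
  pmat[] <- pmin(pmax(pmat, 1e-4), 1 - 1e-4)
  dos_eff <- matrix(stats::rbinom(n * m, 2L, pmat[pop, ]), n, m)
  counted_is_effect <- stats::runif(m) < 0.5
  dos <- dos_eff
  dos[, !counted_is_effect] <- 2 - dos[, !counted_is_effect]
  info <- ifelse(weights$qc_fail,
                 stats::runif(m, 0.30, 0.80),
                 stats::runif(m, 0.85, 0.999))
  n_miss <- round(missing_rate * n)
  if (n_miss > 0) {
    for (j in seq_len(m)) dos[sample.int(n, n_miss), j] <- NA
  }
  rownames(dos) <- sprintf("I%03d", seq_len(n))
  snv <- data.frame(
    snv_id = weights$snv_id,
    counted_allele = ifelse(counted_is_effect, weights$effect_allele,
                            weights$other_allele),
    other_allele = ifelse(counted_is_effect, weights$other_allele,
                          weights$effect_allele),
    info = info,
    stringsAsFactors = FALSE
  )
  out <- geno_matrix(dos, snv)
  attr(out, "truth") <- list(population = pop, pop_freq = pmat,
                             counted_is_effect = counted_is_effect)
  out
}

#' Generate phenotypes with a calibrated incremental GRS signal
#'
#' For each phenotype unit `u` with target incremental variance `r2_u`, the
#' standardized outcome is built as
#' `effect_sign * sqrt(r2_u) * z + sum_k sqrt(pc_r2_k) * PC_k + noise`, where
#' `z` is the unit-variance residual of the GRS on the (orthonormalized) PCs
#' and the Gaussian noise variance completes the budget to 1.  Because `z`
#' is exactly orthogonal to the PCs, the population variance explained by
#' the GRS *beyond* the PCs equals `r2_u` — the quantity a two-step
#' hierarchical regression estimates as its change in R-squared.  Volumetric
#' units are mapped to mm^3 with an intracranial-volume (ICV) component mixed
#' in, so the ICV adjustment stage has real work to do.
#'
#' @param grs numeric GRS vector (one value per individual).
#' @param pcs numeric matrix of ancestry components, one row per individual.
#' @param targets named vector of incremental R-squared targets in \[0, 1).
#'   Recognised unit names: `shaps`, `prt`, `nac_rpe`, `put_rpe`, `nac_vol`,
#'   `put_vol`; defaults are the package's reference study conditions.
#' @param effect_sign -1 (default; higher genetic risk, worse phenotype) or
#'   +1.
#' @param pc_r2 per-PC variance fractions of each phenotype (default 0.02
#'   each).
#' @param unit_n optional named vector of observed sample sizes per unit;
#'   remaining individuals get `NA` in that column (listwise-deletion
#'   realism).  `NULL` (default) leaves everything observed.
#' @param seed optional integer seed.
#' @return data frame with columns `individual`, `shaps`,
#'   `prt_stress_change`, `nac_rpe_change`, `put_rpe_change`, `nac_volume`,
#'   `put_volume`, `icv`; the `"truth"` attribute stores the generating
#'   residual `z`, coefficients and targets.
#' @export
gen_phenotypes <- function(grs, pcs,
                           targets = c(shaps = 0.017, prt = 0.035,
                                       nac_rpe = 0.065, put_rpe = 0.074,
                                       nac_vol = 0.064, put_vol = 0.095),
                           effect_sign = -1,
                           pc_r2 = c(0.02, 0.02),
                           unit_n = NULL, seed = NULL) {
  pcs <- as.matrix(pcs)
  n <- length(grs)
  if (nrow(pcs) != n) stop("'grs' and 'pcs' are not aligned on individuals")
  needed <- c("shaps", "prt", "nac_rpe", "put_rpe", "nac_vol", "put_vol")
  if (!all(needed %in% names(targets))) {
    stop("'targets' must name all units: ", paste(needed, collapse = ", "))
  }
  stopifnot(effect_sign %in% c(-1, 1), length(pc_r2) == ncol(pcs),
            all(pc_r2 >= 0), all(targets >= 0), all(targets < 1))
  if (any(targets + sum(pc_r2) >= 1)) {
    stop("infeasible variance budget: target R2 plus PC-explained variance must be < 1")
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- if (!is.null(rownames(pcs))) rownames(pcs) else
    if (!is.null(names(grs))) names(grs) else sprintf("I%03d", seq_len(n))
  # orthonormal PC basis, unit variance columns
  Q <- qr.Q(qr(cbind(1, pcs)))[, -1, drop = FALSE]
  Q <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
  z <- stats::lm.fit(cbind(1, Q), grs)$residuals
  if (stats::sd(z) < 1e-12) stop("GRS is collinear with the PCs; no residual signal")
  z <- z / stats::sd(z)
  pcpart <- drop(Q %*% sqrt(pc_r2))
  gen_unit <- function(r2) {
    noise_sd <- sqrt(1 - r2 - sum(pc_r2))
    effect_sign * sqrt(r2) * z + pcpart + stats::rnorm(n, 0, noise_sd)
  }
  u <- lapply(targets, gen_unit)
  icv <- stats::rnorm(n, 1.45e6, 1.2e5)
  icv_c <- icv - mean(icv)
  out <- data.frame(
    individual = ids,
    shaps = 22 + 6 * u$shaps,
    prt_stress_change = -0.05 + 0.2 * u$prt,
    nac_rpe_change = -0.3 + 1.0 * u$nac_rpe,
    put_rpe_change = -0.3 + 1.0 * u$put_rpe,
    nac_volume = 1400 + 150 * u$nac_vol + (150 / 1.2e5) * icv_c,
    put_volume = 10200 + 800 * u$put_vol + (900 / 1.2e5) * icv_c,
    icv = icv,
    stringsAsFactors = FALSE
  )
  col_of <- c(shaps = "shaps", prt = "prt_stress_change",
              nac_rpe = "nac_rpe_change", put_rpe = "put_rpe_change",
              nac_vol = "nac_volume", put_vol = "put_volume")
  if (!is.null(unit_n)) {
    for (nm in names(unit_n)) {
      if (!nm %in% names(col_of)) stop("unknown unit name in 'unit_n': ", nm)
      k <- n - unit_n[[nm]]
      if (k < 0) stop("unit_n for '", nm, "' exceeds the cohort size")
      if (k > 0) out[sample.int(n, k), col_of[[nm]]] <- NA
    }
  }
  attr(out, "truth") <- list(z = z, targets = targets,
                             effect_sign = effect_sign, pc_r2 = pc_r2,
                             std_units = as.data.frame(u))
  out
}

#' Simulate one probabilistic-reward-task session
#'
#' Builds trial records for a PRT session of `n_trials / 80` blocks, each
#' with 40 rich- and 40 lean-stimulus trials in random order.  The subject's
#' response is drawn from a logistic accuracy/bias model:
#' `P(correct | rich) = plogis(discrim + bias)` and
#' `P(correct | lean) = plogis(discrim - bias)`, with per-block `bias` in
#' logit units.  Reward delivery is quota-based, matching the task's fixed
#' per-block reinforcement counts: among the correct responses to each
#' stimulus, exactly `rich_reward_target` (default 24) and
#' `lean_reward_target` (default 8) are rewarded — the asymmetric 3:1
#' schedule — unless too few correct responses occurred, in which case all
#' available are rewarded and the shortfall is logged.
#'
#' @param n_trials total trials, a multiple of 80 (default 160, i.e. two
#'   blocks).
#' @param rich_reward_target,lean_reward_target rewarded-correct quotas per
#'   block; each must not exceed 40, the per-stimulus trial count.
#' @param subject_bias list with `bias` (per-block logit bias, recycled) and
#'   `discrim` (logit accuracy, default 1.1).
#' @param seed optional integer seed.
#' @return data frame with columns `block`, `trial`, `stimulus`, `response`,
#'   `correct`, `rewarded`; the `"shortfall"` attribute records any block in
#'   which a reward quota could not be met.
#' @examples
#' s <- gen_prt_session(seed = 7)
#' table(s$block, s$stimulus)
#' @export
gen_prt_session <- function(n_trials = 160, rich_reward_target = 24,
                            lean_reward_target = 8,
                            subject_bias = list(bias = c(0.15, 0.45), discrim = 1.1),
                            seed = NULL) {
  if (n_trials < 80 || n_trials %% 80 != 0) {
    stop("'n_trials' must be a positive multiple of 80 (80-trial blocks)")
  }
  if (rich_reward_target > 40 || lean_reward_target > 40 ||
      rich_reward_target < 0 || lean_reward_target < 0) {
    stop("reward targets must lie in [0, 40], the per-stimulus trial count per block")
  }
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- n_trials / 80
  bias <- rep_len(subject_bias$bias, n_blocks)
  discrim <- if (is.null(subject_bias$discrim)) 1.1 else subject_bias$discrim
  res <- vector("list", n_blocks)
  shortfall <- NULL
  for (b in seq_len(n_blocks)) {
    stim <- sample(rep(c("rich", "lean"), each = 40))
    p_correct <- ifelse(stim == "rich",
                        stats::plogis(discrim + bias[b]),
                        stats::plogis(discrim - bias[b]))
    correct <- stats::runif(80) < p_correct
    response <- ifelse(correct, stim, ifelse(stim == "rich", "lean", "rich"))
    rewarded <- rep(FALSE, 80)
    for (s in c("rich", "lean")) {
      target <- if (s == "rich") rich_reward_target else lean_reward_target
      idx <- which(stim == s & correct)
      if (length(idx) < target) {
        shortfall <- rbind(shortfall,
                           data.frame(block = b, stimulus = s,
                                      target = target, available = length(idx)))
        rewarded[idx] <- TRUE
      } else if (target > 0) {
        rewarded[sample(idx, target)] <- TRUE
      }
    }
    res[[b]] <- data.frame(block = b, trial = seq_len(80), stimulus = stim,
                           response = response, correct = correct,
                           rewarded = rewarded, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "shortfall") <- shortfall
  out
}
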