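#' Synthetic-cohort configuration
#'
#' Bundles every knob of the synthetic-data generator with the package's
#' reference study conditions as defaults: an 83-woman cohort with
#' two-component ancestry structure (70/30 mixture, Balding–Nichols
#' divergence 0.1), a 22-SNV score panel of which 14 survive imputation QC,
#' per-unit incremental-variance targets with a negative GRS direction, the
#' per-unit observed sample sizes, the PRT reward schedule, and the
#' generative Q-learning parameters.
#'
#' @param n_individuals cohort size (default 83).
#' @param n_snvs SNVs in the published panel (default 22).
#' @param n_qc_fail SNVs designated to fail imputation QC (default 8).
#' @param maf_range minor-allele-frequency range (default 0.05–0.5).
#' @param n_populations ancestry components (default 2).
#' @param pop_weights population mixture proportions (default `c(0.7, 0.3)`).
#' @param fst Balding–Nichols divergence (default 0.1).
#' @param snv_missing_rate per-SNV missing proportion (default 0; with a
#'   14-SNV panel a single missing genotype already exceeds the 2%
#'   per-individual QC rule, so missing-data handling is exercised through
#'   the scoring policies instead).
#' @param per_unit_target_r2 named incremental-R-squared targets (see
#'   [gen_phenotypes()]).
#' @param effect_sign direction of the GRS–phenotype association (default
#'   -1).
#' @param pc_r2 per-PC phenotype variance fractions (default 0.02 each).
#' @param unit_n named observed-N per unit (defaults mirror the reference
#'   per-row Ns; set `NULL` for fully observed phenotypes).
#' @param weight_mode `"identity"` or `"log"` scoring-weight transform.
#' @param prt_discrim PRT logit accuracy parameter.
#' @param rl_params generative [qlearn_params()].
#' @param seed master seed; per-stage seeds are fanned out deterministically
#'   from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 83, n_snvs = 22, n_qc_fail = 8,
                          maf_range = c(0.05, 0.5), n_populations = 2,
                          pop_weights = c(0.7, 0.3), fst = 0.1,
                          snv_missing_rate = 0,
                          per_unit_target_r2 = c(shaps = 0.017, prt = 0.035,
                                                 nac_rpe = 0.065, put_rpe = 0.074,
                                                 nac_vol = 0.064, put_vol = 0.095),
                          effect_sign = -1, pc_r2 = c(0.02, 0.02),
                          unit_n = c(shaps = 82, prt = 59, nac_rpe = 62,
                                     put_rpe = 63, nac_vol = 73, put_vol = 73),
                          weight_mode = "identity", prt_discrim = 1.1,
                          rl_params = qlearn_params(), seed = 20260101) {
  stopifnot(all(per_unit_target_r2 >= 0), all(per_unit_target_r2 < 1),
            all(per_unit_target_r2 + sum(pc_r2) < 1),
            maf_range[1] > 0, maf_range[2] <= 0.5,
            effect_sign %in% c(-1, 1), fst >= 0, fst < 1,
            snv_missing_rate >= 0, snv_missing_rate < 1)
  if (!is.null(unit_n) && any(unit_n > n_individuals)) {
    stop("'unit_n' entries cannot exceed 'n_individuals'")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n_individuals, ", SNVs =", x$n_snvs,
      "(", x$n_snvs - x$n_qc_fail, "pass QC ), seed =", x$seed, "\n")
  cat("  target incremental R2:",
      paste(names(x$per_unit_target_r2),
            format(x$per_unit_target_r2), collapse = ", "), "\n")
  invisible(x)
}

# deterministic per-stage seed fan-out (kept well below 2^31)
stage_seed <- function(seed, stage) {
  (seed + 97L * stage) %% .Machine$integer.max
}

#' Simulate a full synthetic cohort
#'
#' Generates every input the analysis pipeline consumes: the weight table,
#' genotype dosages with population structure, calibrated phenotypes, PRT
#' trial records whose generative block biases reproduce each subject's
#' calibrated stress-change score, and instrumental-task choice sequences.
#' Phenotype calibration uses the same QC'd, allele-aligned GRS and
#' ancestry PCs the analysis stages will compute, so the population
#' incremental variance of the GRS beyond the PCs equals the configured
#' target exactly.
#'
#' @param config a [cohort_config()].
#' @param tasks which trial-level task datasets to generate (default both;
#'   pass `character(0)` for a genetics-and-phenotypes-only cohort, e.g. in
#'   large replication studies).
#' @return list with `weights`, `genotypes` (a [geno_matrix()]),
#'   `phenotypes`, `prt_trials`, `rl_choices`, `grs`, `pcs`, and `truth`
#'   (generator bookkeeping: generating GRS, population labels, PRT bias
#'   parameters, RL parameters; never consumed by analysis stages).
#' @export
simulate_cohort <- function(config = cohort_config(), tasks = c("prt", "rl")) {
  stopifnot(inherits(config, "cohort_config"))
  weights <- gen_weight_table(config$n_snvs, config$n_qc_fail,
                              config$maf_range, seed = stage_seed(config$seed, 1L))
  geno <- gen_genotypes(weights, config$n_individuals, config$n_populations,
                        config$pop_weights, config$fst,
                        config$snv_missing_rate,
                        seed = stage_seed(config$seed, 2L))
  w <- transform_weights(weights, config$weight_mode)
  qcd <- apply_qc(geno)
  aligned <- align_effect_alleles(qcd, w)
  grs <- compute_grs(aligned, w)
  pcs <- ancestry_pcs(aligned, k = length(config$pc_r2))
  phen <- gen_phenotypes(stats::setNames(grs$score, grs$individual),
                         pcs$scores,
                         targets = config$per_unit_target_r2,
                         effect_sign = config$effect_sign,
                         pc_r2 = config$pc_r2,
                         unit_n = config$unit_n,
                         seed = stage_seed(config$seed, 3L))
  # PRT sessions for subjects observed on the behavioral unit; the
  # calibrated stress-change score sets the generative block biases
  set.seed(stage_seed(config$seed, 4L))
  prt_subj <- if ("prt" %in% tasks) {
    phen$individual[!is.na(phen$prt_stress_change)]
  } else character(0)
  ln10 <- log(10)
  prt_bias <- list()
  prt_trials <- vector("list", length(prt_subj))
  for (i in seq_along(prt_subj)) {
    s <- prt_subj[i]
    target <- phen$prt_stress_change[phen$individual == s]
    pre_b <- c(0.05, 0.20) * ln10
    post_b <- c(0.05, 0.20 + target) * ln10
    prt_bias[[s]] <- list(pre = pre_b, post = post_b)
    pre <- gen_prt_session(subject_bias = list(bias = pre_b,
                                               discrim = config$prt_discrim))
    post <- gen_prt_session(subject_bias = list(bias = post_b,
                                                discrim = config$prt_discrim))
    pre$session <- "pre"; post$session <- "post"
    both <- rbind(pre, post)
    both$subject <- s
    prt_trials[[i]] <- both
  }
  prt_trials <- if (length(prt_trials)) do.call(rbind, prt_trials) else NULL
  rl_choices <- if ("rl" %in% tasks) {
    simulate_qlearning(config$rl_params, qlearn_design(),
                       n_subjects = config$n_individuals,
                       seed = stage_seed(config$seed, 5L))
  } else NULL
  truth <- list(
    grs = stats::setNames(grs$score, grs$individual),
    population = attr(geno, "truth")$population,
    phenotype = attr(phen, "truth"),
    prt_bias = prt_bias,
    rl_params = config$rl_params,
    seed = config$seed
  )
  list(weights = weights, genotypes = geno, phenotypes = phen,
       prt_trials = prt_trials, rl_choices = rl_choices,
       grs = grs, pcs = pcs, truth = truth)
}

# --- plain-text IO --------------------------------------------------------

#' Read and write the pipeline's tab-separated files
#'
#' Every artifact the pipeline writes is a plain TSV that its own reader
#' parses back; `write_genotypes()`/`read_genotypes()` split a
#' [geno_matrix()] into a dosage table and a SNV annotation table.
#'
#' @param x data frame (or `geno_matrix`) to write.
#' @param path,dosage_path,snv_path file paths.
#' @return readers return the parsed object; writers return the path(s)
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
write_genotypes <- function(x, dosage_path, snv_path) {
  stopifnot(inherits(x, "geno_matrix"))
  d <- data.frame(individual = rownames(x$dosage), x$dosage,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(d, dosage_path)
  write_tsv(x$snv, snv_path)
  invisible(c(dosage_path, snv_path))
}

#' @rdname pipeline_io
#' @export
read_genotypes <- function(dosage_path, snv_path) {
  d <- read_tsv(dosage_path)
  snv <- read_tsv(snv_path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$individual
  colnames(m) <- snv$snv_id
  geno_matrix(m, snv)
}

#' Minimal dosage VCF output and input
#'
#' Writes a [geno_matrix()] as a minimal VCF (one record per SNV, `DS`
#' FORMAT field carrying the counted-allele dosage, INFO score in the
#' `INFO` column) and reads it back.  The ALT allele is the counted allele.
#' Requires the vcfR package for reading.
#'
#' @param geno a [geno_matrix()].
#' @param path VCF file path (uncompressed).
#' @return `read_dosage_vcf()` returns a `geno_matrix`;
#'   `write_dosage_vcf()` returns `path` invisibly.
#' @export
write_dosage_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  ids <- rownames(geno$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(ncol(geno$dosage))) {
    ds <- geno$dosage[, j]
    ds <- ifelse(is.na(ds), ".", format(ds, trim = TRUE))
    writeLines(paste(c("1", j, geno$snv$snv_id[j], geno$snv$other_allele[j],
                       geno$snv$counted_allele[j], ".", "PASS",
                       paste0("INFO=", format(geno$snv$info[j], digits = 6)),
                       "DS", ds), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_dosage_vcf
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fx <- vcfR::getFIX(v)
  info <- as.numeric(sub("^INFO=", "", vcfR::getINFO(v)))
  snv <- data.frame(snv_id = fx[, "ID"],
                    counted_allele = fx[, "ALT"],
                    other_allele = fx[, "REF"],
                    info = info, stringsAsFactors = FALSE)
  geno_matrix(t(ds), snv)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> QC/score/PCA -> PRT -> RL -> association as one
#' reproducible run: generates the cohort, writes every stage input, reads
#' its own files back (round-trip fidelity is part of the contract), runs
#' the analysis stages, and writes the association table, a
#' variance-explained-by-unit summary, a plain-text report and a manifest
#' of output digests.  Identical config and seed give byte-identical
#' outputs.
#'
#' The behavioral unit is computed end to end: the association table's PRT
#' row uses the response-bias change derived from the simulated trial
#' records, not the generator's calibrated column.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `manifest` (file, md5 digest), `results`
#'   (the [build_results_table()] output), `grs_fit` summaries of each
#'   stage, and `paths`.
#' @export
run_pipeline <- function(config = cohort_config(), outdir) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(outdir)) stop("'outdir' is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  sim <- simulate_cohort(config)

  # stage inputs on disk
  write_tsv(sim$weights, p("weights.tsv"))
  write_genotypes(sim$genotypes, p("genotype_dosage.tsv"), p("genotype_snv.tsv"))
  write_tsv(sim$phenotypes, p("phenotypes.tsv"))
  if (!is.null(sim$prt_trials)) write_tsv(sim$prt_trials, p("prt_trials.tsv"))
  write_tsv(sim$rl_choices, p("rl_choices.tsv"))
  truth_df <- data.frame(individual = names(sim$truth$grs),
                         generating_grs = unname(sim$truth$grs),
                         population = sim$truth$population,
                         stringsAsFactors = FALSE)
  write_tsv(truth_df, p("truth.tsv"))

  # genetics stage (from the files, not the in-memory objects)
  weights <- transform_weights(read_tsv(p("weights.tsv")), config$weight_mode)
  geno <- read_genotypes(p("genotype_dosage.tsv"), p("genotype_snv.tsv"))
  qcd <- apply_qc(geno)
  aligned <- align_effect_alleles(qcd, weights)
  grs <- compute_grs(aligned, weights)
  pcs <- ancestry_pcs(aligned, k = length(config$pc_r2))
  write_tsv(grs, p("grs.tsv"))
  write_tsv(data.frame(individual = rownames(pcs$scores), pcs$scores),
            p("pcs.tsv"))

  # PRT stage: trial records -> per-subject stress change
  phen <- read_tsv(p("phenotypes.tsv"))
  if (!is.null(sim$prt_trials)) {
    prt <- prt_summary(read_tsv(p("prt_trials.tsv")))
    write_tsv(prt, p("prt_summary.tsv"))
    phen$prt_stress_change <-
      prt$stress_change[match(phen$individual, prt$subject)]
  }

  # RL stage: RPE regressors and parameter fits
  choices <- read_tsv(p("rl_choices.tsv"))
  rpe <- rpe_regressor(choices, config$rl_params)
  write_tsv(rpe[, c("subject", "condition", "run", "trial", "pair", "delta")],
            p("rpe_regressor.tsv"))
  fit_gain <- qlearn_fit(choices, "gain", per_subject = FALSE)
  fit_loss <- qlearn_fit(choices, "loss", per_subject = FALSE)

  # association stage
  results <- build_results_table(phen, grs, pcs)
  write_tsv(as.data.frame(results), p("results.tsv"))
  usum <- unit_summary(results)
  write_tsv(data.frame(unit = names(usum), variance_explained_pct = unname(usum)),
            p("unit_summary.tsv"))

  report <- c(
    "GRS / anhedonia pipeline report",
    paste0("seed: ", config$seed, "; n = ", config$n_individuals),
    paste0("SNVs: ", config$n_snvs, " in panel, ",
           ncol(qcd$dosage), " after QC"),
    paste0("pooled RL fit (gain): alpha = ",
           sprintf("%.3f", fit_gain$pooled["alpha"]), ", beta = ",
           sprintf("%.3f", fit_gain$pooled["beta"])),
    paste0("pooled RL fit (loss): alpha = ",
           sprintf("%.3f", fit_loss$pooled["alpha"]), ", beta = ",
           sprintf("%.3f", fit_loss$pooled["beta"])),
    "",
    utils::capture.output(print(results))
  )
  writeLines(report, p("report.txt"))

  files <- list.files(outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, p("manifest.tsv"))
  invisible(list(manifest = manifest, results = results,
                 fits = list(gain = fit_gain, loss = fit_loss),
                 paths = stats::setNames(files, basename(files))))
}
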