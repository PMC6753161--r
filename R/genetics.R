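#' @title Genotype container
#'
#' @description A `geno_matrix` is a light S3 container for dosage data:
#' a numeric matrix `dosage` (individuals in rows, SNVs in columns, values in
#' \[0, 2\] counting copies of the per-SNV `counted_allele`, `NA` for missing)
#' plus a per-SNV annotation data frame `snv` with columns `snv_id`,
#' `counted_allele`, `other_allele` and `info` (imputation quality in
#' \[0, 1\]).
#'
#' @param dosage numeric matrix, individuals x SNVs; rownames are individual
#'   ids, colnames are SNV ids.
#' @param snv data frame with columns `snv_id`, `counted_allele`,
#'   `other_allele`, `info`, one row per column of `dosage`.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, snv) {
  stopifnot(is.matrix(dosage),
            is.data.frame(snv),
            ncol(dosage) == nrow(snv),
            all(c("snv_id", "counted_allele", "other_allele", "info") %in% names(snv)))
  if (anyDuplicated(snv$snv_id)) stop("duplicated snv_id in genotype annotation")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  colnames(dosage) <- snv$snv_id
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("I%03d", seq_len(nrow(dosage)))
  }
  structure(list(dosage = dosage, snv = snv), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosage), " individuals x ", ncol(x$dosage),
      " SNVs\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat("  missing dosages: ", format(100 * miss, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

snv_missingness <- function(geno) colMeans(is.na(geno$dosage))
ind_missingness <- function(geno) rowMeans(is.na(geno$dosage))

#' Quality-control filter for genotype data
#'
#' Applies the standard marker- and sample-level filters: SNVs are removed
#' when their missingness exceeds `snv_missing_max` (strictly) or their
#' imputation quality does not exceed `info_min`; individuals are then
#' removed when their missingness across the *surviving* SNVs exceeds
#' `ind_missing_max` (strictly).  Marker-level QC runs before sample-level
#' QC, and the operation is idempotent.
#'
#' @param geno a [geno_matrix()].
#' @param snv_missing_max maximum tolerated per-SNV missing proportion
#'   (default 0.05; a SNV at exactly the threshold is retained).
#' @param ind_missing_max maximum tolerated per-individual missing proportion
#'   (default 0.02).
#' @param info_min retained SNVs must have INFO strictly greater than this
#'   (default 0.8).
#' @return the filtered `geno_matrix`, with a `"qc_log"` attribute listing
#'   removed SNVs/individuals and the reason for each.
#' @export
apply_qc <- function(geno, snv_missing_max = 0.05, ind_missing_max = 0.02,
                     info_min = 0.8) {
  stopifnot(inherits(geno, "geno_matrix"),
            snv_missing_max >= 0, snv_missing_max <= 1,
            ind_missing_max >= 0, ind_missing_max <= 1,
            info_min >= 0, info_min <= 1)
  miss <- snv_missingness(geno)
  drop_miss <- miss > snv_missing_max
  drop_info <- geno$snv$info <= info_min
  drop_snv <- drop_miss | drop_info
  if (all(drop_snv)) stop("QC removed every SNV")
  log_snv <- data.frame(
    snv_id = geno$snv$snv_id[drop_snv],
    reason = ifelse(drop_miss[drop_snv], "missingness", "info"),
    stringsAsFactors = FALSE
  )
  out <- geno_matrix(geno$dosage[, !drop_snv, drop = FALSE],
                     geno$snv[!drop_snv, , drop = FALSE])
  imiss <- ind_missingness(out)
  drop_ind <- imiss > ind_missing_max
  if (all(drop_ind)) stop("QC removed every individual")
  out <- geno_matrix(out$dosage[!drop_ind, , drop = FALSE], out$snv)
  attr(out, "qc_log") <- list(
    snv_removed = log_snv,
    individuals_removed = rownames(geno$dosage)[drop_ind],
    thresholds = c(snv_missing_max = snv_missing_max,
                   ind_missing_max = ind_missing_max, info_min = info_min)
  )
  out
}

strand_ambiguous <- function(a1, a2) {
  p <- paste0(pmin(a1, a2), pmax(a1, a2))
  p %in% c("AT", "CG")
}

#' Orient dosages to the effect allele of a weight table
#'
#' Weighted scoring is only well defined when each dosage counts copies of
#' the allele the GWAS beta refers to.  For every SNV shared with the weight
#' table, if the genotype file's counted allele is the weight table's other
#' allele the dosage is complemented (`2 - dosage`) and the annotation
#' updated; if the allele pair cannot be reconciled at all the function stops
#' and names the SNV.  Strand-ambiguous pairs (A/T, C/G) are resolved by
#' allele match only and reported in the `"align_log"` attribute.
#'
#' @param geno a [geno_matrix()].
#' @param weights weight table with `snv_id`, `effect_allele`, `other_allele`.
#' @return the re-oriented `geno_matrix`, restricted to shared SNVs.
#' @export
align_effect_alleles <- function(geno, weights) {
  stopifnot(inherits(geno, "geno_matrix"))
  shared <- intersect(geno$snv$snv_id, weights$snv_id)
  if (length(shared) == 0L) stop("no SNVs shared between genotypes and weights")
  g <- geno$snv[match(shared, geno$snv$snv_id), ]
  w <- weights[match(shared, weights$snv_id), ]
  same <- g$counted_allele == w$effect_allele & g$other_allele == w$other_allele
  flip <- g$counted_allele == w$other_allele & g$other_allele == w$effect_allele
  bad <- !(same | flip)
  if (any(bad)) {
    stop("allele pair irreconcilable with weight record for SNV(s): ",
         paste(shared[bad], collapse = ", "))
  }
  dos <- geno$dosage[, shared, drop = FALSE]
  if (any(flip)) dos[, flip] <- 2 - dos[, flip]
  snv <- data.frame(
    snv_id = shared,
    counted_allele = w$effect_allele,
    other_allele = w$other_allele,
    info = g$info,
    stringsAsFactors = FALSE
  )
  out <- geno_matrix(dos, snv)
  attr(out, "align_log") <- list(
    flipped = shared[flip],
    strand_ambiguous = shared[strand_ambiguous(g$counted_allele, g$other_allele)]
  )
  out
}

#' Weighted genetic risk score from allele dosages
#'
#' Computes, per individual, `score_i = sum_j weight_j * dosage_ij` over the
#' SNVs shared between the genotype matrix and the weight table.  Dosages
#' must already be oriented to the effect allele (see
#' [align_effect_alleles()]).  Missing dosages are handled by the usual
#' scoring-tool default of frequency mean imputation — a missing entry
#' contributes `2 * p_hat_j * weight_j`, with `p_hat_j` the observed effect
#' allele frequency — or skipped entirely under `missing_policy = "skip"`.
#' Both the raw sum and the per-allele average (`score / (2 * n_snvs_used)`)
#' are reported, since scoring tools differ in convention.
#'
#' @param geno a [geno_matrix()] (QC-filtered and allele-aligned).
#' @param weights weight table with a `weight` column (see
#'   [transform_weights()]); if absent, `beta` is used as-is.
#' @param missing_policy `"mean_impute"` (default) or `"skip"`.
#' @return data frame with columns `individual`, `score`, `score_avg`,
#'   `n_snvs_used`, `n_imputed_missing`.
#' @examples
#' g <- gen_genotypes(gen_weight_table(6, n_qc_fail = 0, seed = 1),
#'                    n_individuals = 10, seed = 2)
#' w <- transform_weights(gen_weight_table(6, n_qc_fail = 0, seed = 1))
#' compute_grs(align_effect_alleles(g, w), w)
#' @export
compute_grs <- function(geno, weights, missing_policy = c("mean_impute", "skip")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(geno, "geno_matrix"))
  shared <- intersect(geno$snv$snv_id, weights$snv_id)
  if (length(shared) == 0L) stop("no SNVs shared between genotypes and weights")
  dos <- geno$dosage[, shared, drop = FALSE]
  w <- weights[match(shared, weights$snv_id), ]
  misaligned <- geno$snv$counted_allele[match(shared, geno$snv$snv_id)] != w$effect_allele
  if (any(misaligned)) {
    stop("dosages not oriented to the effect allele; run align_effect_alleles() first ",
         "(SNVs: ", paste(shared[misaligned], collapse = ", "), ")")
  }
  wt <- if ("weight" %in% names(w)) w$weight else w$beta
  if (any(!is.finite(wt))) stop("non-finite scoring weights")
  isna <- is.na(dos)
  n_missing <- rowSums(isna)
  if (missing_policy == "mean_impute") {
    eaf_hat <- colMeans(dos, na.rm = TRUE) / 2
    fill <- matrix(rep(2 * eaf_hat, each = nrow(dos)), nrow(dos))
    dos[isna] <- fill[isna]
    score <- drop(dos %*% wt)
    n_used <- rep(ncol(dos), nrow(dos))
  } else {
    dos0 <- dos
    dos0[isna] <- 0
    score <- drop(dos0 %*% wt)
    n_used <- ncol(dos) - n_missing
  }
  data.frame(
    individual = rownames(geno$dosage),
    score = score,
    score_avg = score / (2 * pmax(n_used, 1L)),
    n_snvs_used = n_used,
    n_imputed_missing = if (missing_policy == "mean_impute") n_missing else 0L,
    stringsAsFactors = FALSE
  )
}

#' Ancestry principal components from a genotype matrix
#'
#' Standard genotype PCA: missing dosages are mean-imputed, monomorphic SNVs
#' dropped, each column centered by `2 * p_hat` and scaled by
#' `sqrt(2 * p_hat * (1 - p_hat))`, and the top `k` left singular vectors
#' returned as unit-variance scores.  Signs are fixed deterministically by
#' requiring the largest-magnitude SNV loading of each component to be
#' positive.
#'
#' @param geno a [geno_matrix()].
#' @param k number of components (default 2, the usual ancestry covariates).
#' @return list with `scores` (n x k matrix, unit-variance columns, rownames
#'   = individual ids), `loadings`, and `varexp` (fraction of standardized
#'   variance per component).
#' @export
ancestry_pcs <- function(geno, k = 2) {
  stopifnot(inherits(geno, "geno_matrix"), k >= 1)
  X <- geno$dosage
  n <- nrow(X)
  if (n < k + 1) stop("need at least k + 1 individuals for ", k, " components")
  cm <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1 & apply(X, 2, stats::var) > 0
  if (sum(poly) < k) {
    stop("fewer polymorphic SNVs (", sum(poly), ") than requested components (", k, ")")
  }
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u[, seq_len(k), drop = FALSE]
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
    scores[, j] <- scores[, j] / stats::sd(scores[, j])
  }
  rownames(scores) <- rownames(geno$dosage)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       varexp = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}
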