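# hand-built genotype fixtures used across genetics tests

make_geno <- function(dosage, counted = NULL, other = NULL, info = NULL) {
  m <- ncol(dosage)
  snv <- data.frame(
    snv_id = if (is.null(colnames(dosage))) sprintf("snv%02d", seq_len(m))
             else colnames(dosage),
    counted_allele = if (is.null(counted)) rep("A", m) else counted,
    other_allele = if (is.null(other)) rep("G", m) else other,
    info = if (is.null(info)) rep(0.95, m) else info,
    stringsAsFactors = FALSE
  )
  geno_matrix(dosage, snv)
}

make_weights <- function(snv_id, effect, other, beta, eaf = 0.3) {
  data.frame(snv_id = snv_id, effect_allele = effect, other_allele = other,
             beta = beta, weight = beta, eaf = eaf,
             qc_fail = FALSE, stringsAsFactors = FALSE)
}

# a small aligned cohort ready for scoring/association
make_scored_cohort <- function(n = 60, m = 12, seed = 99, fst = 0.05) {
  w <- gen_weight_table(m, n_qc_fail = 0, seed = seed)
  g <- gen_genotypes(w, n_individuals = n, fst = fst, seed = seed + 1)
  w <- transform_weights(w, "identity")
  al <- align_effect_alleles(apply_qc(g), w)
  list(weights = w, geno = al,
       grs = compute_grs(al, w),
       pcs = ancestry_pcs(al, 2))
}
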