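unit_measures <- function() {
  data.frame(
    unit = c("self-report", "behavior", "circuits (functional)",
             "circuits (functional)", "circuits (structural)",
             "circuits (structural)"),
    measure = c("shaps", "prt_stress_change", "nac_rpe_change",
                "put_rpe_change", "nac_volume", "put_volume"),
    label = c("SHAPS score", "PRT stress-induced change in reward learning",
              "Bilateral NAc RPE change", "Bilateral Put RPE change",
              "Bilateral NAc volume", "Bilateral Put volume"),
    is_volume = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    is_circuit = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Association results table across units of analysis
#'
#' Runs, for each anhedonia-related measure, the two-step hierarchical
#' regression — ancestry PCs in step 1, GRS in step 2 — and reports the GRS
#' step's incremental statistics, one row per measure: `n` (listwise),
#' `delta_r2`, `adj_delta_r2`, `delta_f`, `df1`, `df2`, `p`, the
#' standardized GRS coefficient's sign, and for the circuit rows a
#' Bonferroni-corrected significance flag.  Volumetric measures are
#' head-size adjusted first (see [adjust_icv()]).  For the circuit measures
#' a three-step incremental-validity variant — PCs, then the self-report and
#' behavioral measures, then GRS — is appended.
#'
#' Observations can be screened with a z-score outlier rule on each outcome
#' (`|z| > outlier_z` dropped and logged; set `outlier_z = Inf` to disable).
#'
#' @param phenotypes phenotype data frame (see [gen_phenotypes()] for the
#'   column layout; `individual` is the id column).
#' @param grs GRS data frame from [compute_grs()] (or a numeric vector
#'   aligned with `phenotypes`).
#' @param pcs PC score matrix from [ancestry_pcs()] (or the `$scores`
#'   element).
#' @param icv_mode `"residual"` (default) or `"ratio"` head-size adjustment.
#' @param outlier_z outcome z-score exclusion threshold (default 3).
#' @param bonferroni_m number of circuit tests corrected for (default 2).
#' @param alpha nominal significance level (default 0.05).
#' @param three_step also fit the incremental-validity three-step models.
#' @return data frame of class `grs_assoc_table`, with attributes
#'   `unit_summary` (percent variance explained per unit of analysis),
#'   `outliers` (removed observations) and `bonferroni` (corrected
#'   threshold).
#' @export
build_results_table <- function(phenotypes, grs, pcs,
                                icv_mode = c("residual", "ratio"),
                                outlier_z = 3, bonferroni_m = 2,
                                alpha = 0.05, three_step = TRUE) {
  icv_mode <- match.arg(icv_mode)
  if (is.data.frame(grs)) {
    grs <- stats::setNames(grs$score, grs$individual)
  }
  if (is.list(pcs) && !is.null(pcs$scores)) pcs <- pcs$scores
  pcs <- as.matrix(pcs)
  um <- unit_measures()
  missing_cols <- setdiff(c("individual", um$measure, "icv"), names(phenotypes))
  if (length(missing_cols)) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- phenotypes$individual
  d <- data.frame(individual = ids,
                  grs = grs[match(ids, names(grs))],
                  pcs[match(ids, rownames(pcs)), , drop = FALSE],
                  phenotypes[, c(um$measure, "icv")],
                  stringsAsFactors = FALSE)
  if (anyNA(d$grs)) {
    d <- d[!is.na(d$grs), , drop = FALSE]
  }
  pc_names <- colnames(pcs)
  # head-size adjust the volumes
  for (mcol in um$measure[um$is_volume]) {
    d[[mcol]] <- adjust_icv(d[[mcol]], d$icv, method = icv_mode)
  }
  outlog <- NULL
  rows <- vector("list", nrow(um))
  for (i in seq_len(nrow(um))) {
    mcol <- um$measure[i]
    di <- d[!is.na(d[[mcol]]) & stats::complete.cases(d[, pc_names]), ]
    z <- (di[[mcol]] - mean(di[[mcol]])) / stats::sd(di[[mcol]])
    out <- abs(z) > outlier_z
    if (any(out)) {
      outlog <- rbind(outlog, data.frame(measure = mcol,
                                         individual = di$individual[out],
                                         z = z[out]))
      di <- di[!out, ]
    }
    f <- stats::as.formula(paste(mcol, "~", paste(pc_names, collapse = " + "),
                                 "+ grs"))
    fit <- hreg(f, di, blocks = list(pc_names, "grs"))
    s <- fit$steps[2, ]
    rows[[i]] <- data.frame(
      unit = um$unit[i], measure = um$label[i], n = fit$n_used,
      delta_r2 = s$delta_r2, adj_delta_r2 = s$adj_delta_r2,
      delta_f = s$delta_f, df1 = s$df1, df2 = s$df2, p = s$p,
      grs_sign = sign(unname(fit$coefficients["grs"])),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  thr <- bonferroni_threshold(alpha, bonferroni_m)
  tab$significant <- ifelse(um$is_circuit, tab$p < thr, tab$p < alpha)
  tab$model <- "two-step"
  if (three_step) {
    beh <- c("shaps", "prt_stress_change")
    rows3 <- lapply(which(um$is_circuit), function(i) {
      mcol <- um$measure[i]
      di <- d[stats::complete.cases(d[, c(mcol, pc_names, beh, "grs")]), ]
      f <- stats::as.formula(paste(mcol, "~",
                                   paste(c(pc_names, beh, "grs"), collapse = " + ")))
      fit <- hreg(f, di, blocks = list(pc_names, beh, "grs"))
      s <- fit$steps[3, ]
      data.frame(unit = um$unit[i], measure = um$label[i], n = fit$n_used,
                 delta_r2 = s$delta_r2, adj_delta_r2 = s$adj_delta_r2,
                 delta_f = s$delta_f, df1 = s$df1, df2 = s$df2, p = s$p,
                 grs_sign = sign(unname(fit$coefficients["grs"])),
                 significant = s$p < thr, model = "three-step",
                 stringsAsFactors = FALSE)
    })
    tab <- rbind(tab, do.call(rbind, rows3))
  }
  two <- tab[tab$model == "two-step", ]
  usum <- unit_summary_from_r2(stats::setNames(two$delta_r2,
                                               c("shaps", "prt", "nac_rpe",
                                                 "put_rpe", "nac_vol", "put_vol")))
  structure(tab, class = c("grs_assoc_table", "data.frame"),
            unit_summary = usum, outliers = outlog, bonferroni = thr,
            icv_mode = icv_mode)
}

#' Variance explained by unit of analysis
#'
#' @param x a `grs_assoc_table` from [build_results_table()].
#' @return named vector of percent incremental variance explained by the
#'   GRS for each unit of analysis (functional and structural circuit
#'   entries are the average of their two regional rows).
#' @export
unit_summary <- function(x) {
  stopifnot(inherits(x, "grs_assoc_table"))
  attr(x, "unit_summary")
}

#' Unit-of-analysis summary from incremental R-squared values
#'
#' The arithmetic behind the variance-explained-by-unit comparison: the
#' self-report and behavioral units report their single measure's
#' incremental R-squared as a percentage, while each circuit unit reports
#' the average of its two regional measures.
#'
#' @param r2 named vector with entries `shaps`, `prt`, `nac_rpe`,
#'   `put_rpe`, `nac_vol`, `put_vol` (fractions in \[0, 1\]).
#' @return named vector of percentages for the four units of analysis.
#' @examples
#' unit_summary_from_r2(cohort_config()$per_unit_target_r2)
#' @export
unit_summary_from_r2 <- function(r2) {
  need <- c("shaps", "prt", "nac_rpe", "put_rpe", "nac_vol", "put_vol")
  if (!all(need %in% names(r2))) {
    stop("'r2' must name all units: ", paste(need, collapse = ", "))
  }
  c("self-report" = 100 * unname(r2["shaps"]),
    "behavior" = 100 * unname(r2["prt"]),
    "circuits (functional)" = 100 * mean(r2[c("nac_rpe", "put_rpe")]),
    "circuits (structural)" = 100 * mean(r2[c("nac_vol", "put_vol")]))
}

#' @export
print.grs_assoc_table <- function(x, digits = 3, ...) {
  cat("GRS association across units of analysis\n")
  cat("Bonferroni threshold (circuit rows):", format(attr(x, "bonferroni")),
      "; ICV adjustment:", attr(x, "icv_mode"), "\n\n")
  df <- as.data.frame(x)
  num <- c("delta_r2", "adj_delta_r2", "delta_f", "p")
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  us <- attr(x, "unit_summary")
  cat("\nVariance explained by unit (%):\n")
  print(round(us, 2))
  ol <- attr(x, "outliers")
  if (!is.null(ol)) {
    cat("\nOutliers removed:\n")
    print(ol, row.names = FALSE)
  }
  invisible(x)
}

#' Bar plot of variance explained per unit of analysis
#'
#' @param x a `grs_assoc_table`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.grs_assoc_table <- function(x, ...) {
  us <- attr(x, "unit_summary")
  graphics::barplot(us, ylab = "incremental variance explained by GRS (%)",
                    las = 2, ...)
  invisible(us)
}
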