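#' Transform GWAS effect sizes into scoring weights
#'
#' Populates the `weight` column of a weight table.  `"identity"` copies the
#' regression beta unchanged (appropriate for linear-scale effect sizes, which
#' may be signed).  `"log"` applies the natural logarithm and is only valid
#' for effect sizes on the odds-ratio scale, which are strictly positive; a
#' non-positive value under `"log"` is an error naming the offending SNV
#' rather than a silently fabricated weight.
#'
#' @param weights data frame with at least `snv_id` and `beta` columns (see
#'   [gen_weight_table()] for the full layout).
#' @param mode `"identity"` or `"log"`.
#' @return the weight table with a `weight` column added (or replaced).
#' @examples
#' w <- gen_weight_table(5, seed = 1)
#' transform_weights(w, "identity")$weight
#' @export
transform_weights <- function(weights, mode = c("identity", "log")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(weights), all(c("snv_id", "beta") %in% names(weights)))
  if (mode == "identity") {
    weights$weight <- weights$beta
  } else {
    bad <- weights$beta <= 0 | !is.finite(weights$beta)
    if (any(bad)) {
      stop("log-mode weights require strictly positive betas (odds-ratio scale); ",
           "offending SNV(s): ", paste(weights$snv_id[bad], collapse = ", "))
    }
    weights$weight <- log(weights$beta)
  }
  weights
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 2)  # 0.025
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 2) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha <= 1)
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("'m' must be a count >= 1")
  }
  alpha / m
}
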