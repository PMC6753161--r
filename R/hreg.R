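#' Hierarchical (blockwise) linear regression with F-change tests
#'
#' Fits a sequence of nested ordinary-least-squares models, entering the
#' terms of `formula` block by block, and reports for each step the
#' cumulative R-squared, the increment `delta_r2`, its F-change statistic
#' `delta_f = (delta_r2 / q) / ((1 - R2_step) / df2)` with `q` the number of
#' predictors added and `df2 = n - p_cumulative - 1`, and the upper-tail
#' p-value.  This is the workhorse behind "unique variance explained by a
#' predictor after accounting for covariates": the last block's `delta_r2`
#' is that unique variance.
#'
#' A bias-adjusted increment (`adj_delta_r2`, the difference of
#' Wherry-adjusted R-squared between the cumulative and the previous model)
#' is also reported; unlike the raw increment it is approximately unbiased
#' for the population incremental variance.
#'
#' Rows with a missing response or predictor are dropped listwise.  Rank
#' deficiency among the predictors is an error naming the collinear columns;
#' an exactly zero residual variance yields an infinite F with p = 0 and a
#' warning.
#'
#' @param formula full-model formula, e.g. `y ~ PC1 + PC2 + grs`.
#' @param data data frame.
#' @param blocks list of character vectors of term labels, one element per
#'   step, partitioning the formula's terms in entry order.  Default: every
#'   term is its own block.
#' @return object of class `hreg`: list with `steps` (one row per block:
#'   `block`, `terms`, `q`, `r2`, `delta_r2`, `adj_delta_r2`, `delta_f`,
#'   `df1`, `df2`, `p`), `coefficients` (final model), `fitted`,
#'   `residuals`, `n_used`, `formula`, `blocks`, `model` (the model frame).
#' @examples
#' d <- data.frame(y = rnorm(40), p1 = rnorm(40), p2 = rnorm(40), g = rnorm(40))
#' fit <- hreg(y ~ p1 + p2 + g, d, blocks = list(c("p1", "p2"), "g"))
#' fit$steps
#' @export
hreg <- function(formula, data, blocks = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  terms_obj <- attr(mf, "terms")
  labels <- attr(terms_obj, "term.labels")
  if (length(labels) == 0L) stop("the model needs at least one predictor term")
  if (is.null(blocks)) blocks <- as.list(labels)
  blocks <- lapply(blocks, as.character)
  if (!identical(unlist(blocks), labels)) {
    stop("'blocks' must partition the formula terms in entry order; terms are: ",
         paste(labels, collapse = ", "))
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(terms_obj, mf)
  assign <- attr(X, "assign")
  n <- length(y)
  p_total <- ncol(X) - 1L
  if (n < p_total + 2L) stop("too few complete rows (", n, ") for ",
                             p_total, " predictors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient predictor matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("the response has zero variance")
  block_of_term <- rep(seq_along(blocks), lengths(blocks))
  # map each model-matrix column (past the intercept) to its block
  col_block <- c(0L, block_of_term[assign[-1L]])
  nstep <- length(blocks)
  r2 <- numeric(nstep); pcum <- integer(nstep)
  prev_r2 <- 0; prev_p <- 0L
  adj <- function(R2, p) 1 - (1 - R2) * (n - 1) / (n - p - 1)
  steps <- vector("list", nstep)
  for (b in seq_len(nstep)) {
    cols <- which(col_block <= b)
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    rss <- sum(fit$residuals^2)
    R2 <- 1 - rss / tss
    p_cum <- length(cols) - 1L
    q <- p_cum - prev_p
    df2 <- n - p_cum - 1L
    if (df2 < 1L) stop("no residual degrees of freedom at step ", b)
    dr2 <- R2 - prev_r2
    if (rss <= tss * 1e-14) {
      warning("zero residual variance at step ", b,
              "; F-change reported as infinite")
      dF <- Inf
      pval <- 0
    } else {
      dF <- (dr2 / q) / ((1 - R2) / df2)
      pval <- stats::pf(dF, q, df2, lower.tail = FALSE)
    }
    steps[[b]] <- data.frame(
      block = b, terms = paste(blocks[[b]], collapse = " + "), q = q,
      r2 = R2, delta_r2 = dr2,
      adj_delta_r2 = adj(R2, p_cum) - adj(prev_r2, prev_p),
      delta_f = dF, df1 = q, df2 = df2, p = pval,
      stringsAsFactors = FALSE
    )
    prev_r2 <- R2; prev_p <- p_cum
    if (b == nstep) final <- fit
  }
  structure(list(
    steps = do.call(rbind, steps),
    coefficients = final$coefficients,
    fitted = drop(X %*% final$coefficients),
    residuals = final$residuals,
    n_used = n,
    formula = formula,
    blocks = blocks,
    model = mf
  ), class = "hreg")
}

#' @export
print.hreg <- function(x, digits = 4, ...) {
  cat("Hierarchical regression:", deparse(x$formula), "\n")
  cat("n =", x$n_used, "(listwise complete)\n\n")
  s <- x$steps
  s$terms <- format(s$terms)
  print(format(s, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.hreg <- function(object, ...) {
  structure(list(steps = object$steps, coefficients = object$coefficients,
                 n_used = object$n_used, formula = object$formula,
                 r2_full = object$steps$r2[nrow(object$steps)]),
            class = "summary.hreg")
}

#' @export
print.summary.hreg <- function(x, digits = 4, ...) {
  cat("Hierarchical regression:", deparse(x$formula), "\n")
  cat("n =", x$n_used, "; full-model R2 =", format(x$r2_full, digits = digits),
      "\n\nSteps:\n")
  print(format(x$steps, digits = digits), row.names = FALSE)
  cat("\nFinal-model coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.hreg <- function(object, ...) object$coefficients

#' @export
residuals.hreg <- function(object, ...) object$residuals

#' @export
fitted.hreg <- function(object, ...) object$fitted

#' @export
nobs.hreg <- function(object, ...) object$n_used

#' @export
predict.hreg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                  na.action = stats::na.pass))
  drop(X %*% object$coefficients)
}

#' Residualized added-variable plot for the final block
#'
#' Plots the response and the final block's (single) predictor, each
#' residualized on all earlier blocks — the usual way an incremental
#' association is displayed once covariate variance is removed.
#'
#' @param x an [hreg()] fit whose last block adds exactly one predictor.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hreg <- function(x, ...) {
  lastb <- x$blocks[[length(x$blocks)]]
  if (length(lastb) != 1L) {
    stop("plot.hreg needs a final block with exactly one predictor")
  }
  mf <- x$model
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!lastb %in% colnames(X)) {
    stop("final-block predictor '", lastb, "' is not a single numeric column")
  }
  gcol <- X[, lastb]
  Z <- X[, setdiff(colnames(X), lastb), drop = FALSE]
  ry <- stats::lm.fit(Z, y)$residuals
  rg <- stats::lm.fit(Z, gcol)$residuals
  graphics::plot(rg, ry, xlab = paste(lastb, "(residualized)"),
                 ylab = "response (residualized)", ...)
  graphics::abline(stats::lm(ry ~ rg), lty = 2)
  invisible(list(x = rg, y = ry))
}

#' Upper-tail probability of the F distribution
#'
#' Convenience wrapper used for F-change tests: `P(F(df1, df2) >= f)`.
#'
#' @param f observed F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @return upper-tail probability.
#' @examples
#' f_tail_p(5.14, 1, 58)
#' @export
f_tail_p <- function(f, df1, df2) {
  if (any(f < 0)) stop("F must be non-negative")
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Residualize a vector on covariates
#'
#' Returns `y` minus its least-squares projection on `[1, X]` — the
#' covariate-removed values used for plotting incremental associations.
#'
#' @param y numeric vector.
#' @param X covariate matrix (a vector is treated as one column).
#' @return residual vector, orthogonal to every column of `X` and to the
#'   intercept.
#' @export
residualize <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  M <- cbind(`(Intercept)` = 1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) stop("covariate matrix is rank deficient")
  stats::lm.fit(M, y)$residuals
}

#' Head-size adjustment of regional brain volumes
#'
#' Removes inter-individual differences in total brain size from a regional
#' volume.  `"residual"` (default) regresses the volume on intracranial
#' volume (ICV) and returns the residual re-centered at the sample mean
#' volume; `"ratio"` rescales each volume by `mean(icv) / icv`.  The
#' residual method is the default because ratio adjustment distorts
#' whenever the volume–ICV relationship is not strict proportionality.
#'
#' @param volume regional volumes (mm^3), positive.
#' @param icv intracranial volumes (mm^3), positive.
#' @param method `"residual"` or `"ratio"`.
#' @return adjusted volumes on the original scale.
#' @export
adjust_icv <- function(volume, icv, method = c("residual", "ratio")) {
  method <- match.arg(method)
  stopifnot(length(volume) == length(icv))
  ok <- !is.na(volume) & !is.na(icv)
  if (any(volume[ok] <= 0) || any(icv[ok] <= 0)) {
    stop("volumes and ICV must be positive")
  }
  if (stats::sd(icv[ok]) == 0) stop("ICV has zero variance; cannot adjust")
  out <- rep(NA_real_, length(volume))
  if (method == "residual") {
    fit <- stats::lm.fit(cbind(1, icv[ok]), volume[ok])
    out[ok] <- fit$residuals + mean(volume[ok])
  } else {
    out[ok] <- volume[ok] * mean(icv[ok]) / icv[ok]
  }
  out
}
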