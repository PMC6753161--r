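#' Q-learning model parameters
#'
#' Container for the learning rates and softmax temperatures of the
#' instrumental-learning model, one pair per valence.  The temperature is a
#' *divisor*: choice probabilities come from `exp(Q / beta)`, so larger
#' `beta` means more random choice.  (Packages that use a multiplier
#' convention would call `1 / beta` the inverse temperature.)  The defaults
#' are the population-level values used for regressor generation.
#'
#' @param alpha_gain,alpha_loss learning rates in (0, 1].
#' @param beta_gain,beta_loss softmax temperatures > 0.
#' @return a list of class `qlearn_params`.
#' @export
qlearn_params <- function(alpha_gain = 0.28, beta_gain = 2.24,
                          alpha_loss = 0.46, beta_loss = 5.23) {
  for (a in c(alpha_gain, alpha_loss)) {
    if (!is.numeric(a) || a <= 0 || a > 1) stop("alpha must lie in (0, 1]")
  }
  for (b in c(beta_gain, beta_loss)) {
    if (!is.numeric(b) || b <= 0) stop("beta must be > 0")
  }
  structure(list(alpha_gain = alpha_gain, beta_gain = beta_gain,
                 alpha_loss = alpha_loss, beta_loss = beta_loss),
            class = "qlearn_params")
}

#' @export
print.qlearn_params <- function(x, ...) {
  cat("Q-learning parameters (beta = softmax divisor)\n")
  cat(sprintf("  gain: alpha = %.3g, beta = %.3g\n", x$alpha_gain, x$beta_gain))
  cat(sprintf("  loss: alpha = %.3g, beta = %.3g\n", x$alpha_loss, x$beta_loss))
  invisible(x)
}

#' Instrumental-task design
#'
#' @param conditions stress-condition labels; Q values are re-initialized at
#'   0 at each condition boundary.
#' @param runs_per_condition task runs per condition (default 2).
#' @param trials_per_pair_run presentations of each stimulus pair per run
#'   (default 12).
#' @param pairs which pair types to include.
#' @param p_win_good probability that the advantageous stimulus of a pair
#'   delivers its better outcome (default 0.8; the other stimulus uses
#'   `1 - p_win_good`).
#' @return a list of class `qlearn_design`.
#' @export
qlearn_design <- function(conditions = c("prestress", "during", "poststress"),
                          runs_per_condition = 2, trials_per_pair_run = 12,
                          pairs = c("gain", "loss", "neutral"),
                          p_win_good = 0.8) {
  stopifnot(length(conditions) >= 1, runs_per_condition >= 1,
            trials_per_pair_run >= 1, p_win_good > 0, p_win_good < 1,
            all(pairs %in% c("gain", "loss", "neutral")))
  structure(list(conditions = conditions,
                 runs_per_condition = as.integer(runs_per_condition),
                 trials_per_pair_run = as.integer(trials_per_pair_run),
                 pairs = pairs, p_win_good = p_win_good),
            class = "qlearn_design")
}

#' Softmax choice probability
#'
#' `P(choose A) = exp(Qa / beta) / (exp(Qa / beta) + exp(Qb / beta))`,
#' evaluated overflow-safely as a logistic in `(Qa - Qb) / beta`.
#'
#' @param qa,qb expected values of the two options (vectorized).
#' @param beta softmax temperature (divisor), > 0.
#' @return probability of choosing option A; `P(A) + P(B) = 1` holds to
#'   machine precision.
#' @examples
#' softmax_choice_prob(1, 0, 2.24)
#' @export
softmax_choice_prob <- function(qa, qb, beta) {
  if (any(beta <= 0)) stop("beta must be > 0")
  stats::plogis((qa - qb) / beta)
}

#' One Q-learning update
#'
#' `delta = R - Q`; `Q_next = Q + alpha * delta`.  Only the chosen
#' stimulus's value is updated in the task; this helper updates the single
#' value it is given.
#'
#' @param q current expected value.
#' @param r outcome (reinforcement magnitude, +1 / -1 / 0 in this task).
#' @param alpha learning rate in (0, 1].
#' @return list with `q` (updated value) and `delta` (prediction error).
#' @examples
#' q_update(0, 1, 0.28)  # delta 1, q 0.28
#' @export
q_update <- function(q, r, alpha) {
  if (any(alpha <= 0) || any(alpha > 1)) stop("alpha must lie in (0, 1]")
  delta <- r - q
  list(q = q + alpha * delta, delta = delta)
}

pair_params <- function(params, pair) {
  if (pair == "loss") c(params$alpha_loss, params$beta_loss)
  else c(params$alpha_gain, params$beta_gain)
}

# outcome magnitudes per pair type and probability that stimulus A (the
# advantageous one) delivers the non-zero outcome
pair_outcome <- function(pair, choice_is_A, p_good, u) {
  if (pair == "neutral") return(0)
  if (pair == "gain") {
    p <- if (choice_is_A) p_good else 1 - p_good
    if (u < p) 1 else 0
  } else {
    p <- if (choice_is_A) 1 - p_good else p_good  # A loses rarely
    if (u < p) -1 else 0
  }
}

#' Simulate choices from the Q-learning/softmax model
#'
#' Q values start at 0 for every pair and are re-initialized at each
#' condition boundary (or at each run boundary with `reset = "run"`).
#' Choices are sampled from the softmax rule and outcomes from the pair's
#' outcome probabilities; neutral outcomes are always 0, so neutral-pair Q
#' values never move.
#'
#' @param params a [qlearn_params()] (used as the generative, per-valence
#'   values).
#' @param design a [qlearn_design()].
#' @param n_subjects number of subjects.
#' @param reset `"condition"` (default) or `"run"`.
#' @param seed optional integer seed.
#' @return data frame with columns `subject`, `condition`, `run`, `trial`,
#'   `pair`, `choice` ("A"/"B"), `outcome`.
#' @export
simulate_qlearning <- function(params = qlearn_params(),
                               design = qlearn_design(),
                               n_subjects = 1, reset = c("condition", "run"),
                               seed = NULL) {
  stopifnot(inherits(params, "qlearn_params"), inherits(design, "qlearn_design"))
  reset <- match.arg(reset)
  if (!is.null(seed)) set.seed(seed)
  per_run <- design$trials_per_pair_run * length(design$pairs)
  ntot <- n_subjects * length(design$conditions) * design$runs_per_condition * per_run
  subject <- integer(ntot); condition <- character(ntot); run <- integer(ntot)
  trial <- integer(ntot); pairv <- character(ntot); choice <- character(ntot)
  outcome <- numeric(ntot)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    for (cond in design$conditions) {
      Q <- sapply(design$pairs, function(p) c(A = 0, B = 0), simplify = FALSE)
      for (r in seq_len(design$runs_per_condition)) {
        if (reset == "run") {
          Q <- sapply(design$pairs, function(p) c(A = 0, B = 0), simplify = FALSE)
        }
        order <- sample(rep(design$pairs, each = design$trials_per_pair_run))
        for (t in seq_along(order)) {
          p <- order[t]
          ab <- pair_params(params, p)
          pa <- softmax_choice_prob(Q[[p]][1], Q[[p]][2], ab[2])
          ch <- if (stats::runif(1) < pa) 1L else 2L
          out <- pair_outcome(p, ch == 1L, design$p_win_good, stats::runif(1))
          Q[[p]][ch] <- Q[[p]][ch] + ab[1] * (out - Q[[p]][ch])
          i <- i + 1L
          subject[i] <- s; condition[i] <- cond; run[i] <- r; trial[i] <- t
          pairv[i] <- p; choice[i] <- c("A", "B")[ch]; outcome[i] <- out
        }
      }
    }
  }
  data.frame(subject = subject, condition = condition, run = run,
             trial = trial, pair = pairv, choice = choice, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Trial-wise reward-prediction-error regressor
#'
#' Replays the Q-learning update over observed choices and outcomes with
#' fixed (population-level) parameters, emitting the expected values held at
#' each decision and the prediction error `delta = outcome - Q_chosen`.
#' Q values reset to 0 at each condition boundary (or run boundary with
#' `reset = "run"`).  The resulting `delta` column for win and loss trials
#' is the parametric-modulator regressor used in event-related modeling.
#'
#' @param choices choice data frame as produced by [simulate_qlearning()]
#'   (columns `subject`, `condition`, `run`, `trial`, `pair`, `choice`,
#'   `outcome`).
#' @param params a [qlearn_params()].
#' @param reset `"condition"` (default) or `"run"`.
#' @return the choice data frame with `qa`, `qb`, `q_chosen` and `delta`
#'   columns appended; `delta == outcome - q_chosen` exactly.
#' @export
rpe_regressor <- function(choices, params = qlearn_params(),
                          reset = c("condition", "run")) {
  reset <- match.arg(reset)
  stopifnot(inherits(params, "qlearn_params"))
  bad <- !choices$pair %in% c("gain", "loss", "neutral")
  if (any(bad)) {
    stop("unknown pair type(s): ", paste(unique(choices$pair[bad]), collapse = ", "))
  }
  n <- nrow(choices)
  qa <- numeric(n); qb <- numeric(n); delta <- numeric(n)
  seg <- if (reset == "condition") {
    interaction(choices$subject, choices$condition, choices$pair, drop = TRUE)
  } else {
    interaction(choices$subject, choices$condition, choices$run, choices$pair,
                drop = TRUE)
  }
  for (g in split(seq_len(n), seg)) {
    p <- choices$pair[g[1]]
    ab <- pair_params(params, p)
    Q <- c(0, 0)
    for (i in g) {
      qa[i] <- Q[1]; qb[i] <- Q[2]
      ch <- if (choices$choice[i] == "A") 1L else 2L
      delta[i] <- choices$outcome[i] - Q[ch]
      Q[ch] <- Q[ch] + ab[1] * delta[i]
    }
  }
  choices$qa <- qa
  choices$qb <- qb
  choices$q_chosen <- ifelse(choices$choice == "A", qa, qb)
  choices$delta <- delta
  choices
}

# --- internal fitting machinery ------------------------------------------

# per-subject segment list: choice_is_A, outcome, and reset boundaries
fit_segments <- function(choices, valence, reset) {
  d <- choices[choices$pair == valence, , drop = FALSE]
  if (nrow(d) == 0L) stop("no '", valence, "' trials to fit")
  segkey <- if (reset == "condition") paste(d$condition) else
    paste(d$condition, d$run)
  lapply(split(d, d$subject), function(ds) {
    sk <- if (reset == "condition") ds$condition else paste(ds$condition, ds$run)
    list(isA = ds$choice == "A", out = ds$outcome,
         new_seg = c(TRUE, sk[-1] != sk[-length(sk)]))
  })
}

# negative log-likelihood for one subject at scalar (alpha, beta)
nll_subject <- function(alpha, beta, seg) {
  Q <- c(0, 0); ll <- 0
  for (i in seq_along(seg$isA)) {
    if (seg$new_seg[i]) Q <- c(0, 0)
    pa <- stats::plogis((Q[1] - Q[2]) / beta)
    p <- if (seg$isA[i]) pa else 1 - pa
    ll <- ll + log(max(p, 1e-300))
    ch <- if (seg$isA[i]) 1L else 2L
    Q[ch] <- Q[ch] + alpha * (seg$out[i] - Q[ch])
  }
  -ll
}

# log-likelihood surface over an alpha x beta grid, vectorized over alpha
ll_grid_subject <- function(seg, alphas, betas) {
  na <- length(alphas); nb <- length(betas)
  ll <- matrix(0, na, nb)
  Q1 <- numeric(na); Q2 <- numeric(na)
  inv_b <- 1 / betas
  for (i in seq_along(seg$isA)) {
    if (seg$new_seg[i]) { Q1[] <- 0; Q2[] <- 0 }
    pa <- stats::plogis(outer(Q1 - Q2, inv_b))
    p <- if (seg$isA[i]) pa else 1 - pa
    ll <- ll + log(pmax(p, 1e-300))
    if (seg$isA[i]) Q1 <- Q1 + alphas * (seg$out[i] - Q1)
    else Q2 <- Q2 + alphas * (seg$out[i] - Q2)
  }
  ll
}

# pooled negative log-likelihood, vectorized over subjects
nll_pooled <- function(par, segs, box) {
  a <- par[1]; b <- par[2]
  if (a < box[1] || a > box[2] || b < box[3] || b > box[4]) return(1e12)
  sum(vapply(segs, function(s) nll_subject(a, b, s), 0))
}

#' Choice log-likelihood at fixed Q-learning parameters
#'
#' Sums `log P(chosen option | Q history, alpha, beta)` over all trials of
#' one valence, replaying the Q-update with the given parameters.  This is
#' the objective [qlearn_fit()] maximizes, exposed so fitted likelihoods
#' can be compared against alternatives (or against brute-force
#' enumeration on short sequences).
#'
#' @inheritParams qlearn_fit
#' @param alpha,beta parameter values at which to evaluate.
#' @return total log-likelihood (scalar).
#' @export
qlearn_loglik <- function(choices, valence = c("gain", "loss"), alpha, beta,
                          reset = c("condition", "run")) {
  valence <- match.arg(valence)
  reset <- match.arg(reset)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (beta <= 0) stop("beta must be > 0")
  segs <- fit_segments(choices, valence, reset)
  -sum(vapply(segs, function(s) nll_subject(alpha, beta, s), 0))
}

# pick the (alpha, beta) grid maximizer; ties go to smaller alpha, then beta
grid_argmax <- function(ll, alphas, betas) {
  hits <- which(ll == max(ll), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(alpha = alphas[hits[1, 1]], beta = betas[hits[1, 2]])
}

#' Maximum-likelihood estimation of Q-learning parameters
#'
#' Fits the softmax choice likelihood for one valence (gain or loss pairs),
#' replaying the Q-update over each subject's observed choices and outcomes.
#' The per-subject objective `sum_t log P(chosen option | Q history, alpha,
#' beta)` is maximized by a grid search (`alpha` in steps of 0.01,
#' log-spaced `beta`) followed by Nelder–Mead refinement inside the box;
#' exact grid ties break toward smaller `alpha`, then smaller `beta`.  Two
#' group-level summaries are produced: the mean (and median) of the
#' per-subject estimates, and the *pooled* estimate maximizing the summed
#' likelihood under a shared-parameter model.  The pooled estimate is the
#' package's preferred group value: at this task's trial counts per-subject
#' likelihoods are shallow, individual MLEs pile up on the parameter bounds,
#' and their mean is badly biased, while the pooled MLE is approximately
#' unbiased (see the methods vignette).
#'
#' Degenerate sequences (a subject choosing the same option on every trial)
#' yield a boundary estimate and are flagged, not an error.
#'
#' @param choices choice data frame (see [simulate_qlearning()]).
#' @param valence `"gain"` or `"loss"`.
#' @param alpha_grid,beta_grid grid values for the coarse search.
#' @param beta_max upper bound of the beta search box.
#' @param refine run Nelder–Mead refinement from the grid optimum.
#' @param per_subject compute per-subject estimates (set `FALSE` to fit only
#'   the pooled model, which is much faster for large simulations).
#' @param reset Q-reset convention used in the replay.
#' @return object of class `qlearn_fit`: list with `valence`, `subjects`
#'   (per-subject data frame with `alpha`, `beta`, `logLik`, `boundary`),
#'   `group_mean`, `group_median`, `pooled` (named vector with `alpha`,
#'   `beta`), `logLik_pooled`, `n_subjects`, `n_trials`.
#' @export
qlearn_fit <- function(choices, valence = c("gain", "loss"),
                       alpha_grid = seq(0.01, 1, by = 0.01),
                       beta_grid = exp(seq(log(0.1), log(15), length.out = 25)),
                       beta_max = 15, refine = TRUE, per_subject = TRUE,
                       reset = c("condition", "run")) {
  valence <- match.arg(valence)
  reset <- match.arg(reset)
  segs <- fit_segments(choices, valence, reset)
  box <- c(1e-3, 1, 1e-3, beta_max)
  subj <- NULL
  if (per_subject) {
    est <- t(vapply(segs, function(s) {
      ll <- ll_grid_subject(s, alpha_grid, beta_grid)
      par <- grid_argmax(ll, alpha_grid, beta_grid)
      if (refine) {
        o <- stats::optim(par, function(p) {
          if (p[1] < box[1] || p[1] > box[2] || p[2] < box[3] || p[2] > box[4])
            return(1e12)
          nll_subject(p[1], p[2], s)
        }, method = "Nelder-Mead", control = list(maxit = 300))
        par <- o$par
      }
      c(par, -nll_subject(par[1], par[2], s))
    }, numeric(3)))
    degenerate <- vapply(segs, function(s) length(unique(s$isA)) == 1L, TRUE)
    subj <- data.frame(
      subject = names(segs),
      alpha = est[, 1], beta = est[, 2], logLik = est[, 3],
      boundary = degenerate |
        est[, 1] <= box[1] + 1e-6 | est[, 1] >= box[2] - 1e-6 |
        est[, 2] <= box[3] + 1e-6 | est[, 2] >= box[4] - 1e-6,
      stringsAsFactors = FALSE
    )
    rownames(subj) <- NULL
  }
  # pooled fit: coarse grid then refinement on the summed likelihood
  ag <- seq(0.05, 0.95, by = 0.1)
  bg <- exp(seq(log(0.3), log(beta_max * 0.8), length.out = 10))
  llp <- Reduce(`+`, lapply(segs, ll_grid_subject, alphas = ag, betas = bg))
  par <- grid_argmax(llp, ag, bg)
  o <- stats::optim(par, nll_pooled, segs = segs, box = box,
                    method = "Nelder-Mead",
                    control = list(maxit = 500, reltol = 1e-10))
  pooled <- c(alpha = unname(o$par[1]), beta = unname(o$par[2]))
  structure(list(
    valence = valence,
    subjects = subj,
    group_mean = if (per_subject) c(alpha = mean(subj$alpha), beta = mean(subj$beta)),
    group_median = if (per_subject) c(alpha = stats::median(subj$alpha),
                                      beta = stats::median(subj$beta)),
    pooled = pooled,
    logLik_pooled = -o$value,
    n_subjects = length(segs),
    n_trials = sum(vapply(segs, function(s) length(s$isA), 0L))
  ), class = "qlearn_fit")
}

#' @export
print.qlearn_fit <- function(x, ...) {
  cat("Q-learning fit (", x$valence, " pairs): ", x$n_subjects, " subjects, ",
      x$n_trials, " trials\n", sep = "")
  cat(sprintf("  pooled MLE:    alpha = %.3f, beta = %.3f  (logLik %.1f)\n",
              x$pooled["alpha"], x$pooled["beta"], x$logLik_pooled))
  if (!is.null(x$subjects)) {
    cat(sprintf("  subject means: alpha = %.3f, beta = %.3f  (%d boundary fits)\n",
                x$group_mean["alpha"], x$group_mean["beta"],
                sum(x$subjects$boundary)))
  }
  invisible(x)
}

#' @export
coef.qlearn_fit <- function(object, type = c("pooled", "mean", "median"), ...) {
  type <- match.arg(type)
  switch(type,
         pooled = object$pooled,
         mean = object$group_mean,
         median = object$group_median)
}

#' @export
logLik.qlearn_fit <- function(object, ...) {
  structure(object$logLik_pooled, df = 2, nobs = object$n_trials,
            class = "logLik")
}

#' @export
summary.qlearn_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$subjects)) {
    cat("\nPer-subject estimates:\n")
    print(summary(object$subjects[, c("alpha", "beta")]))
  }
  invisible(object)
}

#' Parameter-recovery study for the Q-learning model
#'
#' Simulates `n_reps` independent cohorts of `n_subjects`, each with
#' `trials_per_valence` gain-pair and loss-pair trials at the generative
#' parameters, refits each cohort by maximum likelihood, and averages the
#' pooled estimates across replicates.  This is the package's recovery
#' benchmark: it answers "at the study's design, does the fitting machinery
#' give back the parameters that generated the data?"
#'
#' @param params generative [qlearn_params()].
#' @param n_subjects subjects per replicate cohort (default 200).
#' @param trials_per_valence trials per pair type per subject (default 144;
#'   split over 3 conditions x 2 runs as in the task).
#' @param n_reps replicate cohorts (default 10).
#' @param seed integer seed.
#' @return list with `estimates` (data frame of per-replicate pooled
#'   estimates) and `means` (named vector `alpha_gain`, `beta_gain`,
#'   `alpha_loss`, `beta_loss` averaged over replicates).
#' @export
qlearn_recovery <- function(params = qlearn_params(), n_subjects = 200,
                            trials_per_valence = 144, n_reps = 10,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (trials_per_valence %% 6 != 0) {
    stop("'trials_per_valence' must be divisible by 6 (3 conditions x 2 runs)")
  }
  design <- qlearn_design(trials_per_pair_run = trials_per_valence / 6,
                          pairs = c("gain", "loss"))
  one <- function(r) {
    ch <- simulate_qlearning(params, design, n_subjects)
    fg <- qlearn_fit(ch, "gain", per_subject = FALSE)
    fl <- qlearn_fit(ch, "loss", per_subject = FALSE)
    c(alpha_gain = unname(fg$pooled["alpha"]), beta_gain = unname(fg$pooled["beta"]),
      alpha_loss = unname(fl$pooled["alpha"]), beta_loss = unname(fl$pooled["beta"]))
  }
  est <- as.data.frame(t(vapply(seq_len(n_reps), one, numeric(4))))
  list(estimates = est, means = colMeans(est))
}
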