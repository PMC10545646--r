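# 2AFC psychometric-function fitting and gap-detection thresholds.
#
# The model is a two-parameter logistic with the 2AFC guess rate fixed at
# 0.5 and no lapse term:
#
#     p(x) = 0.5 + 0.5 * plogis(beta0 + beta1 * x)
#
# fitted by maximum likelihood (binomial) on per-gap correct/total counts.
# The gap-detection threshold is the fitted curve's inverse at a target
# proportion correct, by default 0.76 -- the unbiased 2IFC performance at
# d' = 1.  Standard errors come from a nonparametric bootstrap that
# resamples trials with replacement within each gap cell.

#' Unbiased 2IFC proportion correct at a given d'
#'
#' `pnorm(dprime / sqrt(2))`: the percent correct of an unbiased observer
#' in two-interval forced choice.  At d' = 1 this is 0.7602, i.e. the 76%
#' criterion used to define gap-detection thresholds.
#'
#' @param dprime Non-negative discriminability index (vectorised).
#' @return Proportion correct in \[0.5, 1\].
#' @examples
#' pc2afc_from_dprime(1) # 0.7602
#' @export
pc2afc_from_dprime <- function(dprime) {
  if (any(dprime < 0)) stop("`dprime` must be non-negative", call. = FALSE)
  stats::pnorm(dprime / sqrt(2))
}

pf_prob <- function(beta, x) {
  unname(0.5 + 0.5 * stats::plogis(beta[1] + beta[2] * x))
}

# Binomial negative log-likelihood and gradient, numerically stable at
# extreme linear predictors: log p = log 0.5 + log1p(lambda),
# log(1 - p) = log 0.5 + log lambda(-eta).
pf_nll <- function(beta, x, k, n) {
  eta <- beta[1] + beta[2] * x
  lam <- stats::plogis(eta)
  logp <- log(0.5) + log1p(lam)
  logq <- log(0.5) + stats::plogis(-eta, log.p = TRUE)
  -sum(k * logp + (n - k) * logq)
}

pf_gr <- function(beta, x, k, n) {
  eta <- beta[1] + beta[2] * x
  lam <- stats::plogis(eta)
  p <- 0.5 * (1 + lam)
  dp <- 0.5 * lam * (1 - lam)
  common <- -(k / p - (n - k) / (1 - p)) * dp
  c(sum(common), sum(common * x))
}

#' Fit a 2AFC logistic psychometric function
#'
#' Maximum-likelihood fit of `p(x) = 0.5 + 0.5 * plogis(beta0 + beta1 *
#' x)` to per-gap correct/total counts, using BFGS on the binomial
#' log-likelihood with fixed starting values (beta0 = 0, beta1 = 0.1) and
#' relative tolerance 1e-10, so the fit is deterministic for a given
#' input.  Complete or quasi-complete separation (e.g. all-correct data at
#' every level) drives the MLE to infinity; such fits are flagged
#' `converged = FALSE` and yield no threshold.
#'
#' @param data Data frame with columns `gap_ms`, `n_correct`, `n_total`
#'   (one row per gap level; at least 2 distinct levels with nonzero
#'   totals).
#' @param scope Label stored on the fit: `"group"` or `"subject"`.
#' @return Object of class `pf_fit`: list with `coef` (beta0, beta1),
#'   `loglik`, `converged`, `scope`, `data`, `n_trials`.
#' @export
fit_pf_2afc <- function(data, scope = c("group", "subject")) {
  scope <- match.arg(scope)
  stopifnot(all(c("gap_ms", "n_correct", "n_total") %in% names(data)))
  data <- dplyr::summarise(
    dplyr::group_by(data[data$n_total > 0, ], .data$gap_ms),
    n_correct = sum(.data$n_correct), n_total = sum(.data$n_total),
    .groups = "drop"
  )
  data <- dplyr::arrange(data, .data$gap_ms)
  if (nrow(data) < 2) {
    stop("psychometric fit requires at least 2 gap levels", call. = FALSE)
  }
  if (any(data$n_correct > data$n_total) || any(data$n_correct < 0)) {
    stop("`n_correct` must lie in [0, n_total]", call. = FALSE)
  }
  # Two deterministic starts.  The fixed start (0, 0.1) can land on the
  # likelihood plateau where the curve hugs the 0.5 guess rate for every
  # gap (the 2AFC likelihood is not concave), so a second, data-driven
  # start is derived from the empirical logit of 2*p_hat - 1; the fit with
  # the better likelihood wins.  Both are deterministic for a given input.
  starts <- list(c(0, 0.1))
  p_hat <- pmin(pmax(2 * data$n_correct / data$n_total - 1, 1e-3), 1 - 1e-3)
  ls <- stats::lm.fit(cbind(1, data$gap_ms), stats::qlogis(p_hat))$coefficients
  if (all(is.finite(ls))) starts <- c(starts, list(unname(ls)))
  runs <- lapply(starts, function(s) {
    stats::optim(
      s, pf_nll, pf_gr,
      x = data$gap_ms, k = data$n_correct, n = data$n_total,
      method = "BFGS", control = list(maxit = 500, reltol = 1e-10)
    )
  })
  opt <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  # separation: with all cells perfect the MLE sits at infinity, and more
  # generally runaway coefficients on these ms scales indicate a boundary
  # maximum rather than an interior one
  separated <- all(data$n_correct == data$n_total) ||
    abs(opt$par[1]) > 30 || abs(opt$par[2]) > 15
  structure(
    list(
      coef = c(beta0 = opt$par[1], beta1 = opt$par[2]),
      loglik = -opt$value,
      converged = opt$convergence == 0 && !separated,
      scope = scope,
      data = data,
      n_trials = sum(data$n_total)
    ),
    class = "pf_fit"
  )
}

#' @export
print.pf_fit <- function(x, ...) {
  cat(sprintf(
    "<pf_fit %s> beta0 = %.4f, beta1 = %.4f, logLik = %.2f, %s (%d trials)\n",
    x$scope, x$coef[1], x$coef[2], x$loglik,
    if (x$converged) "converged" else "NOT converged", x$n_trials
  ))
  invisible(x)
}

#' Predicted proportion correct from a psychometric fit
#'
#' @param fit A [fit_pf_2afc()] object.
#' @param gap_ms Gap durations (ms), vectorised.
#' @return Fitted p(gap), in \[0.5, 1\].
#' @export
predict_pf <- function(fit, gap_ms) {
  stopifnot(inherits(fit, "pf_fit"))
  pf_prob(fit$coef, gap_ms)
}

#' Invert a psychometric fit at a target proportion correct
#'
#' Closed form: `x* = (qlogis(2 * target_pc - 1) - beta0) / beta1`, so
#' that the fitted p(x*) equals `target_pc` exactly.  The default target
#' 0.76 is the unbiased 2IFC percent correct at d' = 1.
#'
#' @param fit A converged [fit_pf_2afc()] with positive slope.
#' @param target_pc Target proportion correct, strictly between 0.5 and 1.
#' @return Threshold gap duration in ms.
#' @examples
#' # beta0 = -2, beta1 = 0.2 gives (log(0.52/0.48) + 2) / 0.2 = 10.4 ms
#' @export
threshold_from_fit <- function(fit, target_pc = 0.76) {
  stopifnot(inherits(fit, "pf_fit"))
  if (target_pc <= 0.5 || target_pc >= 1) {
    stop("`target_pc` must be strictly between 0.5 and 1", call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge; no threshold", call. = FALSE)
  if (fit$coef[2] <= 0) {
    stop("non-positive psychometric slope; no threshold", call. = FALSE)
  }
  unname((stats::qlogis(2 * target_pc - 1) - fit$coef[1]) / fit$coef[2])
}

#' Bootstrap standard error of a gap-detection threshold
#'
#' Resamples trials with replacement within each gap cell (equivalently,
#' redraws each cell's correct count from Binomial(n, k/n)), refits the
#' psychometric function, and re-inverts it at `target_pc`.  Resamples
#' whose refit fails to converge are dropped and counted; a warning is
#' attached when they exceed 20%.  With `cluster = "subject"` the
#' resampling unit is the subject instead (requires a `subject_id`
#' column in `trials`).
#'
#' @param trials Trial-level data with columns `gap_ms` and `correct`
#'   (and `subject_id` for the cluster bootstrap), already restricted to
#'   one modality.
#' @param B Number of bootstrap resamples (default 5000).
#' @param target_pc Threshold criterion, as in [threshold_from_fit()].
#' @param cluster `"trial"` (default) or `"subject"`.
#' @param seed Optional integer seed.
#' @return List with `se_ms`, `ci` (2.5% / 97.5% percentiles),
#'   `n_converged`, `n_dropped`, `thresholds` (the bootstrap draws).
#' @export
bootstrap_threshold_se <- function(trials, B = 5000, target_pc = 0.76,
                                   cluster = c("trial", "subject"),
                                   seed = NULL) {
  cluster <- match.arg(cluster)
  if (B < 1) stop("`B` must be a positive integer", call. = FALSE)
  base_counts <- aggregate_gap_counts(trials)
  base_fit <- fit_pf_2afc(base_counts)
  if (!base_fit$converged) {
    stop("base fit did not converge; bootstrap undefined", call. = FALSE)
  }
  thresholds <- maybe_with_seed(seed, {
    vapply(seq_len(B), function(i) {
      counts <- if (cluster == "trial") {
        dplyr::mutate(base_counts, n_correct = stats::rbinom(
          dplyr::n(), .data$n_total, .data$n_correct / .data$n_total
        ))
      } else {
        ids <- unique(trials$subject_id)
        take <- sample(ids, length(ids), replace = TRUE)
        resampled <- purrr::map_dfr(take, ~ trials[trials$subject_id == .x, ])
        aggregate_gap_counts(resampled)
      }
      fit <- fit_pf_2afc(counts)
      if (fit$converged && fit$coef[2] > 0) {
        threshold_from_fit(fit, target_pc)
      } else {
        NA_real_
      }
    }, numeric(1))
  })
  ok <- thresholds[!is.na(thresholds)]
  out <- list(
    se_ms = stats::sd(ok),
    ci = stats::quantile(ok, c(0.025, 0.975), names = FALSE),
    n_converged = length(ok),
    n_dropped = B - length(ok),
    thresholds = thresholds
  )
  if (out$n_dropped > 0.2 * B) {
    warning("more than 20% of bootstrap refits failed to converge",
            call. = FALSE)
  }
  out
}

#' Aggregate trial-level gap data to per-gap counts
#'
#' @param trials Data with columns `gap_ms` and logical `correct`
#'   (no-response rows, `correct = NA`, are dropped).
#' @return Tibble with `gap_ms`, `n_correct`, `n_total`.
#' @export
aggregate_gap_counts <- function(trials) {
  trials <- trials[!is.na(trials$correct), ]
  dplyr::summarise(
    dplyr::group_by(trials, .data$gap_ms),
    n_correct = sum(.data$correct), n_total = dplyr::n(),
    .groups = "drop"
  )
}

#' Group-level gap-detection thresholds per modality
#'
#' The full experiment-2 analysis path: drops no-response trials, pools
#' trials over subjects within each modality, fits the 2AFC logistic,
#' inverts it at `target_pc`, and (optionally) attaches bootstrap SEs and
#' percentile CIs.
#'
#' @param trials An experiment-2 trial table.
#' @param target_pc Threshold criterion (default 0.76, d' = 1).
#' @param B Bootstrap resamples per modality; 0 skips the bootstrap.
#' @param seed Optional integer seed for the bootstrap.
#' @return Tibble, one row per modality: `beta0`, `beta1`,
#'   `threshold_ms`, `se_ms`, `ci_lo`, `ci_hi`, `converged`, `n_trials`.
#' @export
fit_gap_thresholds <- function(trials, target_pc = 0.76, B = 5000,
                               seed = NULL) {
  trials <- apply_exclusions(trials, experiment = 2)$trials
  purrr::map_dfr(sort(unique(trials$modality)), function(m) {
    sub <- trials[trials$modality == m, ]
    fit <- fit_pf_2afc(aggregate_gap_counts(sub))
    thr <- if (fit$converged && fit$coef[2] > 0) {
      threshold_from_fit(fit, target_pc)
    } else {
      NA_real_
    }
    boot <- if (B > 0 && !is.na(thr)) {
      bootstrap_threshold_se(sub, B = B, target_pc = target_pc, seed = seed)
    } else {
      list(se_ms = NA_real_, ci = c(NA_real_, NA_real_))
    }
    tibble::tibble(
      modality = m,
      beta0 = unname(fit$coef[1]), beta1 = unname(fit$coef[2]),
      threshold_ms = thr, se_ms = boot$se_ms,
      ci_lo = boot$ci[1], ci_hi = boot$ci[2],
      converged = fit$converged, n_trials = fit$n_trials
    )
  })
}

#' Per-subject psychometric fits and mean accuracies
#'
#' Independent maximum-likelihood fits per subject x modality (subjects
#' with fewer than 2 usable gap levels are flagged and skipped), plus each
#' subject's mean accuracy pooled over all gap levels per modality -- the
#' summaries consumed by the unimodal-bimodal correlation analysis.
#'
#' @param trials An experiment-2 trial table.
#' @param target_pc Threshold criterion for the subject-level thresholds.
#' @return List with `fits` (tibble: subject, modality, beta0, beta1,
#'   threshold_ms, converged, n_trials, skipped) and `accuracy` (tibble:
#'   subject, modality, accuracy as proportion correct).
#' @export
fit_subject_pfs <- function(trials, target_pc = 0.76) {
  trials <- apply_exclusions(trials, experiment = 2)$trials
  groups <- dplyr::distinct(trials, .data$subject_id, .data$modality)
  fits <- purrr::pmap_dfr(groups, function(subject_id, modality) {
    sub <- trials[trials$subject_id == subject_id &
                    trials$modality == modality, ]
    counts <- aggregate_gap_counts(sub)
    if (nrow(counts) < 2) {
      return(tibble::tibble(
        subject_id = subject_id, modality = modality,
        beta0 = NA_real_, beta1 = NA_real_, threshold_ms = NA_real_,
        converged = FALSE, n_trials = sum(counts$n_total), skipped = TRUE
      ))
    }
    fit <- fit_pf_2afc(counts, scope = "subject")
    thr <- if (fit$converged && fit$coef[2] > 0) {
      threshold_from_fit(fit, target_pc)
    } else {
      NA_real_
    }
    tibble::tibble(
      subject_id = subject_id, modality = modality,
      beta0 = unname(fit$coef[1]), beta1 = unname(fit$coef[2]),
      threshold_ms = thr, converged = fit$converged,
      n_trials = fit$n_trials, skipped = FALSE
    )
  })
  accuracy <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject_id, .data$modality),
    accuracy = mean(.data$correct), .groups = "drop"
  )
  list(fits = fits, accuracy = accuracy)
}
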