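# Repeated-measures inference on the subject-level summaries: tests of the
# decision criterion against neutrality, simple effects of modality,
# within-subject error bars, and the unimodal-bimodal accuracy relation.

# one-sample t machinery tolerant of degenerate (zero-variance) input
one_sample_t <- function(x, mu, conf.level) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) {
    # all observations identical: flag rather than error
    p <- if (isTRUE(all.equal(m, mu))) 1 else 0
    return(list(mean = m, p = p, ci = c(m, m), degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = mu, conf.level = conf.level)
  list(mean = m, p = unname(tt$p.value),
       ci = unname(tt$conf.int), degenerate = FALSE)
}

#' Test the decision criterion against neutrality in each condition
#'
#' One-sample t-tests of H0: b = 1, one per condition, with Bonferroni
#' adjustment over the family of conditions: p-values are multiplied by
#' the number of conditions (capped at 1) and confidence intervals widened
#' to level `1 - alpha / m`.
#'
#' @param estimates Subject-level estimates, e.g. from [estimate_sdt()]:
#'   columns `subject_id`, `modality`, `noise_level`, `b`.
#' @param alpha Familywise error rate (default 0.05).
#' @return Tibble, one row per modality x noise condition: `mean_b`,
#'   `ci_lo`, `ci_hi` (Bonferroni-adjusted), `p_raw`, `p_adj`, `n`,
#'   `degenerate`.
#' @export
test_bias_neutral <- function(estimates, alpha = 0.05) {
  conds <- dplyr::distinct(estimates, .data$modality, .data$noise_level)
  m <- nrow(conds)
  if (m < 1) stop("no conditions found", call. = FALSE)
  purrr::pmap_dfr(conds, function(modality, noise_level) {
    b <- estimates$b[estimates$modality == modality &
                       estimates$noise_level == noise_level]
    if (length(b) < 2) {
      stop("criterion test requires at least 2 subjects per condition",
           call. = FALSE)
    }
    res <- one_sample_t(b, mu = 1, conf.level = 1 - alpha / m)
    tibble::tibble(
      modality = modality, noise_level = noise_level,
      mean_b = res$mean, ci_lo = res$ci[1], ci_hi = res$ci[2],
      p_raw = res$p, p_adj = min(1, res$p * m),
      n = length(b), degenerate = res$degenerate
    )
  })
}

#' Simple effect of modality at each noise level
#'
#' Paired t-tests of the tactile-minus-visual difference in a
#' subject-level measure (by default sensitivity A), one per noise level.
#' P-values are reported unadjusted.
#'
#' @param estimates Subject-level estimates with columns `subject_id`,
#'   `modality` (V and T), `noise_level` and the measure column.
#' @param measure Name of the column to compare (default `"A"`).
#' @return Tibble per noise level: `mean_diff` (T - V), `ci_lo`, `ci_hi`,
#'   `p`, `n`, `degenerate`.
#' @export
simple_effect_modality <- function(estimates, measure = "A") {
  wide <- tidyr::pivot_wider(
    estimates[, c("subject_id", "modality", "noise_level", measure)],
    names_from = "modality", values_from = dplyr::all_of(measure)
  )
  if (!all(c("V", "T") %in% names(wide)) || anyNA(wide$V) || anyNA(wide$T)) {
    stop("paired data required: both modalities for every subject x noise",
         call. = FALSE)
  }
  purrr::map_dfr(sort(unique(wide$noise_level)), function(lev) {
    d <- wide$T[wide$noise_level == lev] - wide$V[wide$noise_level == lev]
    res <- one_sample_t(d, mu = 0, conf.level = 0.95)
    tibble::tibble(
      noise_level = lev, mean_diff = res$mean,
      ci_lo = res$ci[1], ci_hi = res$ci[2], p = res$p,
      n = length(d), degenerate = res$degenerate
    )
  })
}

#' Within-subject standard error per condition
#'
#' Cousineau subject-centering (subtract each subject's mean, add the
#' grand mean) followed by Morey's bias correction `sqrt(C / (C - 1))`,
#' where C is the number of conditions; the per-condition SE of the
#' centered data is the repeated-measures error bar.
#'
#' @param data Long data with columns `subject_id`, `condition`, `value`;
#'   every subject must have every condition exactly once.
#' @return Tibble per condition: `mean`, `wsse`, `n`.
#' @export
within_subject_se <- function(data) {
  stopifnot(all(c("subject_id", "condition", "value") %in% names(data)))
  tab <- table(data$subject_id, data$condition)
  if (any(tab != 1)) {
    stop("within-subject SE requires a complete subject x condition matrix",
         call. = FALSE)
  }
  C <- length(unique(data$condition))
  if (C < 2) {
    stop("within-subject SE is undefined with a single condition",
         call. = FALSE)
  }
  grand <- mean(data$value)
  centered <- dplyr::mutate(
    dplyr::group_by(data, .data$subject_id),
    centered = .data$value - mean(.data$value) + grand
  )
  morey <- sqrt(C / (C - 1))
  dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(centered), .data$condition),
    mean = mean(.data$value),
    wsse = stats::sd(.data$centered) * morey / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Relate unimodal to bimodal accuracy across subjects
#'
#' Pearson correlation (reported as R^2 with its test) between a unimodal
#' condition's subject accuracies and the bimodal condition's, plus the
#' ordinary least-squares slope of bimodal on unimodal accuracy with a
#' t-test of H0: slope = 1 -- the value expected under complete unimodal
#' cue dominance.
#'
#' @param unimodal,bimodal Numeric vectors of per-subject mean accuracy,
#'   same subject order, length >= 3.
#' @return List: `r`, `r_squared`, `p_cor`, `slope`, `slope_se`,
#'   `p_slope_vs_1`, `intercept`, `n`, `degenerate`.
#' @export
unimodal_bimodal_relation <- function(unimodal, bimodal) {
  n <- length(unimodal)
  if (n != length(bimodal) || n < 3) {
    stop("need >= 3 paired subject accuracies", call. = FALSE)
  }
  if (stats::sd(unimodal) == 0) {
    stop("zero variance in unimodal accuracies; correlation undefined",
         call. = FALSE)
  }
  fit <- stats::lm(bimodal ~ unimodal)
  slope <- unname(stats::coef(fit)[2])
  # exact linear data trip base R's perfect-fit warning; the degenerate
  # flag below reports that case explicitly
  slope_se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2]))
  degenerate <- slope_se < 1e-12
  if (degenerate) {
    p_slope <- if (isTRUE(all.equal(slope, 1))) 1 else 0
    r <- sign(slope)
    p_cor <- 0
  } else {
    p_slope <- 2 * stats::pt(-abs((slope - 1) / slope_se), df = n - 2)
    ct <- stats::cor.test(unimodal, bimodal)
    r <- unname(ct$estimate)
    p_cor <- unname(ct$p.value)
  }
  list(
    r = r, r_squared = r^2, p_cor = p_cor,
    slope = slope, slope_se = slope_se, p_slope_vs_1 = p_slope,
    intercept = unname(stats::coef(fit)[1]), n = n,
    degenerate = degenerate
  )
}
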