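#' Exact binomial upper-tail probability
#'
#' Probability of observing at least `k` successes out of `n` under success
#' probability `p0`, by direct summation of the binomial probability mass
#' function. Used to compare the prevalence of a modal inferred goal against
#' the chance level 1/4.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @return `P(X >= k)` for `X ~ Binomial(n, p0)`.
#' @examples
#' binom_tail(10, 13, 0.25)
#' @export
binom_tail <- function(k, n, p0) {
  if (length(k) != 1L || length(n) != 1L || k < 0 || k > n || n < 1) {
    abort("`k` must satisfy 0 <= k <= n with n >= 1.")
  }
  if (p0 <= 0 || p0 >= 1) abort("`p0` must lie strictly in (0, 1).")
  if (k == 0) return(1)
  sum(dbinom(seq.int(k, n), n, p0))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subjects decomposition for an `n` subjects by `k`
#' conditions table, with the Greenhouse-Geisser sphericity correction
#' epsilon estimated from the sample covariance of the conditions and applied
#' to both degrees of freedom. Both partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`, the default) and classical eta
#' squared are reported.
#'
#' @param data Numeric matrix or data frame, subjects in rows, conditions in
#'   columns (`n >= 2`, `k >= 2`, no missing cells).
#' @param gg Apply the Greenhouse-Geisser correction. `"always"` (default)
#'   corrects whenever `k > 2`; `"mauchly"` corrects only when Mauchly's
#'   sphericity test rejects at 0.05; `"never"` reports uncorrected df.
#' @return A list of class `rm_anova`: `F`, `df1`, `df2` (corrected, possibly
#'   non-integer), `epsilon_gg`, `p`, `eta_sq` (partial), `eta_sq_classical`,
#'   and the uncorrected df.
#' @export
rm_anova_gg <- function(data, gg = c("always", "mauchly", "never")) {
  gg <- match.arg(gg)
  Y <- as.matrix(data)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L || k < 2L) abort("Need at least 2 subjects and 2 conditions.")
  if (anyNA(Y)) abort("Missing cells are not supported.")
  grand <- mean(Y)
  cond_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  tol0 <- 1e-12 * max(1, ss_total)
  if (ss_total <= tol0) abort("Constant data: F is undefined.")
  if (ss_cond <= tol0 && ss_err <= tol0) {
    # identical condition profiles within every subject: no effect, no error
    return(structure(list(
      F = 0, df1 = df1, df2 = df2, df1_uncorrected = df1, df2_uncorrected = df2,
      epsilon_gg = 1, p = 1, eta_sq = 0, eta_sq_classical = 0, n = n, k = k
    ), class = "rm_anova"))
  }
  f_stat <- (ss_cond / df1) / (ss_err / df2)

  # Greenhouse-Geisser epsilon from the double-centered condition covariance.
  S <- cov(Y)
  Sd <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))
  eps <- min(1, max(eps, 1 / (k - 1)))

  apply_gg <- switch(gg,
    always = k > 2,
    mauchly = k > 2 && mauchly_p(Y) < 0.05,
    never = FALSE
  )
  eff_eps <- if (apply_gg) eps else 1
  structure(list(
    F = f_stat,
    df1 = df1 * eff_eps, df2 = df2 * eff_eps,
    df1_uncorrected = df1, df2_uncorrected = df2,
    epsilon_gg = eps,
    p = pf(f_stat, df1 * eff_eps, df2 * eff_eps, lower.tail = FALSE),
    eta_sq = ss_cond / (ss_cond + ss_err),
    eta_sq_classical = ss_cond / ss_total,
    n = n, k = k
  ), class = "rm_anova")
}

# Mauchly's sphericity test on the orthonormal-contrast covariance.
mauchly_p <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))
  S <- t(C) %*% cov(Y) %*% C
  p <- k - 1
  W <- det(S) / (sum(diag(S)) / p)^p
  if (W <= 0) return(0)
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chi <- -(n - 1) * d * log(W)
  stats::pchisq(chi, p * (p + 1) / 2 - 1, lower.tail = FALSE)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%.2f, %.2f) = %.2f, p = %.4g, eta_sq(partial) = %.2f (GG epsilon = %.3f)\n",
              x$df1, x$df2, x$F, x$p, x$eta_sq, x$epsilon_gg))
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(F = x$F, df1 = x$df1, df2 = x$df2, p = x$p,
                 epsilon_gg = x$epsilon_gg, eta_sq = x$eta_sq,
                 eta_sq_classical = x$eta_sq_classical)
}

#' Paired two-tailed t-test
#'
#' @param x,y Equal-length paired samples (length >= 3, nonzero difference
#'   variance).
#' @return Tibble with `statistic`, `df`, `p_two_tailed`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must be paired samples of equal length >= 3.")
  }
  if (sd(x - y) == 0) {
    if (mean(x - y) != 0) abort("Zero variance of nonzero differences: t is undefined.")
    return(tibble::tibble(statistic = 0, df = length(x) - 1, p_two_tailed = 1))
  }
  res <- t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(res$statistic), df = unname(res$parameter),
                 p_two_tailed = res$p.value)
}

#' Pearson correlation with a two-tailed test
#'
#' @param x,y Equal-length samples (length >= 3, nonzero variance).
#' @return Tibble with `estimate` (r), `statistic` (t), `df`, `p_two_tailed`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance: r is undefined.")
  res <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(res$estimate),
                 statistic = unname(res$statistic),
                 df = unname(res$parameter), p_two_tailed = res$p.value)
}

#' Statistical summary of a cohort goal inference
#'
#' Mirrors the study's reporting for one agent role: a repeated-measures
#' ANOVA (with Greenhouse-Geisser correction) of the per-dyad posterior
#' probabilities across the four goals, paired two-tailed t-tests of the
#' modal goal against each other goal, and the exact binomial tail of the
#' modal goal's prevalence against chance 0.25.
#'
#' @param cohort A [infer_cohort()] result.
#' @return List with `anova` (class `rm_anova`), `pairwise` (tibble), and
#'   `binomial` (tibble from [glance.goal_cohort()]).
#' @export
cohort_stats <- function(cohort) {
  P <- as.matrix(tibble::as_tibble(cohort)[, paste0("p_", goal_levels())])
  an <- rm_anova_gg(P)
  modal <- glance(cohort)$modal_goal
  others <- setdiff(goal_levels(), modal)
  pairwise <- purrr::map_dfr(others, function(g) {
    tt <- paired_t(P[, paste0("p_", modal)], P[, paste0("p_", g)])
    dplyr::mutate(tt, comparison = sprintf("%s vs %s", modal, g), .before = 1)
  })
  list(anova = an, pairwise = pairwise, binomial = glance(cohort))
}

#' Statistical summary of a controller-versus-adult experiment
#'
#' Mirrors the study's reporting: the correlation between mutual-smiling
#' seconds and the positivity proxy across all sessions, a repeated-measures
#' ANOVA of participant-only smiling seconds across the four controllers,
#' and paired t-tests of the infant controller against each alternative.
#'
#' @param experiment A [run_experiment()] tibble.
#' @return List with `positivity_r` (tibble), `anova` (class `rm_anova`) and
#'   `pairwise` (tibble).
#' @export
experiment_stats <- function(experiment) {
  wide <- experiment |>
    dplyr::select("participant", "condition", "participant_only_s") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "participant_only_s") |>
    dplyr::arrange(.data$participant)
  conds <- c("infant", "replay", "mirror", "infant_plus")
  M <- as.matrix(wide[, conds])
  pairwise <- purrr::map_dfr(setdiff(conds, "infant"), function(cond) {
    tt <- paired_t(M[, "infant"], M[, cond])
    dplyr::mutate(tt, comparison = sprintf("infant vs %s", cond), .before = 1)
  })
  list(
    positivity_r = pearson_r(experiment$both_s, experiment$positivity),
    anova = rm_anova_gg(M),
    pairwise = pairwise
  )
}
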