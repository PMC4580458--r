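#' Noisy-rationality configuration for goal inference
#'
#' The bridge between an optimal plan and observed behaviour is a
#' noisy-rationality likelihood: under the default Boltzmann (softmax) model
#' an agent pursuing goal g picks action u in state s with probability
#' proportional to `exp(beta * Q_g(s, u))`. The rationality temperature
#' `beta` is unknown and is marginalised over a shared grid (uniform prior on
#' the grid). An epsilon-greedy alternative is provided for sensitivity
#' analysis.
#'
#' @param model `"softmax"` (default) or `"epsilon_greedy"`.
#' @param beta_grid Positive inverse-temperature grid; default 16 log-spaced
#'   points on `[0.1, 100]`.
#' @param epsilon_grid Slip-probability grid for the epsilon-greedy model.
#' @param goal_prior Prior over the four goals in canonical order
#'   (neither, infant_only, mother_only, mutual); default uniform 0.25.
#' @return A list of class `rationality_config`.
#' @export
rationality_config <- function(model = c("softmax", "epsilon_greedy"),
                               beta_grid = exp(seq(log(0.1), log(100), length.out = 16)),
                               epsilon_grid = seq(0.05, 0.5, by = 0.05),
                               goal_prior = rep(0.25, 4)) {
  model <- match.arg(model)
  if (length(beta_grid) < 1L || any(beta_grid < 0)) abort("`beta_grid` must be nonempty and >= 0.")
  if (length(epsilon_grid) < 1L) abort("`epsilon_grid` must be nonempty.")
  if (length(goal_prior) != 4L || abs(sum(goal_prior) - 1) > 1e-8 || any(goal_prior < 0)) {
    abort("`goal_prior` must be 4 nonnegative probabilities summing to 1.")
  }
  structure(list(model = model, beta_grid = beta_grid,
                 epsilon_grid = epsilon_grid, goal_prior = goal_prior),
            class = "rationality_config")
}

# Per-transition action values and realized actions along observed episodes.
# tau counters reset at each episode start, matching the fitting convention.
episode_transitions <- function(episodes, plan) {
  m <- plan$mdp
  Qk <- numeric(0); Qt <- numeric(0); act <- integer(0)
  for (e in seq_len(nrow(episodes))) {
    a <- episodes$agent_smile[[e]]
    p <- episodes$partner_smile[[e]]
    len <- length(a)
    if (len < 2L) next
    ta <- tau_sequence(a, m$K_a)
    tp <- tau_sequence(p, m$K)
    idx <- seq_len(len - 1L)
    s <- state_index(a[idx], p[idx], ta[idx], tp[idx], m$K_a, m$K)
    Qk <- c(Qk, plan$Q[s, 1L])
    Qt <- c(Qt, plan$Q[s, 2L])
    act <- c(act, ifelse(a[idx + 1L] != a[idx], 2L, 1L))
  }
  list(Qk = Qk, Qt = Qt, act = act)
}

#' Log-likelihood of observed actions under a plan's softmax policy
#'
#' Scores each observed keep/toggle decision with the Boltzmann policy
#' `P(u | s) = exp(beta * Q(s, u)) / sum_u' exp(beta * Q(s, u'))` and sums the
#' log-probabilities over all bin transitions in the episodes.
#'
#' @param episodes Episode tibble ([extract_episodes()]).
#' @param plan A solved [value_iteration()] plan for the hypothesised goal.
#' @param beta Inverse temperature (>= 0); `beta = 0` is the uniform policy.
#' @return Scalar log-likelihood (0 for empty episodes).
#' @export
action_loglik <- function(episodes, plan, beta) {
  tr <- episode_transitions(episodes, plan)
  sum(transition_loglik(tr, beta, model = "softmax"))
}

transition_loglik <- function(tr, par, model) {
  if (length(tr$act) == 0L) return(numeric(0))
  if (model == "softmax") {
    zk <- par * tr$Qk
    zt <- par * tr$Qt
    m <- pmax(zk, zt)
    lse <- m + log(exp(zk - m) + exp(zt - m))
    ifelse(tr$act == 2L, zt, zk) - lse
  } else {
    best <- ifelse(tr$Qt > tr$Qk, 2L, ifelse(tr$Qt < tr$Qk, 1L, 0L))
    p <- ifelse(best == 0L, 0.5, ifelse(tr$act == best, 1 - par, par))
    log(p)
  }
}

#' Posterior over the four dyadic goals for one agent
#'
#' Implements the inverse-optimal-control scoring: for each candidate goal,
#' solve for the optimal plan against the fitted partner model, compute the
#' marginal likelihood of the agent's observed keep/toggle decisions under
#' the noisy-rationality model (rationality parameter marginalised over the
#' config grid in log-space), and combine with the goal prior.
#'
#' @param episodes Episode tibble for the agent under analysis.
#' @param partner Fitted [fit_hazard()] model of the *other* member, from the
#'   same dyad's episodes.
#' @param agent_role `"infant"` or `"mother"`.
#' @param config A [rationality_config()].
#' @param gamma Discount per bin (default 0.98).
#' @param K_a Agent elapsed-time cap (default 10).
#' @param dyad_id Identifier carried into the result.
#' @param plans Optional named list of pre-solved [value_iteration()] plans
#'   (one per goal, named by goal) to avoid re-solving; they must have been
#'   built against `partner`.
#' @return A `goal_posterior` tibble: one row per goal with `goal`,
#'   `log_evidence`, `posterior`; attributes `dyad_id`, `agent_role`,
#'   `map_goal`, `n_transitions`. With no usable episodes the prior is
#'   returned with a warning.
#' @export
goal_posterior <- function(episodes, partner, agent_role = c("infant", "mother"),
                           config = rationality_config(), gamma = 0.98, K_a = 10,
                           dyad_id = NULL, plans = NULL) {
  agent_role <- match.arg(agent_role)
  dyad_id <- dyad_id %||% (if (nrow(episodes) > 0L) episodes$dyad_id[[1]] else NA_character_)
  grid <- if (config$model == "softmax") config$beta_grid else config$epsilon_grid
  n_tr <- 0L
  log_ev <- vapply(goal_levels(), function(goal) {
    plan <- plans[[goal]] %||%
      value_iteration(build_mdp(partner, goal, agent_role, gamma = gamma, K_a = K_a))
    tr <- episode_transitions(episodes, plan)
    n_tr <<- length(tr$act)
    if (n_tr == 0L) return(0)
    log_mean_exp(vapply(grid, function(par) sum(transition_loglik(tr, par, config$model)),
                        numeric(1)))
  }, numeric(1))
  if (n_tr == 0L) {
    warn("No usable episode transitions; returning the goal prior.")
  }
  lp <- unname(log(config$goal_prior) + log_ev)
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  out <- tibble::tibble(goal = goal_levels(), log_evidence = unname(log_ev),
                        posterior = post)
  attr(out, "dyad_id") <- dyad_id
  attr(out, "agent_role") <- agent_role
  attr(out, "map_goal") <- goal_levels()[which.max(post)]
  attr(out, "n_transitions") <- n_tr
  class(out) <- c("goal_posterior", class(out))
  out
}

#' Infer goals for every dyad of a cohort
#'
#' For each dyad: pool that dyad's gaze-gated episodes across sessions, fit
#' the partner's hazard model on them, and compute the goal posterior of the
#' agent. Dyads without usable episodes are excluded with a message.
#'
#' @param sessions Tibble with one row per session: a `dyad_id` column and a
#'   `series` list-column of [smile_series()] objects (the format produced by
#'   [make_cohort()]).
#' @param agent_role `"infant"` or `"mother"`.
#' @param config A [rationality_config()].
#' @param gamma,K,K_a,alpha,min_len_bins Model and gating parameters passed
#'   through to [fit_hazard()], [build_mdp()] and [extract_episodes()].
#' @param gaze_gate Apply gaze gating when extracting episodes (default TRUE
#'   for both roles).
#' @return A `goal_cohort` tibble, one row per dyad: `dyad_id`,
#'   `p_neither, p_infant_only, p_mother_only, p_mutual`, `map_goal`,
#'   `n_transitions`. Summaries: [goal_counts()], [goal_means()],
#'   [glance.goal_cohort()].
#' @export
infer_cohort <- function(sessions, agent_role = c("infant", "mother"),
                         config = rationality_config(), gamma = 0.98,
                         K = 30, K_a = 10, alpha = 1, min_len_bins = 2,
                         gaze_gate = TRUE) {
  agent_role <- match.arg(agent_role)
  partner_name <- if (agent_role == "infant") "mother" else "infant"
  rows <- sessions |>
    dplyr::group_by(.data$dyad_id) |>
    dplyr::group_map(function(df, key) {
      eps <- purrr::map(df$series, extract_episodes, agent = agent_role,
                        min_len_bins = min_len_bins, gaze_gate = gaze_gate) |>
        dplyr::bind_rows()
      if (nrow(eps) == 0L) {
        inform(sprintf("Dyad %s has no usable episodes; excluded.", key$dyad_id))
        return(NULL)
      }
      partner <- fit_hazard(eps, modeled_partner = partner_name, K = K, alpha = alpha)
      post <- goal_posterior(eps, partner, agent_role, config = config,
                             gamma = gamma, K_a = K_a, dyad_id = key$dyad_id)
      tibble::tibble(
        dyad_id = key$dyad_id,
        p_neither = post$posterior[1], p_infant_only = post$posterior[2],
        p_mother_only = post$posterior[3], p_mutual = post$posterior[4],
        map_goal = attr(post, "map_goal"),
        n_transitions = attr(post, "n_transitions")
      )
    }) |>
    dplyr::bind_rows()
  attr(rows, "agent_role") <- agent_role
  class(rows) <- c("goal_cohort", class(rows))
  rows
}

#' Count dyads per most-probable goal
#'
#' @param cohort A [infer_cohort()] result.
#' @return Tibble `goal`, `n` in canonical goal order (zero-filled).
#' @export
goal_counts <- function(cohort) {
  tibble::tibble(goal = goal_levels()) |>
    dplyr::left_join(dplyr::count(tibble::as_tibble(cohort), .data$map_goal),
                     by = c(goal = "map_goal")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Across-dyad mean posterior per goal with a 95% confidence interval
#'
#' @param cohort A [infer_cohort()] result.
#' @return Tibble `goal`, `mean`, `ci_lo`, `ci_hi` (95% CI of the mean across
#'   dyads).
#' @export
goal_means <- function(cohort) {
  tibble::as_tibble(cohort) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("p_", goal_levels())),
                        names_to = "goal", values_to = "p") |>
    dplyr::mutate(goal = sub("^p_", "", .data$goal)) |>
    dplyr::group_by(.data$goal) |>
    dplyr::summarise(
      mean = mean(.data$p),
      ci_lo = mean + qt(0.025, dplyr::n() - 1L) * sd(.data$p) / sqrt(dplyr::n()),
      ci_hi = mean + qt(0.975, dplyr::n() - 1L) * sd(.data$p) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$goal, goal_levels()))
}

#' One-row summary of a cohort inference
#'
#' @param x A `goal_cohort`.
#' @param ... Unused.
#' @return Tibble with the modal goal, its prevalence, and the exact binomial
#'   tail probability of that prevalence against chance 0.25.
#' @export
glance.goal_cohort <- function(x, ...) {
  cnt <- goal_counts(x)
  top <- cnt[which.max(cnt$n), ]
  tibble::tibble(
    n_dyads = nrow(x),
    modal_goal = top$goal,
    n_modal = top$n,
    p_binomial_vs_chance = binom_tail(top$n, nrow(x), 0.25)
  )
}
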