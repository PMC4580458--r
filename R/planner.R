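# Decision problem of the smiling agent: the agent chooses each second to
# keep or toggle its own smile; the partner evolves by the fitted hazard
# model; reward 1 accrues in every bin the dyad occupies the goal
# configuration. States are (a, p, tau_a, tau_p): both smile states plus both
# elapsed times since last toggle.

state_index <- function(a, p, ta, tp, K_a, K) {
  1L + a + 2L * p + 4L * ta + 4L * K_a * tp
}

#' Build the agent's decision problem against a fitted partner model
#'
#' Encodes the smile game as a finite Markov decision process. The agent's
#' action (`keep` or `toggle`) sets its own smile deterministically; the
#' partner toggles with the hazard evaluated at the agent's *pre-action*
#' state, so the agent's move is seen by the partner only from the next bin
#' (one bin of reaction latency). Reward 1 is collected whenever the
#' post-transition configuration matches the goal.
#'
#' @param partner A [fit_hazard()] model of the partner.
#' @param goal One of `"neither"`, `"infant_only"`, `"mother_only"`,
#'   `"mutual"`.
#' @param agent_role `"infant"` or `"mother"` (robot controllers use
#'   `"infant"`).
#' @param gamma Discount factor per bin, in (0, 1). Default 0.98.
#' @param K_a Cap on the agent's own elapsed-time counter (default 10).
#' @return A `smile_mdp` list: state grids, per-state partner hazards,
#'   next-state index vectors for both actions and both partner outcomes, and
#'   the reward vector.
#' @export
build_mdp <- function(partner, goal, agent_role = c("infant", "mother"),
                      gamma = 0.98, K_a = 10) {
  agent_role <- match.arg(agent_role)
  if (gamma <= 0 || gamma >= 1) abort("`gamma` must lie strictly in (0, 1).")
  if (K_a < 1) abort("`K_a` must be >= 1.")
  K_a <- as.integer(K_a)
  K <- partner$K
  grid <- expand.grid(a = 0:1, p = 0:1, ta = seq_len(K_a) - 1L, tp = seq_len(K) - 1L)
  a <- grid$a; p <- grid$p; ta <- grid$ta; tp <- grid$tp
  target <- goal_target(goal, agent_role)
  reward <- as.numeric(a == target[["agent"]] & p == target[["partner"]])
  # Partner hazard at the pre-action joint state.
  q <- partner$h[cbind(p + 1L, a + 1L, tp + 1L)]
  ta_keep <- pmin(ta + 1L, K_a - 1L)
  tp_stay <- pmin(tp + 1L, K - 1L)
  nxt <- function(a2, ta2, p2, tp2) state_index(a2, p2, ta2, tp2, K_a, K)
  structure(list(
    goal = match.arg(goal, goal_levels()), agent_role = agent_role,
    gamma = gamma, K_a = K_a, K = K,
    a = a, p = p, ta = ta, tp = tp,
    reward = reward, q = q,
    nk_stay = nxt(a, ta_keep, p, tp_stay),
    nk_tog  = nxt(a, ta_keep, 1L - p, 0L),
    nt_stay = nxt(1L - a, 0L, p, tp_stay),
    nt_tog  = nxt(1L - a, 0L, 1L - p, 0L)
  ), class = "smile_mdp")
}

q_backup <- function(mdp, V) {
  g <- mdp$gamma
  uk <- mdp$reward[mdp$nk_stay] + g * V[mdp$nk_stay]
  tk <- mdp$reward[mdp$nk_tog] + g * V[mdp$nk_tog]
  ut <- mdp$reward[mdp$nt_stay] + g * V[mdp$nt_stay]
  tt <- mdp$reward[mdp$nt_tog] + g * V[mdp$nt_tog]
  cbind(keep = (1 - mdp$q) * uk + mdp$q * tk,
        toggle = (1 - mdp$q) * ut + mdp$q * tt)
}

#' Solve a smile-game decision problem by value iteration
#'
#' Iterates the Bellman optimality backup to a sup-norm residual below `tol`.
#' Ties between actions break toward `keep`.
#'
#' @param mdp A [build_mdp()] object.
#' @param tol Sup-norm Bellman residual tolerance (default 1e-9).
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual reached.
#' @return A `smile_plan`: the mdp plus `V` (optimal state values), `Q`
#'   (state x action values), `policy` (1 = keep, 2 = toggle), the final
#'   `residual` and the `iterations` used.
#' @export
value_iteration <- function(mdp, tol = 1e-9, max_iter = 1e5) {
  V <- numeric(length(mdp$reward))
  res <- Inf
  it <- 0L
  while (res >= tol) {
    it <- it + 1L
    if (it > max_iter) {
      abort(sprintf("Value iteration failed to converge: residual %.3g after %d iterations.",
                    res, max_iter))
    }
    Q <- q_backup(mdp, V)
    Vn <- pmax(Q[, 1L], Q[, 2L])
    res <- max(abs(Vn - V))
    V <- Vn
  }
  Q <- q_backup(mdp, V)
  structure(list(
    mdp = mdp, goal = mdp$goal, agent_role = mdp$agent_role,
    gamma = mdp$gamma, K_a = mdp$K_a, K = mdp$K,
    V = V, Q = Q, policy = ifelse(Q[, 2L] > Q[, 1L], 2L, 1L),
    residual = res, iterations = it
  ), class = "smile_plan")
}

#' @export
print.smile_plan <- function(x, ...) {
  cat(sprintf("<smile_plan> goal=%s, agent=%s, gamma=%g, %d states, %d iterations (residual %.2g)\n",
              x$goal, x$agent_role, x$gamma, length(x$V), x$iterations, x$residual))
  cat(sprintf("  normalized optimal value from (a=0, p=0, fresh): %.3f\n",
              (1 - x$gamma) * x$V[state_index(0L, 0L, 0L, 0L, x$K_a, x$K)]))
  invisible(x)
}

#' Tidy a solved plan into a per-state table
#'
#' @param x A `smile_plan`.
#' @param ... Unused.
#' @return Tibble with one row per state: `a, p, ta, tp, V, Q_keep, Q_toggle,
#'   action`.
#' @export
tidy.smile_plan <- function(x, ...) {
  m <- x$mdp
  tibble::tibble(
    a = m$a, p = m$p, ta = m$ta, tp = m$tp,
    V = x$V, Q_keep = x$Q[, 1L], Q_toggle = x$Q[, 2L],
    action = c("keep", "toggle")[x$policy]
  )
}

#' @export
glance.smile_plan <- function(x, ...) {
  tibble::tibble(
    goal = x$goal, agent_role = x$agent_role, gamma = x$gamma,
    n_states = length(x$V), iterations = x$iterations, residual = x$residual,
    value_norm_max = (1 - x$gamma) * max(x$V)
  )
}

#' Expected performance of fixed smile wait times
#'
#' From a given context state, evaluates the family of strategies "hold the
#' current smile state for `t` bins, then toggle, and follow the optimal
#' policy thereafter", for `t = 0..t_max`. Performance is the exact expected
#' discounted occupancy of the goal configuration (dynamic programming over
#' partner trajectories, no sampling), normalised by `1/(1 - gamma)` so that
#' 1 means the goal configuration every bin forever.
#'
#' The canonical context is "partner smiling, agent has just stopped
#' smiling": `a = 0, p = 1, tau_a = 0`.
#'
#' @param plan A solved [value_iteration()] plan.
#' @param context Named list/vector with `a`, `p`, `ta`, `tp` (defaults
#'   `a = 0, p = 1, ta = 0, tp = 0`).
#' @param t_max Largest wait time, in bins (>= 0).
#' @return A tibble of class `wait_curve`: `wait_bins`, `performance`, plus
#'   the goal, and attribute `optimal` = normalised optimal value at the
#'   context state.
#' @export
wait_time_performance <- function(plan, context = NULL, t_max = 15) {
  if (t_max < 0) abort("`t_max` must be >= 0.")
  ctx <- resolve_context(plan, context)
  m <- plan$mdp
  g <- m$gamma
  s0 <- state_index(ctx$a, ctx$p, ctx$ta, ctx$tp, m$K_a, m$K)
  W <- plan$Q[, 2L]           # toggle immediately, optimal thereafter
  perf <- numeric(t_max + 1L)
  perf[1L] <- W[s0]
  for (t in seq_len(t_max)) {
    W <- (1 - m$q) * (m$reward[m$nk_stay] + g * W[m$nk_stay]) +
      m$q * (m$reward[m$nk_tog] + g * W[m$nk_tog])
    perf[t + 1L] <- W[s0]
  }
  out <- tibble::tibble(
    wait_bins = 0:t_max,
    performance = (1 - g) * perf,
    goal = plan$goal
  )
  attr(out, "optimal") <- (1 - g) * plan$V[s0]
  attr(out, "context") <- ctx
  class(out) <- c("wait_curve", class(out))
  out
}

resolve_context <- function(plan, context) {
  ctx <- list(a = 0L, p = 1L, ta = 0L, tp = 0L)
  for (nm in names(context)) {
    if (!nm %in% names(ctx)) abort(sprintf("Unknown context field `%s`.", nm))
    ctx[[nm]] <- as.integer(context[[nm]])
  }
  if (ctx$ta >= plan$K_a || ctx$tp >= plan$K || ctx$ta < 0 || ctx$tp < 0) {
    abort("Context elapsed times exceed the plan's caps.")
  }
  ctx
}

#' Empirical distribution of agent wait times in a context
#'
#' Finds every bin at which the agent toggles *into* the context's smile state
#' while the partner is in the context's smile state, and measures how many
#' bins pass until the agent toggles again. Waits censored by the end of an
#' episode are excluded from the distribution but counted.
#'
#' @param episodes Episode tibble from [extract_episodes()].
#' @param context Named vector/list with the entry condition `a` and `p`
#'   (defaults `a = 0, p = 1`).
#' @return Tibble `wait_bins` (1..max observed), `count`, `prob` (sums to 1
#'   over observed waits), with attribute `censored` = number of censored
#'   entries. Empty (with a warning) when the context never occurs.
#' @export
empirical_wait_distribution <- function(episodes, context = c(a = 0, p = 1)) {
  a_ctx <- as.integer(context[["a"]])
  p_ctx <- as.integer(context[["p"]])
  waits <- integer(0)
  censored <- 0L
  for (e in seq_len(nrow(episodes))) {
    a <- episodes$agent_smile[[e]]
    p <- episodes$partner_smile[[e]]
    len <- length(a)
    if (len < 2L) next
    entries <- which(a[-1] == a_ctx & a[-len] != a_ctx & p[-1] == p_ctx) + 1L
    for (i in entries) {
      nxt <- which(a[seq.int(i, len)] != a_ctx)
      if (length(nxt) == 0L) censored <- censored + 1L else waits <- c(waits, nxt[1] - 1L)
    }
  }
  if (length(waits) == 0L) {
    warn("No context entries with observed waits found; returning empty distribution.")
    out <- tibble::tibble(wait_bins = integer(0), count = integer(0), prob = numeric(0))
  } else {
    tabulated <- tabulate(waits, nbins = max(waits))
    out <- tibble::tibble(
      wait_bins = seq_along(tabulated),
      count = tabulated,
      prob = tabulated / sum(tabulated)
    )
  }
  attr(out, "censored") <- censored
  out
}
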