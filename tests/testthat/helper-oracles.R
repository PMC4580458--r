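# Independent oracles used across the test files. None of these reuse the
# package's transition bookkeeping: transitions are re-enumerated from the
# stated rules.

# Enumerate the full decision problem for a 2 x 2 x K hazard array by brute
# force: explicit |S| x |S| transition matrices per action and the reward
# vector, with states ordered exactly as stated (a, p, tau_a, tau_p nested).
oracle_enumerate <- function(h, target_agent, target_partner, K_a, K) {
  ns <- 4 * K_a * K
  idx <- function(a, p, ta, tp) 1 + a + 2 * p + 4 * ta + 4 * K_a * tp
  P_keep <- matrix(0, ns, ns)
  P_tog <- matrix(0, ns, ns)
  reward <- numeric(ns)
  for (a in 0:1) for (p in 0:1) for (ta in 0:(K_a - 1)) for (tp in 0:(K - 1)) {
    s <- idx(a, p, ta, tp)
    reward[s] <- as.numeric(a == target_agent && p == target_partner)
    q <- h[p + 1, a + 1, tp + 1]
    # keep
    a2 <- a; ta2 <- min(ta + 1, K_a - 1)
    P_keep[s, idx(a2, p, ta2, min(tp + 1, K - 1))] <-
      P_keep[s, idx(a2, p, ta2, min(tp + 1, K - 1))] + (1 - q)
    P_keep[s, idx(a2, 1 - p, ta2, 0)] <- P_keep[s, idx(a2, 1 - p, ta2, 0)] + q
    # toggle
    a2 <- 1 - a; ta2 <- 0
    P_tog[s, idx(a2, p, ta2, min(tp + 1, K - 1))] <-
      P_tog[s, idx(a2, p, ta2, min(tp + 1, K - 1))] + (1 - q)
    P_tog[s, idx(a2, 1 - p, ta2, 0)] <- P_tog[s, idx(a2, 1 - p, ta2, 0)] + q
  }
  list(P_keep = P_keep, P_tog = P_tog, reward = reward, ns = ns, idx = idx)
}

# Finite-horizon backward induction on the enumerated problem; converges to
# the discounted infinite-horizon values as the horizon grows.
oracle_backward_induction <- function(or, gamma, horizon) {
  V <- numeric(or$ns)
  for (i in seq_len(horizon)) {
    Qk <- as.numeric(or$P_keep %*% (or$reward + gamma * V))
    Qt <- as.numeric(or$P_tog %*% (or$reward + gamma * V))
    V <- pmax(Qk, Qt)
  }
  list(V = V, Qk = Qk, Qt = Qt)
}

# Monte-Carlo rollout estimate of the fixed-wait strategies' performance:
# keep for `wait` bins, toggle once, then follow the plan's optimal policy.
# Vectorised over rollouts; returns mean normalised return and its standard
# error. Transition sampling re-implements the stated dynamics directly.
oracle_rollout_perf <- function(plan, h, context, wait, n_roll, horizon = 500) {
  K_a <- plan$K_a; K <- plan$K; g <- plan$gamma
  idx <- function(a, p, ta, tp) 1 + a + 2 * p + 4 * ta + 4 * K_a * tp
  target <- goal_target(plan$goal, plan$agent_role)
  a <- rep(context$a, n_roll); p <- rep(context$p, n_roll)
  ta <- rep(context$ta, n_roll); tp <- rep(context$tp, n_roll)
  ret <- numeric(n_roll)
  for (step in 0:(horizon - 1)) {
    act <- if (step < wait) {
      rep(1L, n_roll)
    } else if (step == wait) {
      rep(2L, n_roll)
    } else {
      plan$policy[idx(a, p, ta, tp)]
    }
    tog_a <- act == 2L
    q <- h[cbind(p + 1, a + 1, tp + 1)]
    tog_p <- runif(n_roll) < q
    a2 <- ifelse(tog_a, 1L - a, a)
    ta <- ifelse(tog_a, 0L, pmin(ta + 1L, K_a - 1L))
    p <- ifelse(tog_p, 1L - p, p)
    tp <- ifelse(tog_p, 0L, pmin(tp + 1L, K - 1L))
    a <- a2
    ret <- ret + g^step * as.numeric(a == target[["agent"]] & p == target[["partner"]])
  }
  ret <- (1 - g) * ret
  list(mean = mean(ret), se = sd(ret) / sqrt(n_roll))
}

# A quick deterministic episode tibble from explicit channel vectors.
make_episode <- function(agent, partner, dyad_id = "d1") {
  tibble::tibble(
    dyad_id = dyad_id, session_id = "s1",
    start_bin = 0L, end_bin = length(agent),
    agent_smile = list(as.integer(agent)),
    partner_smile = list(as.integer(partner))
  )
}

# Constant-hazard array of the model's table shape.
const_hazard <- function(value, K = 5) {
  hazard_from_array(array(value, dim = c(2, 2, K)))
}
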