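test_that("the built decision problem matches hand enumeration at K = K_a = 1", {
  set.seed(1)
  h <- array(runif(4, 0, 0.5), dim = c(2, 2, 1))
  partner <- hazard_from_array(h)
  mdp <- build_mdp(partner, "mutual", "infant", gamma = 0.9, K_a = 1)
  or <- oracle_enumerate(h, 1, 1, K_a = 1, K = 1)
  # state space collapses to the 4 smile configurations
  expect_equal(length(mdp$reward), 4L)
  expect_equal(mdp$reward, or$reward)
  # package transition law vs the explicit 4 x 4 matrices
  for (s in 1:4) {
    pk <- numeric(4); pk[mdp$nk_stay[s]] <- pk[mdp$nk_stay[s]] + (1 - mdp$q[s])
    pk[mdp$nk_tog[s]] <- pk[mdp$nk_tog[s]] + mdp$q[s]
    pt <- numeric(4); pt[mdp$nt_stay[s]] <- pt[mdp$nt_stay[s]] + (1 - mdp$q[s])
    pt[mdp$nt_tog[s]] <- pt[mdp$nt_tog[s]] + mdp$q[s]
    expect_equal(pk, or$P_keep[s, ])
    expect_equal(pt, or$P_tog[s, ])
  }

  # frozen partner: partner state is absorbing
  mdp0 <- build_mdp(const_hazard(0, K = 1), "mutual", "infant", K_a = 1)
  expect_equal(mdp0$p[mdp0$nk_stay], mdp0$p)
  expect_true(all(mdp0$q == 0))

  # reward definition for the mutual goal
  mdp <- build_mdp(const_hazard(0.2), "mutual", "infant", K_a = 2)
  expect_true(all(mdp$reward[mdp$a == 1 & mdp$p == 1] == 1))
  expect_true(all(mdp$reward[mdp$a == 1 & mdp$p == 0] == 0))

  expect_error(build_mdp(partner, "mutual", "infant", gamma = 1.2), "gamma")
})

test_that("value iteration solves the Bellman equation", {
  set.seed(2)
  partner <- hazard_from_array(array(runif(8, 0, 0.5), dim = c(2, 2, 2)))
  mdp <- build_mdp(partner, "mother_only", "infant", gamma = 0.95, K_a = 2)

  # reward 1 in every state: V = 1 / (1 - gamma)
  mdp1 <- mdp
  mdp1$reward <- rep(1, length(mdp$reward))
  plan1 <- value_iteration(mdp1)
  expect_equal(plan1$V, rep(1 / (1 - 0.95), length(mdp$reward)), tolerance = 1e-7)

  # V = max_action Q, residual below tolerance, V bounded by 1/(1-gamma)
  plan <- value_iteration(mdp, tol = 1e-10)
  expect_equal(plan$V, pmax(plan$Q[, 1], plan$Q[, 2]))
  expect_lt(plan$residual, 1e-10)
  expect_true(all(plan$V <= 1 / (1 - 0.95) + 1e-9))

  # near-myopic discount reproduces the one-step-lookahead policy
  mdp_my <- build_mdp(partner, "mother_only", "infant", gamma = 0.01, K_a = 2)
  plan_my <- value_iteration(mdp_my)
  r <- mdp_my$reward
  one_step_keep <- (1 - mdp_my$q) * r[mdp_my$nk_stay] + mdp_my$q * r[mdp_my$nk_tog]
  one_step_tog <- (1 - mdp_my$q) * r[mdp_my$nt_stay] + mdp_my$q * r[mdp_my$nt_tog]
  myopic <- ifelse(one_step_tog > one_step_keep, 2L, 1L)
  distinct <- abs(one_step_tog - one_step_keep) > 1e-6
  expect_equal(plan_my$policy[distinct], myopic[distinct])

  # convergence failure is an error naming the residual
  expect_error(value_iteration(mdp, tol = 1e-12, max_iter = 5), "residual")
})

test_that("value iteration matches long-horizon backward induction on random problems", {
  for (seed in 1:3) {
    set.seed(seed)
    gamma <- 0.9
    h <- array(runif(2 * 2 * 3, 0, 0.5), dim = c(2, 2, 3))
    goal <- sample(c("neither", "infant_only", "mother_only", "mutual"), 1)
    partner <- hazard_from_array(h)
    plan <- value_iteration(build_mdp(partner, goal, "infant",
                                      gamma = gamma, K_a = 3))
    tgt <- goal_target(goal, "infant")
    or <- oracle_enumerate(h, tgt[["agent"]], tgt[["partner"]], K_a = 3, K = 3)
    bi <- oracle_backward_induction(or, gamma, horizon = 5000)
    expect_lt(max(abs(plan$V - bi$V)), 1e-6 / (1 - gamma))
  }
})

test_that("relabeling smiles and swapping complementary goals preserves values", {
  set.seed(4)
  h <- array(runif(2 * 2 * 3, 0, 0.5), dim = c(2, 2, 3))
  h_flip <- h
  h_flip[1, 1, ] <- h[2, 2, ]; h_flip[2, 2, ] <- h[1, 1, ]
  h_flip[1, 2, ] <- h[2, 1, ]; h_flip[2, 1, ] <- h[1, 2, ]
  swaps <- c(mutual = "neither", neither = "mutual",
             mother_only = "infant_only", infant_only = "mother_only")
  for (goal in names(swaps)) {
    p1 <- value_iteration(build_mdp(hazard_from_array(h), goal, "infant",
                                    gamma = 0.92, K_a = 3))
    p2 <- value_iteration(build_mdp(hazard_from_array(h_flip), swaps[[goal]],
                                    "infant", gamma = 0.92, K_a = 3))
    # map each state to its relabeled twin (a, p flipped; taus unchanged)
    m <- p1$mdp
    twin <- smilegames:::state_index(1L - m$a, 1L - m$p, m$ta, m$tp, 3L, 3L)
    expect_equal(p1$V, p2$V[twin], tolerance = 1e-7)
  }
})

test_that("wait-time curves have the right endpoints under frozen partners", {
  # partner frozen smiling; infant agent
  frozen <- const_hazard(0, K = 3)
  ctx <- list(a = 0L, p = 1L, ta = 0L, tp = 0L)

  # goal mother-only: any own smile only loses occupancy, so performance
  # rises with the wait and never toggling is best
  plan <- value_iteration(build_mdp(frozen, "mother_only", "infant", K_a = 3))
  perf <- wait_time_performance(plan, ctx, t_max = 8)$performance
  expect_true(all(diff(perf) > 0))
  expect_equal(which.max(perf), 9L) # t = t_max

  # goal mutual: smile immediately
  plan <- value_iteration(build_mdp(frozen, "mutual", "infant", K_a = 3))
  perf <- wait_time_performance(plan, ctx, t_max = 8)$performance
  expect_equal(which.max(perf), 1L) # t = 0

  expect_error(wait_time_performance(plan, ctx, t_max = -1), "t_max")
})

test_that("wait-time curves agree with Monte-Carlo rollouts and are dominated by the optimum", {
  set.seed(6)
  h <- array(runif(2 * 2 * 4, 0.02, 0.4), dim = c(2, 2, 4))
  plan <- value_iteration(build_mdp(hazard_from_array(h), "mother_only",
                                    "infant", gamma = 0.95, K_a = 4))
  ctx <- list(a = 0L, p = 1L, ta = 0L, tp = 0L)
  curve <- wait_time_performance(plan, ctx, t_max = 6)
  for (t in c(0, 2, 5)) {
    mc <- oracle_rollout_perf(plan, h, ctx, wait = t, n_roll = 20000,
                              horizon = 400)
    expect_lt(abs(curve$performance[t + 1] - mc$mean), 3 * mc$se)
  }
  # optimal policy weakly dominates every fixed-wait strategy
  expect_true(all(curve$performance <= attr(curve, "optimal") + 1e-9))
})

test_that("empirical wait distributions count waits from context entries", {
  # agent toggles exactly 1 bin after each entry: point mass at 1
  ep <- make_episode(agent = c(1, 0, 1, 0, 1, 0, 1), partner = rep(1, 7))
  d <- empirical_wait_distribution(ep, context = c(a = 0, p = 1))
  expect_equal(d$wait_bins, 1L)
  expect_equal(d$prob, 1)

  # waits {1, 1, 2, 4} -> probabilities 0.5, 0.25, 0, 0.25 at t = 1..4
  agent <- c(1, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0, 0, 0, 0, 1)
  ep <- make_episode(agent = agent, partner = rep(1, length(agent)))
  d <- empirical_wait_distribution(ep, context = c(a = 0, p = 1))
  expect_equal(d$prob, c(0.5, 0.25, 0, 0.25))
  expect_equal(attr(d, "censored"), 0L)

  # censored wait: agent still in context at the episode end
  ep <- make_episode(agent = c(1, 0, 0), partner = c(1, 1, 1))
  expect_warning(d <- empirical_wait_distribution(ep), "empty")
  expect_equal(attr(d, "censored"), 1L)

  # no context entries at all
  ep <- make_episode(agent = c(0, 0, 0), partner = c(0, 0, 0))
  expect_warning(empirical_wait_distribution(ep), "No context entries")
})
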