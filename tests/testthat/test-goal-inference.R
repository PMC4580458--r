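solved_plans <- function(partner, agent_role = "infant", gamma = 0.98, K_a = 10) {
  plans <- purrr::map(
    purrr::set_names(c("neither", "infant_only", "mother_only", "mutual")),
    ~ value_iteration(build_mdp(partner, .x, agent_role, gamma = gamma, K_a = K_a))
  )
  plans
}

test_that("action log-likelihood scores keep/toggle decisions by softmax(beta * Q)", {
  partner <- const_hazard(0.2, K = 2)
  plan <- value_iteration(build_mdp(partner, "mutual", "infant", gamma = 0.9, K_a = 2))
  ep <- make_episode(agent = c(0, 1, 1, 0), partner = c(0, 0, 1, 1))

  # beta = 0: uniform over two actions for each of the 3 transitions
  expect_equal(action_loglik(ep, plan, beta = 0), -3 * log(2))

  # hand-computed softmax logs against an explicitly set Q table
  plan2 <- plan
  plan2$Q <- matrix(0, nrow = nrow(plan$Q), ncol = 2)
  m <- plan$mdp
  s1 <- smilegames:::state_index(0L, 0L, 0L, 0L, 2L, 2L) # then toggles
  s2 <- smilegames:::state_index(1L, 0L, 0L, 1L, 2L, 2L) # agent fresh, partner held
  s3 <- smilegames:::state_index(1L, 1L, 1L, 0L, 2L, 2L) # then toggles
  plan2$Q[s1, ] <- c(1.0, 2.0)
  plan2$Q[s2, ] <- c(0.5, 0.25)
  plan2$Q[s3, ] <- c(-1.0, 3.0)
  beta <- 1.5
  by_hand <- (beta * 2.0 - log(exp(beta * 1.0) + exp(beta * 2.0))) +
    (beta * 0.5 - log(exp(beta * 0.5) + exp(beta * 0.25))) +
    (beta * 3.0 - log(exp(beta * -1.0) + exp(beta * 3.0)))
  expect_equal(action_loglik(ep, plan2, beta = beta), by_hand)

  # perfectly argmax-consistent actions approach certainty as beta grows
  set.seed(8)
  sims <- simulate_dyad(const_hazard(0.15, K = 30), "mother_only",
                        agent_beta = 1e6,
                        params = generator_params(n_sessions = 2,
                                                  session_len_bins = 150,
                                                  gaze_on_prob = 1))
  eps <- dplyr::bind_rows(purrr::map(sims$series, extract_episodes, agent = "infant"))
  plan_opt <- value_iteration(build_mdp(const_hazard(0.15, K = 30),
                                        "mother_only", "infant"))
  ll_small <- action_loglik(eps, plan_opt, beta = 5)
  ll_big <- action_loglik(eps, plan_opt, beta = 50)
  expect_gt(ll_big, ll_small) # approaches 0 from below as beta grows
  expect_gt(ll_big, -0.2)
  expect_lt(ll_big, 0)
})

test_that("goal posteriors normalise, default to the prior, and recover a planted goal", {
  partner <- make_partner_hazard()
  plans <- solved_plans(partner)

  # no data: prior, with a warning
  empty <- make_episode(integer(0), integer(0))[0, ]
  expect_warning(post <- goal_posterior(empty, partner, "infant", plans = plans),
                 "prior")
  expect_equal(post$posterior, rep(0.25, 4))

  # simulated near-optimal mother_only agent is identified
  set.seed(10)
  sims <- simulate_dyad(partner, "mother_only", agent_beta = 50,
                        params = generator_params(n_sessions = 4,
                                                  session_len_bins = 300,
                                                  gaze_on_prob = 1),
                        plan = plans$mother_only)
  eps <- dplyr::bind_rows(purrr::map(sims$series, extract_episodes, agent = "infant"))
  expect_gt(sum(lengths(eps$agent_smile)), 1000)
  post <- goal_posterior(eps, partner, "infant", plans = plans)
  expect_equal(attr(post, "map_goal"), "mother_only")
  expect_equal(sum(post$posterior), 1, tolerance = 1e-12)
  expect_true(all(post$posterior >= 0))
})

test_that("evidence for the generating goal grows with more data", {
  # sign test across seeded replicates: the posterior for the generating goal
  # on a longer record is at least as often larger than on its prefix
  partner <- make_partner_hazard()
  plans <- solved_plans(partner)
  set.seed(12)
  wins <- 0L; n_rep <- 40L
  for (r in seq_len(n_rep)) {
    sims <- simulate_dyad(partner, "mother_only", agent_beta = 20,
                          params = generator_params(n_sessions = 2,
                                                    session_len_bins = 120,
                                                    gaze_on_prob = 1),
                          plan = plans$mother_only)
    short <- sims[1, ]
    p_short <- goal_posterior(extract_episodes(short$series[[1]], "infant"),
                              partner, "infant", plans = plans)
    eps_long <- dplyr::bind_rows(purrr::map(sims$series, extract_episodes,
                                            agent = "infant"))
    p_long <- goal_posterior(eps_long, partner, "infant", plans = plans)
    if (p_long$posterior[3] >= p_short$posterior[3]) wins <- wins + 1L
  }
  # one-sided binomial sign test against a fair coin
  expect_lt(binom_tail(wins, n_rep, 0.5), 0.01)
})

test_that("cohort inference recovers planted goals and tabulates counts", {
  cohort <- make_cohort(n_dyads = 4,
                        goal_assignment = c("mother_only", "mutual",
                                            "mother_only", "neither"),
                        params = generator_params(n_sessions = 6),
                        seed = 20)
  inferred <- infer_cohort(cohort$sessions, "infant")
  expect_equal(nrow(inferred), 4L)
  expect_equal(inferred$map_goal, cohort$manifest$true_goal)
  cnt <- goal_counts(inferred)
  expect_equal(cnt$goal, c("neither", "infant_only", "mother_only", "mutual"))
  expect_equal(cnt$n, c(1L, 0L, 2L, 1L))
  expect_equal(sum(cnt$n), 4L)
  m <- goal_means(inferred)
  expect_true(all(m$ci_lo <= m$mean & m$mean <= m$ci_hi))
  g <- glance(inferred)
  expect_equal(g$modal_goal, "mother_only")
  expect_equal(g$n_modal, 2L)

  # rows of per-dyad posteriors sum to one
  P <- as.matrix(tibble::as_tibble(inferred)[, paste0("p_", c("neither",
    "infant_only", "mother_only", "mutual"))])
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
})

test_that("epsilon-greedy rationality is available and behaves sanely", {
  partner <- make_partner_hazard()
  plans <- solved_plans(partner)
  set.seed(14)
  sims <- simulate_dyad(partner, "mother_only", agent_beta = 50,
                        params = generator_params(n_sessions = 3,
                                                  gaze_on_prob = 1),
                        plan = plans$mother_only)
  eps <- dplyr::bind_rows(purrr::map(sims$series, extract_episodes, agent = "infant"))
  post <- goal_posterior(eps, partner, "infant",
                         config = rationality_config(model = "epsilon_greedy"),
                         plans = plans)
  expect_equal(attr(post, "map_goal"), "mother_only")
})

test_that("rationality configuration is validated", {
  expect_error(rationality_config(beta_grid = numeric(0)), "beta_grid")
  expect_error(rationality_config(goal_prior = c(0.5, 0.5)), "goal_prior")
  expect_error(rationality_config(goal_prior = c(0.5, 0.3, 0.1, 0.2)), "goal_prior")
})
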