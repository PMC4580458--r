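test_that("hazard fitting matches hand counts and the smoothing formula", {
  # empty data, alpha = 1: pure prior 1/2 everywhere
  m <- fit_hazard(make_episode(integer(0), integer(0))[0, ], K = 5, alpha = 1)
  expect_true(all(m$h == 0.5))

  # partner holds for 10 bins then toggles once (11 bins, 10 transitions):
  # cells tau = 0..8 exposed once with no toggle, tau = 9 exposed with one
  ep <- make_episode(agent = rep(0, 11), partner = c(rep(0, 10), 1))
  m <- fit_hazard(ep, K = 30, alpha = 0)
  expect_equal(sum(m$exposures), 10)
  expect_equal(sum(m$toggles), 1)
  expect_equal(m$toggles[1, 1, 10], 1)   # s_self=0, s_other=0, tau=9
  expect_equal(m$exposures[1, 1, 10], 1)
  expect_equal(m$h[1, 1, 10], 1)
  expect_true(all(m$h[1, 1, 1:9] == 0))

  # partner toggles every bin, alpha = 0: h = 1 in all visited cells
  ep <- make_episode(agent = rep(0, 8), partner = rep(c(0, 1), 4))
  m <- fit_hazard(ep, alpha = 0)
  visited <- m$exposures > 0
  expect_true(all(m$h[visited] == 1))

  # smoothing formula holds entrywise; larger alpha pulls toward 1/2
  ep <- make_episode(agent = rbinom(50, 1, 0.5), partner = rbinom(50, 1, 0.5))
  m1 <- fit_hazard(ep, alpha = 1)
  expect_equal(m1$h, (m1$toggles + 1) / (m1$exposures + 2))
  m5 <- fit_hazard(ep, alpha = 5)
  expect_true(all(abs(m5$h - 0.5) <= abs(m1$h - 0.5) + 1e-12))

  expect_error(fit_hazard(ep, K = 0), "K")
  expect_error(fit_hazard(ep, alpha = -1), "alpha")
})

test_that("the forward sampler realises the table hazards", {
  m0 <- const_hazard(0)
  st <- list(s_self = 1L, tau = 0L)
  for (i in 1:10) st <- step_partner(m0, st$s_self, 0, st$tau)
  expect_equal(st$s_self, 1L)
  expect_equal(st$tau, m0$K - 1L) # saturates at the cap

  m1 <- const_hazard(1)
  st <- list(s_self = 0L, tau = 0L)
  states <- integer(6)
  for (i in 1:6) {
    st <- step_partner(m1, st$s_self, 0, st$tau)
    states[i] <- st$s_self
    expect_equal(st$tau, 0L)
  }
  expect_equal(states, rep(c(1L, 0L), 3))

  # Monte-Carlo toggle frequency vs the binomial CI at h = 0.3
  set.seed(99)
  n <- 1e5
  m3 <- const_hazard(0.3)
  tog <- logical(n)
  for (i in seq_len(n)) tog[i] <- step_partner(m3, 0, 1, 2)$s_self == 1L
  expect_lt(abs(mean(tog) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("log-likelihood sums log-hazards and is maximal at the MLE", {
  # h = 1/2 everywhere: -m log 2 over m transitions
  ep <- make_episode(agent = rbinom(30, 1, 0.5), partner = rbinom(30, 1, 0.5))
  m <- fit_hazard(ep[0, ], alpha = 1) # pure prior
  expect_equal(hazard_loglik(m, ep), -29 * log(2))

  # empty episodes: 0
  expect_equal(hazard_loglik(m, ep[0, ]), 0)

  # alpha = 0 refit on the training data maximises the likelihood over
  # grid perturbations of each visited cell
  set.seed(3)
  ep <- make_episode(agent = rbinom(200, 1, 0.3), partner = rbinom(200, 1, 0.4))
  mle <- fit_hazard(ep, K = 5, alpha = 0)
  ll_mle <- hazard_loglik(mle, ep)
  visited <- which(mle$exposures > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(visited))) {
    for (delta in c(-0.07, 0.07)) {
      h2 <- mle$h
      h2[!is.finite(h2)] <- 0.5 # unvisited cells are undefined at alpha = 0
      v <- h2[visited[r, 1], visited[r, 2], visited[r, 3]] + delta
      if (v < 0 || v > 1) next
      h2[visited[r, 1], visited[r, 2], visited[r, 3]] <- v
      expect_lte(hazard_loglik(hazard_from_array(h2), ep), ll_mle + 1e-12)
    }
  }

  # impossible outcome under a degenerate hazard: -Inf, with a message
  ep_tog <- make_episode(agent = c(0, 0), partner = c(0, 1))
  expect_message(ll <- hazard_loglik(const_hazard(0), ep_tog), "-Inf")
  expect_identical(ll, -Inf)
})

test_that("fitting recovers a known generating hazard model", {
  # simulate a long single episode from a known table with a randomly
  # toggling other-channel, then refit without smoothing
  set.seed(21)
  truth <- make_partner_hazard(generator_params(), K = 10)
  n <- 50000
  x <- integer(n); y <- integer(n)
  xi <- 0L; yi <- 0L; tau <- 0L
  for (i in seq_len(n)) {
    x[i] <- xi; y[i] <- yi
    if (runif(1) < truth$h[yi + 1, xi + 1, tau + 1]) {
      yi <- 1L - yi; tau <- 0L
    } else {
      tau <- min(tau + 1L, truth$K - 1L)
    }
    if (runif(1) < 0.25) xi <- 1L - xi
  }
  fit <- fit_hazard(make_episode(x, y), K = 10, alpha = 0)
  well_exposed <- fit$exposures >= 500
  expect_gt(sum(well_exposed), 10)
  expect_lt(max(abs(fit$h[well_exposed] - truth$h[well_exposed])), 0.05)
})

test_that("a responsive-partner fit shows responsivity and duration-dependent cessation", {
  # random (beta = 0) agent, so both joint smile states are well visited
  set.seed(5)
  truth <- make_partner_hazard()
  sims <- simulate_dyad(truth, agent_beta = 0,
                        params = generator_params(n_sessions = 10,
                                                  session_len_bins = 500,
                                                  gaze_on_prob = 1))
  eps <- dplyr::bind_rows(purrr::map(sims$series, extract_episodes, agent = "infant"))
  fit <- fit_hazard(eps, K = 15, alpha = 1)
  # pooled onset hazard is higher while the agent smiles
  pooled <- function(ss, so) sum(fit$toggles[ss, so, ]) / sum(fit$exposures[ss, so, ])
  expect_gt(pooled(1, 2), pooled(1, 1))
  # offset hazard while smiling alone trends upward in elapsed time
  off <- which(fit$exposures[2, 1, ] >= 30)
  expect_gt(length(off), 2)
  expect_gt(stats::cor(off, fit$h[2, 1, off]), 0)
})

test_that("hazard model serialization round-trips", {
  set.seed(13)
  ep <- make_episode(agent = rbinom(100, 1, 0.4), partner = rbinom(100, 1, 0.4))
  m <- fit_hazard(ep, K = 7, alpha = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hazard_csv(m, path)
  m2 <- read_hazard_csv(path)
  expect_equal(m2$h, m$h)
  expect_equal(m2$toggles, m$toggles)
  expect_equal(m2$exposures, m$exposures)
  expect_equal(m2$K, 7L)
  expect_equal(m2$alpha, 0.5)
  expect_equal(m2$modeled_partner, "mother")
})
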