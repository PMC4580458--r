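# Software-only counterpart of the controller-versus-adult smile study: four
# smile-timing controllers interact with a simulated adult (a hazard-model
# plant of the same family as the mother model), and each session's occupancy
# of the four smile configurations is measured.

#' Construct a smile controller
#'
#' Four controller kinds: `infant` acts by the optimal policy inferred for
#' the infant goal (argmax by default, Boltzmann if `beta` is given);
#' `replay` plays back a fixed smile trace with no contingency on the
#' partner; `mirror` copies the participant's smile state
#' `mirror_delay_bins` ago; `infant_plus` takes the infant action and then,
#' with probability `match_prob` per bin, overwrites it with the
#' participant's current state.
#'
#' @param kind One of `"infant"`, `"replay"`, `"mirror"`, `"infant_plus"`.
#' @param plan A solved [value_iteration()] plan (required for `infant` and
#'   `infant_plus`).
#' @param replay_trace 0/1 vector at least as long as the session (required
#'   for `replay`).
#' @param match_prob Per-bin matching probability for `infant_plus`
#'   (default 0.5).
#' @param mirror_delay_bins Mirror latency in bins (default 1).
#' @param beta Optional acting temperature for the `infant`/`infant_plus`
#'   policy; `NULL` (default) means deterministic argmax.
#' @return A list of class `smile_controller`.
#' @export
smile_controller <- function(kind = c("infant", "replay", "mirror", "infant_plus"),
                             plan = NULL, replay_trace = NULL,
                             match_prob = 0.5, mirror_delay_bins = 1,
                             beta = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("infant", "infant_plus") && !inherits(plan, "smile_plan")) {
    abort(sprintf("Controller `%s` requires a solved plan.", kind))
  }
  if (kind == "replay" && is.null(replay_trace)) {
    abort("Controller `replay` requires a replay trace.")
  }
  check_scalar_prob(match_prob, "match_prob")
  structure(list(kind = kind, plan = plan, replay_trace = replay_trace,
                 match_prob = match_prob,
                 mirror_delay_bins = as.integer(mirror_delay_bins),
                 beta = beta),
            class = "smile_controller")
}

policy_action <- function(plan, s, beta) {
  if (is.null(beta)) return(plan$policy[s])
  zk <- beta * plan$Q[s, 1L]; zt <- beta * plan$Q[s, 2L]
  m <- max(zk, zt)
  if (runif(1) < exp(zt - m) / (exp(zk - m) + exp(zt - m))) 2L else 1L
}

#' Run one controller-versus-adult smile session
#'
#' Per-bin loop: the adult (a [fit_hazard()]-family plant) toggles with the
#' hazard evaluated at the controller's pre-action smile state; the
#' controller then emits its next smile state per its kind; the
#' post-update configuration is tallied. Both members start not smiling.
#'
#' @param controller A [smile_controller()].
#' @param adult A `hazard_model` of the adult participant.
#' @param duration_s Session length in seconds (default 180; 1-s bins).
#' @return A list of class `session_result`: `kind`, `duration_s`,
#'   `occupancy` (named seconds in `both`, `robot_only`, `participant_only`,
#'   `neither`; sums to `duration_s`), `robot_trace`, `participant_trace`.
#' @export
run_session <- function(controller, adult, duration_s = 180) {
  n <- as.integer(duration_s)
  if (controller$kind == "replay" && length(controller$replay_trace) < n) {
    abort("Replay trace is shorter than the session.")
  }
  plan <- controller$plan
  r <- integer(n); u <- integer(n)
  tr <- 0L; tu <- 0L
  for (t in seq_len(n - 1L)) {
    # adult reacts to the robot's pre-action state
    p_tog <- adult$h[u[t] + 1L, r[t] + 1L, tu + 1L]
    if (runif(1) < p_tog) {
      u[t + 1L] <- 1L - u[t]; tu <- 0L
    } else {
      u[t + 1L] <- u[t]; tu <- min(tu + 1L, adult$K - 1L)
    }
    r_next <- switch(controller$kind,
      infant = {
        s <- state_index(r[t], u[t], tr, min(tu, plan$K - 1L), plan$K_a, plan$K)
        if (policy_action(plan, s, controller$beta) == 2L) 1L - r[t] else r[t]
      },
      replay = as.integer(controller$replay_trace[t + 1L]),
      mirror = {
        src <- t + 1L - controller$mirror_delay_bins
        if (src >= 1L) u[src] else 0L
      },
      infant_plus = {
        s <- state_index(r[t], u[t], tr, min(tu, plan$K - 1L), plan$K_a, plan$K)
        act <- if (policy_action(plan, s, controller$beta) == 2L) 1L - r[t] else r[t]
        if (runif(1) < controller$match_prob) u[t + 1L] else act
      }
    )
    tr <- if (r_next != r[t]) 0L else tr + 1L
    if (!is.null(plan)) tr <- min(tr, plan$K_a - 1L)
    r[t + 1L] <- r_next
  }
  occupancy <- c(
    both = sum(r == 1L & u == 1L),
    robot_only = sum(r == 1L & u == 0L),
    participant_only = sum(r == 0L & u == 1L),
    neither = sum(r == 0L & u == 0L)
  )
  structure(list(kind = controller$kind, duration_s = n,
                 occupancy = occupancy, robot_trace = r, participant_trace = u),
            class = "session_result")
}

#' Positivity-rating proxy for one session
#'
#' Stands in for the questionnaire's summed positivity score: a linear
#' function of the seconds of simultaneous smiling plus Gaussian noise, so
#' simulated experiments reproduce the correlation structure between mutual
#' smiling and rated positivity. It makes no claim about questionnaire
#' content.
#'
#' @param session A [run_session()] result.
#' @param weight Seconds-of-mutual-smiling weight (default 1).
#' @param noise_sd Noise standard deviation in score units (default 40).
#' @return A scalar score.
#' @export
positivity_proxy <- function(session, weight = 1, noise_sd = 40) {
  weight * unname(session$occupancy[["both"]]) + rnorm(1, 0, noise_sd)
}

# Williams 4x4 Latin square: each condition appears once per row and column
# and each condition precedes every other equally often.
latin_square_order <- function() {
  matrix(c(1, 2, 4, 3,
           2, 3, 1, 4,
           3, 4, 2, 1,
           4, 1, 3, 2), nrow = 4, byrow = TRUE)
}

#' Run a full counterbalanced controller-versus-adult experiment
#'
#' Each participant completes four 3-minute sessions, one per controller, in
#' a Williams Latin-square order. The infant policy is solved once against
#' the base adult model (the robot carried one fixed policy); each
#' participant's own adult plant jitters the hazard parameters lognormally
#' (sd 0.2 on the log scale) to model individual differences. Each
#' participant's replay trace is the robot trace recorded by the *previous*
#' participant's infant-controller session; the first participant replays a
#' seeded bootstrap session.
#'
#' @param n_participants Number of participants (>= 2; default 32).
#' @param adult_params Base [generator_params()] describing the adult plant.
#' @param duration_s Session length in seconds (default 180).
#' @param seed Integer seed; the experiment is fully reproducible from it.
#' @param gamma,K,K_a Planner settings for the infant policy.
#' @param match_prob,mirror_delay_bins,beta Controller settings, see
#'   [smile_controller()].
#' @param positivity_weight,positivity_noise_sd See [positivity_proxy()].
#' @param plan Optional pre-solved infant policy (a [value_iteration()] plan
#'   against the base adult model); solved internally when `NULL`.
#' @return A tibble with one row per session: `participant`, `condition`,
#'   `order_pos`, `both_s`, `robot_only_s`, `participant_only_s`,
#'   `neither_s`, `positivity`.
#' @export
run_experiment <- function(n_participants = 32,
                           adult_params = generator_params(), duration_s = 180,
                           seed = 1, gamma = 0.98, K = 30, K_a = 10,
                           match_prob = 0.5, mirror_delay_bins = 1, beta = NULL,
                           positivity_weight = 1, positivity_noise_sd = 40,
                           plan = NULL) {
  if (n_participants < 2L) {
    abort("`n_participants` must be >= 2 (replay is defined by the previous participant).")
  }
  set.seed(seed)
  conditions <- c("infant", "replay", "mirror", "infant_plus")
  base_adult <- make_partner_hazard(adult_params, K = K, modeled_partner = "adult")
  if (is.null(plan)) {
    plan <- value_iteration(build_mdp(base_adult, "mother_only", "infant",
                                      gamma = gamma, K_a = K_a))
  }
  square <- latin_square_order()

  # bootstrap replay source for the first participant
  boot <- run_session(smile_controller("infant", plan = plan, beta = beta),
                      base_adult, duration_s)
  prev_infant_trace <- boot$robot_trace

  rows <- vector("list", n_participants * 4L)
  k <- 0L
  for (i in seq_len(n_participants)) {
    jit <- function(x) min(0.5, x * exp(rnorm(1, 0, 0.2)))
    pi_params <- adult_params
    pi_params$base_onset_hazard <- jit(adult_params$base_onset_hazard)
    pi_params$offset_c0 <- jit(adult_params$offset_c0)
    pi_params$offset_c1 <- jit(adult_params$offset_c1)
    pi_params$offset_hazard_mutual <- jit(adult_params$offset_hazard_mutual)
    adult_i <- make_partner_hazard(pi_params, K = K, modeled_partner = "adult")
    order_i <- conditions[square[(i - 1L) %% 4L + 1L, ]]
    replay_trace_i <- prev_infant_trace
    for (pos in seq_along(order_i)) {
      cond <- order_i[pos]
      ctrl <- switch(cond,
        infant = smile_controller("infant", plan = plan, beta = beta),
        replay = smile_controller("replay", replay_trace = replay_trace_i),
        mirror = smile_controller("mirror", mirror_delay_bins = mirror_delay_bins),
        infant_plus = smile_controller("infant_plus", plan = plan,
                                       match_prob = match_prob, beta = beta)
      )
      sess <- run_session(ctrl, adult_i, duration_s)
      if (cond == "infant") prev_infant_trace <- sess$robot_trace
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        participant = i, condition = cond, order_pos = pos,
        both_s = unname(sess$occupancy[["both"]]),
        robot_only_s = unname(sess$occupancy[["robot_only"]]),
        participant_only_s = unname(sess$occupancy[["participant_only"]]),
        neither_s = unname(sess$occupancy[["neither"]]),
        positivity = positivity_proxy(sess, positivity_weight, positivity_noise_sd)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("smile_experiment", class(out))
  out
}
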