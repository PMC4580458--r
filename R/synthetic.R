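#' Parameters of the synthetic dyad generator
#'
#' The generator emulates the statistical regularities the analysis assumes:
#' a responsive partner whose smile-onset hazard rises while the other member
#' smiles, duration-dependent cessation (the offset hazard grows linearly
#' with the seconds already spent smiling alone), intermittent gaze segments,
#' and multiple weekly sessions per dyad. All hazards are per 1-second bin
#' and capped at 0.5 to keep toggling identifiable at this resolution.
#'
#' @param base_onset_hazard Partner smile-onset probability per bin while the
#'   other is not smiling (default 0.03).
#' @param responsive_onset_boost Multiplier on the onset hazard while the
#'   other member smiles (default 4.0).
#' @param offset_c0,offset_c1 Offset hazard while smiling alone is
#'   `min(offset_c0 + offset_c1 * tau, 0.5)` (defaults 0.02 and 0.02/bin).
#' @param offset_hazard_mutual Offset probability per bin during mutual
#'   smiling (default 0.05).
#' @param gaze_on_prob Stationary fraction of time gazing at the partner
#'   (default 0.6).
#' @param gaze_run_mean_bins Mean length of a gaze-on run (default 8).
#' @param session_len_bins Bins per session (default 300).
#' @param n_sessions Sessions per dyad (default 10).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(base_onset_hazard = 0.03,
                             responsive_onset_boost = 4.0,
                             offset_c0 = 0.02, offset_c1 = 0.02,
                             offset_hazard_mutual = 0.05,
                             gaze_on_prob = 0.6, gaze_run_mean_bins = 8,
                             session_len_bins = 300, n_sessions = 10) {
  p <- list(
    base_onset_hazard = base_onset_hazard,
    responsive_onset_boost = responsive_onset_boost,
    offset_c0 = offset_c0, offset_c1 = offset_c1,
    offset_hazard_mutual = offset_hazard_mutual,
    gaze_on_prob = gaze_on_prob, gaze_run_mean_bins = gaze_run_mean_bins,
    session_len_bins = as.integer(session_len_bins),
    n_sessions = as.integer(n_sessions)
  )
  for (nm in c("base_onset_hazard", "offset_c0", "offset_hazard_mutual")) {
    check_scalar_prob(p[[nm]], nm, 0, 0.5)
  }
  check_scalar_prob(p$gaze_on_prob, "gaze_on_prob", 0, 1)
  if (p$session_len_bins < 1L || p$n_sessions < 0L) {
    abort("Session length and session count must be positive.")
  }
  structure(p, class = "generator_params")
}

#' Exact ground-truth hazard table from generator parameters
#'
#' @param params A [generator_params()] list.
#' @param K Elapsed-time cap of the table (default 30).
#' @param modeled_partner Label for the modelled partner (default "mother").
#' @return A `hazard_model` realising the parametric hazards: onset
#'   `base_onset_hazard` (times `responsive_onset_boost` when the other
#'   smiles, capped at 0.5), offset `min(offset_c0 + offset_c1 * tau, 0.5)`
#'   alone and `offset_hazard_mutual` during mutual smiling.
#' @export
make_partner_hazard <- function(params = generator_params(), K = 30,
                                modeled_partner = "mother") {
  tau <- seq_len(K) - 1
  h <- array(0, dim = c(2, 2, K))
  h[1, 1, ] <- min(params$base_onset_hazard, 0.5)
  h[1, 2, ] <- min(params$base_onset_hazard * params$responsive_onset_boost, 0.5)
  h[2, 1, ] <- pmin(params$offset_c0 + params$offset_c1 * tau, 0.5)
  h[2, 2, ] <- min(params$offset_hazard_mutual, 0.5)
  hazard_from_array(h, modeled_partner = modeled_partner)
}

# Two-state gaze Markov chain with given stationary on-fraction and mean
# on-run length; started from its stationary distribution.
simulate_gaze <- function(n, gaze_on_prob, run_mean) {
  if (gaze_on_prob >= 1) return(rep(1L, n))
  if (gaze_on_prob <= 0) return(rep(0L, n))
  p_off <- 1 / run_mean                                  # leave the on state
  p_on <- min(1, p_off * gaze_on_prob / (1 - gaze_on_prob))  # enter it
  g <- integer(n)
  g[1] <- rbinom(1, 1, gaze_on_prob)
  u <- runif(n)
  for (i in seq_len(n - 1L)) {
    g[i + 1L] <- if (g[i] == 1L) as.integer(u[i] >= p_off) else as.integer(u[i] < p_on)
  }
  g
}

#' Simulate one dyad of smile-game sessions
#'
#' The partner evolves by the ground-truth hazard model; the agent acts by
#' sampling keep/toggle from the Boltzmann policy `softmax(beta * Q)` of the
#' optimal plan for its goal (computed internally against the truth), so the
#' synthetic agent is self-consistent with the planner. Gaze is an
#' independent two-state Markov chain. A hand-coded reflex agent (smile with
#' fixed probability once the partner has smiled for a fixed delay) is
#' available to probe inference under misspecification.
#'
#' @param partner_truth Ground-truth `hazard_model` of the partner.
#' @param agent_goal Goal driving the agent (canonical goal name).
#' @param agent_beta Boltzmann inverse temperature of the acting agent
#'   (default 20).
#' @param params A [generator_params()] list.
#' @param agent_role `"infant"` (default) or `"mother"`.
#' @param dyad_id Identifier for the generated dyad.
#' @param gamma,K_a Planner settings for the internal plan.
#' @param agent_kind `"planner"` (default) or `"reflex"`.
#' @param reflex_delay,reflex_prob,reflex_offset Reflex agent: after the
#'   partner has smiled for `reflex_delay` bins, start smiling with
#'   probability `reflex_prob` per bin; while smiling, stop with hazard
#'   `reflex_offset`.
#' @param plan Optional precomputed [value_iteration()] plan (skips the
#'   internal solve).
#' @return Tibble with one row per session: `dyad_id`, `session_id`, and a
#'   `series` list-column of [smile_series()] objects.
#' @export
simulate_dyad <- function(partner_truth, agent_goal = "mother_only",
                          agent_beta = 20, params = generator_params(),
                          agent_role = "infant", dyad_id = "d1",
                          gamma = 0.98, K_a = 10,
                          agent_kind = c("planner", "reflex"),
                          reflex_delay = 1, reflex_prob = 0.5,
                          reflex_offset = 0.15, plan = NULL) {
  agent_kind <- match.arg(agent_kind)
  if (agent_kind == "planner" && is.null(plan)) {
    plan <- value_iteration(build_mdp(partner_truth, agent_goal, agent_role,
                                      gamma = gamma, K_a = K_a))
  }
  K <- partner_truth$K
  n <- params$session_len_bins
  sessions <- purrr::map(seq_len(params$n_sessions), function(sess) {
    a <- integer(n); p <- integer(n)
    ai <- 0L; pi <- 0L; ta <- 0L; tp <- 0L
    run_p <- 0L  # bins the partner has spent smiling, for the reflex agent
    for (i in seq_len(n)) {
      a[i] <- ai; p[i] <- pi
      if (i == n) break
      if (agent_kind == "planner") {
        s <- state_index(ai, pi, ta, tp, plan$K_a, plan$K)
        zk <- agent_beta * plan$Q[s, 1L]; zt <- agent_beta * plan$Q[s, 2L]
        m <- max(zk, zt)
        p_toggle <- exp(zt - m) / (exp(zk - m) + exp(zt - m))
      } else {
        p_toggle <- if (ai == 0L) {
          if (pi == 1L && run_p >= reflex_delay) reflex_prob else 0.02
        } else {
          reflex_offset
        }
      }
      toggled <- runif(1) < p_toggle
      ai_next <- if (toggled) 1L - ai else ai
      ta <- if (toggled) 0L else min(ta + 1L, K_a - 1L)
      # partner reacts to the agent's pre-action state
      p_tog <- partner_truth$h[pi + 1L, ai + 1L, tp + 1L]
      if (runif(1) < p_tog) {
        pi <- 1L - pi; tp <- 0L
      } else {
        tp <- min(tp + 1L, K - 1L)
      }
      run_p <- if (pi == 1L) run_p + 1L else 0L
      ai <- ai_next
    }
    gaze <- simulate_gaze(n, params$gaze_on_prob, params$gaze_run_mean_bins)
    if (agent_role == "infant") {
      smile_series(a, p, gaze, dyad_id = dyad_id,
                   session_id = sprintf("s%02d", sess))
    } else {
      smile_series(p, a, gaze, dyad_id = dyad_id,
                   session_id = sprintf("s%02d", sess))
    }
  })
  tibble::tibble(
    dyad_id = dyad_id,
    session_id = sprintf("s%02d", seq_len(params$n_sessions)),
    series = sessions
  )
}

#' Generate a synthetic cohort of dyads with known goals
#'
#' Mirrors the observed study layout: a set of dyads, each with several
#' sessions, whose agents pursue known goals. Per-dyad individual differences
#' are introduced by jittering every hazard parameter lognormally (sd 0.2 on
#' the log scale, about +/-20%), capped at 0.5.
#'
#' @param n_dyads Number of dyads (default 13).
#' @param goal_assignment Character vector of generating goals, recycled to
#'   `n_dyads` (default `"mother_only"`, the infant-side finding).
#' @param params Base [generator_params()].
#' @param agent_beta Acting inverse temperature (default 20).
#' @param agent_role `"infant"` (default) or `"mother"`.
#' @param seed Integer seed; the output is fully reproducible from it.
#' @param K Elapsed-time cap of the ground-truth hazard tables.
#' @param gamma,K_a Planner settings for the acting agents.
#' @return List with `sessions` (tibble: `dyad_id`, `session_id`, `series`
#'   list-column) and `manifest` (tibble per dyad: true goal, beta, and the
#'   jittered hazard parameters).
#' @export
make_cohort <- function(n_dyads = 13, goal_assignment = "mother_only",
                        params = generator_params(), agent_beta = 20,
                        agent_role = "infant", seed = 1, K = 30,
                        gamma = 0.98, K_a = 10) {
  set.seed(seed)
  if (n_dyads == 0L) {
    return(list(sessions = tibble::tibble(dyad_id = character(0),
                                          session_id = character(0),
                                          series = list()),
                manifest = tibble::tibble()))
  }
  goals <- rep_len(goal_assignment, n_dyads)
  out <- purrr::map(seq_len(n_dyads), function(d) {
    jit <- function(x) min(0.5, x * exp(rnorm(1, 0, 0.2)))
    pd <- params
    pd$base_onset_hazard <- jit(params$base_onset_hazard)
    pd$offset_c0 <- jit(params$offset_c0)
    pd$offset_c1 <- jit(params$offset_c1)
    pd$offset_hazard_mutual <- jit(params$offset_hazard_mutual)
    truth <- make_partner_hazard(pd, K = K)
    id <- sprintf("d%02d", d)
    sessions <- simulate_dyad(truth, agent_goal = goals[d], agent_beta = agent_beta,
                              params = pd, agent_role = agent_role, dyad_id = id,
                              gamma = gamma, K_a = K_a)
    manifest <- tibble::tibble(
      dyad_id = id, true_goal = goals[d], agent_beta = agent_beta,
      base_onset_hazard = pd$base_onset_hazard,
      responsive_onset_boost = pd$responsive_onset_boost,
      offset_c0 = pd$offset_c0, offset_c1 = pd$offset_c1,
      offset_hazard_mutual = pd$offset_hazard_mutual
    )
    list(sessions = sessions, manifest = manifest)
  })
  list(
    sessions = dplyr::bind_rows(purrr::map(out, "sessions")),
    manifest = dplyr::bind_rows(purrr::map(out, "manifest"))
  )
}

#' Write a cohort as event + manifest CSV files
#'
#' Converts the binned synthetic series back to onset/offset event rows in
#' the standard event schema (smile and gaze intervals) and writes the
#' ground-truth manifest alongside.
#'
#' @param cohort A [make_cohort()] result.
#' @param events_path,manifest_path Output CSV paths.
#' @return `events_path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, events_path, manifest_path) {
  events <- purrr::pmap(cohort$sessions, function(dyad_id, session_id, series) {
    series_to_events(series)
  }) |> dplyr::bind_rows()
  readr::write_csv(events, events_path)
  readr::write_csv(cohort$manifest, manifest_path)
  invisible(events_path)
}

series_to_events <- function(series) {
  w <- attr(series, "bin_width_s") %||% 1
  one_channel <- function(x, actor, behavior) {
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values == 1L
    tibble::tibble(
      dyad_id = attr(series, "dyad_id") %||% "d1",
      session_id = attr(series, "session_id") %||% "s1",
      actor = actor, behavior = behavior,
      onset_s = (starts[keep] - 1L) * w,
      offset_s = ends[keep] * w
    )
  }
  dplyr::bind_rows(
    one_channel(series$infant_smile, "infant", "smile"),
    one_channel(series$mother_smile, "mother", "smile"),
    one_channel(series$gaze, "infant", "gaze_at_partner")
  )
}
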