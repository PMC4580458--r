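# Internal helpers shared across modules.

# Canonical order of the four dyadic goals. Tables and posteriors always use
# this order: (neither, infant_only, mother_only, mutual).
goal_levels <- function() c("neither", "infant_only", "mother_only", "mutual")

actor_levels <- function() c("infant", "mother", "adult", "robot")

#' Map a dyadic goal onto (agent, partner) smile targets for a given role
#'
#' A goal names a joint smile configuration of the dyad. Which member of the
#' pair is "the agent" depends on whose behaviour is being analysed, so the
#' same goal maps onto different (agent, partner) targets for the infant-side
#' and mother-side analyses. The robot/adult pairing reuses the infant role:
#' the controller plays the infant, the adult plays the mother.
#'
#' @param goal One of `"neither"`, `"infant_only"`, `"mother_only"`, `"mutual"`.
#' @param agent_role `"infant"` (also used for robot controllers) or `"mother"`.
#' @return Named integer vector with elements `agent` and `partner` in {0, 1}.
#' @examples
#' goal_target("mother_only", "infant")  # agent quiet, partner smiling
#' @export
goal_target <- function(goal, agent_role = c("infant", "mother")) {
  goal <- match.arg(goal, goal_levels())
  agent_role <- match.arg(agent_role)
  infant_smile <- switch(goal, neither = 0L, infant_only = 1L, mother_only = 0L, mutual = 1L)
  mother_smile <- switch(goal, neither = 0L, infant_only = 0L, mother_only = 1L, mutual = 1L)
  if (agent_role == "infant") {
    c(agent = infant_smile, partner = mother_smile)
  } else {
    c(agent = mother_smile, partner = infant_smile)
  }
}

# log(mean(exp(x))) computed stably.
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Elapsed-time (tau) sequence for a binary state vector within one episode:
# tau[i] = bins since the state's last toggle, 0 at the episode start and
# immediately after each toggle, capped at cap - 1.
tau_sequence <- function(x, cap) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tau <- integer(n)
  for (i in seq_len(n - 1L)) {
    tau[i + 1L] <- if (x[i + 1L] != x[i]) 0L else min(tau[i] + 1L, cap - 1L)
  }
  tau
}

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must contain only 0/1 values.", name))
  }
  as.integer(x)
}

check_scalar_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi))
  }
  x
}
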