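#' Fit a discrete-time hazard model of a partner's smile toggles
#'
#' The "plant" of the smile game: a semi-Markov toggle model of the modelled
#' partner. At every bin the partner either keeps or toggles its smile state;
#' the toggle probability is conditioned on its own current smile state
#' (`s_self`), the other member's smile state (`s_other`), and the elapsed
#' time `tau` (bins since the partner's own last toggle, capped at `K - 1`).
#' This captures both responsivity (a raised onset hazard while the other is
#' smiling) and duration-dependent cessation (an offset hazard that grows the
#' longer a smile has lasted).
#'
#' Cell estimates are Laplace-smoothed:
#' `h = (toggles + alpha) / (exposures + 2 * alpha)`.
#'
#' @param episodes Episode tibble from [extract_episodes()] in which
#'   `partner_smile` is the channel of the partner being modelled. May be
#'   empty, yielding the pure-prior model `h = 1/2`.
#' @param modeled_partner Label stored on the model (`"mother"`, `"infant"`,
#'   or `"adult"`).
#' @param K Elapsed-time cap in bins (>= 1); hazards beyond `K - 1` bins are
#'   pooled into the last cell. Default 30.
#' @param alpha Pseudo-count smoothing (>= 0). Default 1.
#' @return An object of class `hazard_model`: a list with the 2 x 2 x K arrays
#'   `h`, `toggles`, `exposures` (dimensions: s_self, s_other, tau) and the
#'   fitting parameters.
#' @seealso [step_partner()], [hazard_loglik()], [tidy.hazard_model()]
#' @export
fit_hazard <- function(episodes, modeled_partner = "mother", K = 30, alpha = 1) {
  if (K < 1) abort("`K` must be >= 1.")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  K <- as.integer(K)
  toggles <- array(0, dim = c(2, 2, K))
  exposures <- array(0, dim = c(2, 2, K))
  n_ep <- if (is.null(episodes)) 0L else nrow(episodes)
  for (e in seq_len(n_ep)) {
    y <- episodes$partner_smile[[e]]
    x <- episodes$agent_smile[[e]]
    len <- length(y)
    if (len < 2L) next
    tau <- tau_sequence(y, K)
    for (i in seq_len(len - 1L)) {
      ss <- y[i] + 1L; so <- x[i] + 1L; tt <- tau[i] + 1L
      exposures[ss, so, tt] <- exposures[ss, so, tt] + 1
      if (y[i + 1L] != y[i]) toggles[ss, so, tt] <- toggles[ss, so, tt] + 1
    }
  }
  new_hazard_model(toggles, exposures, modeled_partner, K, alpha)
}

new_hazard_model <- function(toggles, exposures, modeled_partner, K, alpha,
                             h = NULL) {
  if (is.null(h)) h <- (toggles + alpha) / (exposures + 2 * alpha)
  structure(
    list(
      modeled_partner = modeled_partner, K = as.integer(K), alpha = alpha,
      h = h, toggles = toggles, exposures = exposures
    ),
    class = "hazard_model"
  )
}

#' Build a hazard model directly from a 2 x 2 x K probability array
#'
#' Useful for specifying ground-truth plants (array dimensions: s_self,
#' s_other, tau).
#'
#' @param h Array of toggle probabilities in `[0, 1]`, dim `c(2, 2, K)`.
#' @param modeled_partner Label for the modelled partner.
#' @return A `hazard_model`.
#' @export
hazard_from_array <- function(h, modeled_partner = "mother") {
  stopifnot(length(dim(h)) == 3L, dim(h)[1] == 2L, dim(h)[2] == 2L)
  if (any(h < 0 | h > 1)) abort("Hazards must lie in [0, 1].")
  K <- dim(h)[3]
  new_hazard_model(array(0, dim(h)), array(0, dim(h)), modeled_partner, K,
                   alpha = 0, h = h)
}

hazard_at <- function(model, s_self, s_other, tau) {
  model$h[s_self + 1L, s_other + 1L, pmin(tau, model$K - 1L) + 1L]
}

#' Sample one partner transition from a hazard model
#'
#' @param model A `hazard_model`.
#' @param s_self Partner's current smile state (0/1).
#' @param s_other The other member's current smile state (0/1).
#' @param tau Bins since the partner's last toggle, in `[0, K - 1]`.
#' @return List with `s_self` (next state) and `tau` (next elapsed time):
#'   a toggle resets `tau` to 0, otherwise `tau` advances, saturating at
#'   `K - 1`.
#' @export
step_partner <- function(model, s_self, s_other, tau) {
  p <- hazard_at(model, s_self, s_other, tau)
  if (runif(1) < p) {
    list(s_self = 1L - as.integer(s_self), tau = 0L)
  } else {
    list(s_self = as.integer(s_self), tau = min(as.integer(tau) + 1L, model$K - 1L))
  }
}

#' Log-likelihood of episodes under a hazard model
#'
#' Sums `log h` over observed toggles and `log(1 - h)` over observed holds, a
#' held-out diagnostic for comparing elapsed-time caps or smoothing levels.
#' Returns `-Inf` (with a message) if a zero-probability outcome is observed.
#'
#' @inheritParams fit_hazard
#' @param model A `hazard_model`.
#' @return Scalar log-likelihood; `0` for empty episodes.
#' @export
hazard_loglik <- function(model, episodes) {
  ll <- 0
  n_ep <- if (is.null(episodes)) 0L else nrow(episodes)
  for (e in seq_len(n_ep)) {
    y <- episodes$partner_smile[[e]]
    x <- episodes$agent_smile[[e]]
    len <- length(y)
    if (len < 2L) next
    tau <- tau_sequence(y, model$K)
    idx <- seq_len(len - 1L)
    p <- model$h[cbind(y[idx] + 1L, x[idx] + 1L, tau[idx] + 1L)]
    tog <- y[idx + 1L] != y[idx]
    contrib <- ifelse(tog, log(p), log1p(-p))
    if (any(!is.finite(contrib))) {
      inform("Zero-probability outcome observed; log-likelihood is -Inf.")
      return(-Inf)
    }
    ll <- ll + sum(contrib)
  }
  ll
}

#' @export
print.hazard_model <- function(x, ...) {
  cat(sprintf(
    "<hazard_model> partner=%s, K=%d, alpha=%g, %g transitions observed\n",
    x$modeled_partner, x$K, x$alpha, sum(x$exposures)
  ))
  cat(sprintf("  onset hazard (other not smiling / smiling): %.3f / %.3f (tau-mean)\n",
              mean(x$h[1, 1, ]), mean(x$h[1, 2, ])))
  cat(sprintf("  offset hazard (other not smiling / smiling): %.3f / %.3f (tau-mean)\n",
              mean(x$h[2, 1, ]), mean(x$h[2, 2, ])))
  invisible(x)
}

#' Tidy a hazard model into a long table
#'
#' @param x A `hazard_model`.
#' @param ... Unused.
#' @return Tibble with columns `s_self, s_other, tau, toggles, exposures, h`.
#' @export
tidy.hazard_model <- function(x, ...) {
  grid <- expand.grid(s_self = 0:1, s_other = 0:1, tau = seq_len(x$K) - 1L)
  tibble::tibble(
    s_self = grid$s_self, s_other = grid$s_other, tau = grid$tau,
    toggles = x$toggles[cbind(grid$s_self + 1L, grid$s_other + 1L, grid$tau + 1L)],
    exposures = x$exposures[cbind(grid$s_self + 1L, grid$s_other + 1L, grid$tau + 1L)],
    h = x$h[cbind(grid$s_self + 1L, grid$s_other + 1L, grid$tau + 1L)]
  ) |>
    dplyr::arrange(.data$s_self, .data$s_other, .data$tau)
}

#' Serialize / deserialize a hazard model as plain text
#'
#' Key-value header lines (`#`-prefixed) followed by the cell table CSV
#' (`s_self,s_other,tau,toggles,exposures,h`).
#'
#' @param model A `hazard_model`.
#' @param path File path.
#' @return `write_hazard_csv()` returns `path` invisibly; `read_hazard_csv()`
#'   returns the reconstructed `hazard_model`.
#' @export
write_hazard_csv <- function(model, path) {
  writeLines(c(sprintf("# modeled_partner=%s", model$modeled_partner),
               sprintf("# K=%d", model$K),
               sprintf("# alpha=%s", format(model$alpha))), path)
  readr::write_csv(tidy(model), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_hazard_csv
#' @export
read_hazard_csv <- function(path) {
  header <- grep("^#", readLines(path, n = 10L), value = TRUE)
  meta <- function(key) sub(sprintf("^# %s=", key), "",
                            grep(sprintf("^# %s=", key), header, value = TRUE)[1])
  df <- readr::read_csv(path, comment = "#", col_types = readr::cols())
  K <- as.integer(meta("K"))
  to_arr <- function(col) {
    a <- array(0, dim = c(2, 2, K))
    a[cbind(df$s_self + 1L, df$s_other + 1L, df$tau + 1L)] <- col
    a
  }
  new_hazard_model(to_arr(df$toggles), to_arr(df$exposures),
                   meta("modeled_partner"), K, as.numeric(meta("alpha")),
                   h = to_arr(df$h))
}
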