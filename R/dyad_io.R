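#' Read a dyadic behaviour event table
#'
#' Events are timestamped onset/offset intervals of a behaviour (smiling, or
#' gazing at the partner) for one actor of a dyad. The expected CSV header is
#' `dyad_id,session_id,actor,behavior,onset_s,offset_s`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per event, sorted by
#'   `(dyad_id, session_id, onset_s)`. `actor` is one of
#'   `r paste(actor_levels(), collapse = ", ")`; `behavior` is `smile` or
#'   `gaze_at_partner`.
#' @details Validation errors name the offending data line. Events of the same
#'   `(dyad_id, session_id, actor, behavior)` must not overlap, and every
#'   offset must exceed its onset.
#' @seealso [bin_events()], [write_series_csv()]
#' @export
read_event_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Event file not found: %s", path))
  # parsing problems are surfaced as errors below, not as readr warnings
  ev <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    dyad_id = readr::col_character(),
    session_id = readr::col_character(),
    actor = readr::col_character(),
    behavior = readr::col_character(),
    onset_s = readr::col_double(),
    offset_s = readr::col_double()
  )))
  prob <- readr::problems(ev)
  if (nrow(prob) > 0L) {
    abort(sprintf("Malformed event row at line %d of %s: %s",
                  prob$row[1] + 1L, path, prob$expected[1]))
  }
  missing_cols <- setdiff(
    c("dyad_id", "session_id", "actor", "behavior", "onset_s", "offset_s"),
    names(ev)
  )
  if (length(missing_cols) > 0L) {
    abort(sprintf("Event file %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(is.na(ev$onset_s) | is.na(ev$offset_s) |
                 !(ev$actor %in% actor_levels()) |
                 !(ev$behavior %in% c("smile", "gaze_at_partner")))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed event row at line %d of %s", bad[1] + 1L, path))
  }
  validate_events(ev, path)
  dplyr::arrange(ev, .data$dyad_id, .data$session_id, .data$onset_s)
}

validate_events <- function(ev, path = "<events>") {
  bad <- which(ev$offset_s <= ev$onset_s | ev$onset_s < 0)
  if (length(bad) > 0L) {
    abort(sprintf("Event at line %d of %s has offset_s <= onset_s (or negative onset).",
                  bad[1] + 1L, path))
  }
  overlaps <- ev |>
    dplyr::group_by(.data$dyad_id, .data$session_id, .data$actor, .data$behavior) |>
    dplyr::arrange(.data$onset_s, .by_group = TRUE) |>
    dplyr::summarise(
      overlap = any(.data$onset_s[-1] < .data$offset_s[-dplyr::n()]) && dplyr::n() > 1L,
      .groups = "drop"
    )
  if (any(overlaps$overlap)) {
    off <- overlaps[which(overlaps$overlap)[1], ]
    abort(sprintf(
      "Overlapping %s/%s events for dyad %s session %s in %s.",
      off$actor, off$behavior, off$dyad_id, off$session_id, path
    ))
  }
  invisible(ev)
}

#' Construct a binned smile series
#'
#' A smile series is the per-bin binary state of one dyad session: infant
#' smiling, mother smiling, and infant gaze at the partner, all sampled on a
#' common fixed-width time grid.
#'
#' @param infant_smile,mother_smile,gaze Equal-length 0/1 vectors.
#' @param dyad_id,session_id Identifiers.
#' @param bin_width_s Bin width in seconds.
#' @return A tibble of class `smile_series` with columns
#'   `bin, infant_smile, mother_smile, gaze` (bins are 0-based) and
#'   attributes `dyad_id`, `session_id`, `bin_width_s`.
#' @export
smile_series <- function(infant_smile, mother_smile, gaze,
                         dyad_id = "d1", session_id = "s1", bin_width_s = 1) {
  n <- length(infant_smile)
  if (length(mother_smile) != n || length(gaze) != n) {
    abort("All channels of a smile series must have the same length.")
  }
  if (n < 1L) abort("A smile series must contain at least one bin.")
  out <- tibble::tibble(
    bin = seq_len(n) - 1L,
    infant_smile = check_binary(infant_smile, "infant_smile"),
    mother_smile = check_binary(mother_smile, "mother_smile"),
    gaze = check_binary(gaze, "gaze")
  )
  attr(out, "dyad_id") <- dyad_id
  attr(out, "session_id") <- session_id
  attr(out, "bin_width_s") <- bin_width_s
  class(out) <- c("smile_series", class(out))
  out
}

#' Bin interval events into a smile series
#'
#' Converts onset/offset events of one session into fixed-width binary bins. A
#' bin is scored 1 for a channel when the behaviour covers at least
#' `coverage` of that bin (default one half), computed by exact interval
#' intersection.
#'
#' @param events Event tibble (one `(dyad_id, session_id)` only), as returned
#'   by [read_event_csv()].
#' @param bin_width_s Bin width in seconds (> 0); default 1.
#' @param duration_s Session duration in seconds; bins cover
#'   `ceiling(duration_s / bin_width_s)` bins. Defaults to the latest offset.
#' @param coverage Minimum occupied fraction of a bin to score it 1.
#' @return A [smile_series()] tibble. The mother/adult/robot smile channel is
#'   stored as `mother_smile`; `infant`/`robot`-actor smiles as `infant_smile`.
#' @details Events extending past `duration_s` are clipped with a warning.
#' @export
bin_events <- function(events, bin_width_s = 1, duration_s = NULL, coverage = 0.5) {
  if (bin_width_s <= 0) abort("`bin_width_s` must be > 0.")
  ids <- dplyr::distinct(events, .data$dyad_id, .data$session_id)
  if (nrow(ids) > 1L) abort("`bin_events()` expects events from a single session.")
  if (is.null(duration_s)) duration_s <- max(events$offset_s, 0)
  if (nrow(events) > 0L) validate_events(events)
  n <- max(1L, as.integer(ceiling(duration_s / bin_width_s)))
  if (nrow(events) > 0L && any(events$offset_s > duration_s + 1e-12)) {
    warn("Events extending past `duration_s` were clipped.")
  }

  channel <- function(keep) {
    cov <- numeric(n)
    sub <- events[keep, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      on <- sub$onset_s[i]
      off <- min(sub$offset_s[i], duration_s)
      if (off <= on) next
      b0 <- max(0L, floor(on / bin_width_s))
      b1 <- min(n - 1L, ceiling(off / bin_width_s) - 1L)
      for (b in b0:b1) {
        lo <- b * bin_width_s
        hi <- lo + bin_width_s
        cov[b + 1L] <- cov[b + 1L] + max(0, min(off, hi) - max(on, lo))
      }
    }
    as.integer(cov / bin_width_s >= coverage - 1e-12)
  }

  smile_series(
    infant_smile = channel(events$actor %in% c("infant", "robot") & events$behavior == "smile"),
    mother_smile = channel(events$actor %in% c("mother", "adult") & events$behavior == "smile"),
    gaze = channel(events$behavior == "gaze_at_partner"),
    dyad_id = if (nrow(ids)) ids$dyad_id[1] else "d1",
    session_id = if (nrow(ids)) ids$session_id[1] else "s1",
    bin_width_s = bin_width_s
  )
}

#' Extract gaze-gated analysis episodes from a smile series
#'
#' Analysis is restricted to stretches where the infant is gazing at the
#' partner, so that the partner's smiles are visible to the agent. Episodes
#' are maximal runs of `gaze == 1` of at least `min_len_bins` bins; elapsed
#' time context is considered to reset at each episode start.
#'
#' @param series A [smile_series()] tibble.
#' @param agent `"infant"` or `"mother"`: whose actions are under analysis.
#'   The agent's own smile channel becomes `agent_smile`, the other partner's
#'   becomes `partner_smile`.
#' @param min_len_bins Minimum episode length in bins (>= 1); default 2.
#' @param gaze_gate Set `FALSE` to treat the whole series as one episode
#'   (available for the mother-as-agent analysis, whose view of the infant
#'   does not depend on infant gaze).
#' @return A tibble with one row per episode: `dyad_id`, `session_id`,
#'   `start_bin`, `end_bin` (0-based, half-open) and list-columns
#'   `agent_smile`, `partner_smile`.
#' @export
extract_episodes <- function(series, agent = c("infant", "mother"),
                             min_len_bins = 2, gaze_gate = TRUE) {
  agent <- match.arg(agent)
  if (min_len_bins < 1) abort("`min_len_bins` must be >= 1.")
  gaze <- if (gaze_gate) series$gaze else rep(1L, nrow(series))
  r <- rle(gaze)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L & r$lengths >= min_len_bins
  a_chan <- if (agent == "infant") series$infant_smile else series$mother_smile
  p_chan <- if (agent == "infant") series$mother_smile else series$infant_smile
  tibble::tibble(
    dyad_id = rep(attr(series, "dyad_id") %||% "d1", sum(keep)),
    session_id = rep(attr(series, "session_id") %||% "s1", sum(keep)),
    start_bin = starts[keep] - 1L,
    end_bin = ends[keep],
    agent_smile = purrr::map2(starts[keep], ends[keep], ~ a_chan[.x:.y]),
    partner_smile = purrr::map2(starts[keep], ends[keep], ~ p_chan[.x:.y])
  )
}

#' Write / read a binned smile series as CSV
#'
#' Lossless plain-text round trip with columns `bin, infant_smile,
#' mother_smile, gaze`; identifiers and the bin width travel in `#`-prefixed
#' header comments.
#'
#' @param series A [smile_series()] tibble.
#' @param path Output (input) path.
#' @return `write_series_csv()` returns `path` invisibly; `read_series_csv()`
#'   returns a [smile_series()] tibble.
#' @export
write_series_csv <- function(series, path) {
  header <- c(
    sprintf("# dyad_id=%s", attr(series, "dyad_id") %||% "d1"),
    sprintf("# session_id=%s", attr(series, "session_id") %||% "s1"),
    sprintf("# bin_width_s=%s", format(attr(series, "bin_width_s") %||% 1))
  )
  tryCatch(writeLines(header, path), error = function(e) {
    abort(sprintf("Cannot open %s for writing: %s", path, conditionMessage(e)))
  })
  readr::write_csv(series[, c("bin", "infant_smile", "mother_smile", "gaze")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  header <- readLines(path, n = 10L)
  header <- header[startsWith(header, "#")]
  meta <- function(key, default) {
    hit <- grep(sprintf("^# %s=", key), header, value = TRUE)
    if (length(hit)) sub(sprintf("^# %s=", key), "", hit[1]) else default
  }
  df <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    bin = readr::col_integer(),
    infant_smile = readr::col_integer(),
    mother_smile = readr::col_integer(),
    gaze = readr::col_integer()
  ))
  smile_series(
    df$infant_smile, df$mother_smile, df$gaze,
    dyad_id = meta("dyad_id", "d1"),
    session_id = meta("session_id", "s1"),
    bin_width_s = as.numeric(meta("bin_width_s", "1"))
  )
}
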