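## Inhibitory-resetting oscillator model of male chorusing.
##
## Each male carries a free-running central rhythm generator with period T.
## A heard call (neighbour or playback) momentarily inhibits the generator
## and resets its phase: the male's next call is delayed by D(d), a
## non-increasing function of the post-call delay d at which the stimulus
## arrived. D(d) ranges from T (stimulus immediately after the male's own
## call) down to the minimum post-stimulus delay m (stimulus at the
## generator's peak, d = T - t, where t is the motor effector delay).

#' Oscillator parameters for one male
#'
#' Bundles the timing parameters of the inhibitory-resetting call oscillator:
#' the free-running call period `T`, the effector delay `t` between the
#' rhythm generator's peak and sound production, the minimum post-stimulus
#' call delay `m`, the call duration, an optional Gaussian jitter on
#' scheduled intervals, and whether the male resets at all.
#'
#' @param free_run_period_T_ms free-running call period T (ms), > 0.
#' @param effector_delay_t_ms effector delay t (ms), 0 < t < T.
#' @param min_reset_delay_m_ms minimum post-stimulus call delay m (ms),
#'   0 < m <= T.
#' @param call_duration_ms call duration (ms), 0 < duration < T.
#' @param period_jitter_sd_ms standard deviation of Gaussian jitter added to
#'   every scheduled inter-call interval (ms), >= 0.
#' @param resetting_enabled logical; if `FALSE` the male ignores stimuli and
#'   free-runs.
#' @return an object of class `oscillator_params`.
#' @export
oscillator_params <- function(free_run_period_T_ms,
                              effector_delay_t_ms,
                              min_reset_delay_m_ms,
                              call_duration_ms = free_run_period_T_ms / 10,
                              period_jitter_sd_ms = 0,
                              resetting_enabled = TRUE) {
  T_ <- free_run_period_T_ms; t_ <- effector_delay_t_ms
  m_ <- min_reset_delay_m_ms
  if (!is_number(T_) || T_ <= 0) stop_invalid("T must be a positive number")
  if (!is_number(t_) || t_ <= 0 || t_ >= T_) stop_invalid("need 0 < t < T")
  if (!is_number(m_) || m_ <= 0 || m_ > T_) stop_invalid("need 0 < m <= T")
  if (!is_number(call_duration_ms) || call_duration_ms <= 0 ||
      call_duration_ms >= T_)
    stop_invalid("need 0 < call_duration < T")
  if (!is_number(period_jitter_sd_ms) || period_jitter_sd_ms < 0)
    stop_invalid("jitter sd must be >= 0")
  structure(list(free_run_period_T_ms = T_,
                 effector_delay_t_ms = t_,
                 min_reset_delay_m_ms = m_,
                 call_duration_ms = call_duration_ms,
                 period_jitter_sd_ms = period_jitter_sd_ms,
                 resetting_enabled = isTRUE(resetting_enabled)),
            class = "oscillator_params")
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat(sprintf(
    "oscillator_params: T = %g ms, t = %g ms, m = %g ms, dur = %g ms, jitter sd = %g ms, resetting %s\n",
    x$free_run_period_T_ms, x$effector_delay_t_ms, x$min_reset_delay_m_ms,
    x$call_duration_ms, x$period_jitter_sd_ms,
    if (x$resetting_enabled) "on" else "off"))
  invisible(x)
}

#' Post-stimulus call delay of a reset oscillator
#'
#' The phase-resetting map D(d): the delay from a stimulus, heard at
#' post-call delay `d` after the male's own last call onset, to his next
#' call onset. The rebound from inhibition steepens as the stimulus arrives
#' later in the cycle, so D falls linearly from T (at d = 0) to the minimum
#' m (at d = T - t, the generator's peak) and stays at m for later stimuli:
#'
#' `D(d) = m + (T - t - d) (T - m) / (T - t)` for `0 <= d <= T - t`,
#' `D(d) = m` for `d > T - t`.
#'
#' D is continuous, non-increasing and bounded in \[m, T\]. The function is
#' the single point where the rebound geometry enters the model; alternative
#' (concave/convex) maps can be swapped in via the `delay_fun` argument of
#' [simulate_chorus()].
#'
#' @param d_ms post-call delay of the stimulus (ms), vectorised, >= 0.
#' @param params an [oscillator_params()] object.
#' @return delay(s) to the next call onset, in ms.
#' @export
reset_delay <- function(d_ms, params) {
  stopifnot(inherits(params, "oscillator_params"))
  if (any(!is.finite(d_ms)) || any(d_ms < 0))
    stop_invalid("post-call delay d must be finite and >= 0")
  T_ <- params$free_run_period_T_ms
  t_ <- params$effector_delay_t_ms
  m_ <- params$min_reset_delay_m_ms
  D <- m_ + (T_ - t_ - d_ms) * (T_ - m_) / (T_ - t_)
  pmax(D, m_)
}

new_call_series <- function(events, params_list, duration_ms) {
  events <- events[order(events$onset_ms, events$caller_id), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, params = params_list,
                 duration_ms = duration_ms),
            class = "call_series")
}

#' @export
print.call_series <- function(x, ...) {
  cat(sprintf("call_series: %d calls by %d caller(s) over %g ms\n",
              nrow(x$events), length(unique(x$events$caller_id)),
              x$duration_ms))
  invisible(x)
}

#' Free-running call series of a single male
#'
#' Call onsets at `t0 + k T` (plus Gaussian period jitter if configured),
#' with no stimuli processed. The first onset falls one period after the
#' start offset.
#'
#' @param params an [oscillator_params()] object.
#' @param duration_ms total simulated time (ms), >= T.
#' @param seed optional RNG seed (only used when jitter > 0).
#' @param start_offset_ms time of the male's virtual previous call onset
#'   (default 0).
#' @param caller_id caller label.
#' @return a `call_series`.
#' @export
free_run <- function(params, duration_ms, seed = NULL, start_offset_ms = 0,
                     caller_id = "M1") {
  stopifnot(inherits(params, "oscillator_params"))
  T_ <- params$free_run_period_T_ms
  if (!is_number(duration_ms) || duration_ms < T_)
    stop_invalid("duration must be >= T")
  with_rng(seed, {
    onsets <- numeric(0)
    now <- start_offset_ms
    repeat {
      step <- T_ + if (params$period_jitter_sd_ms > 0)
        rnorm(1, 0, params$period_jitter_sd_ms) else 0
      step <- max(step, params$min_reset_delay_m_ms)
      now <- now + step
      if (now > duration_ms) break
      onsets <- c(onsets, now)
    }
    events <- data.frame(caller_id = rep(caller_id, length(onsets)),
                         onset_ms = onsets,
                         duration_ms = rep(params$call_duration_ms,
                                           length(onsets)),
                         stringsAsFactors = FALSE)
    new_call_series(events, setNames(list(params), caller_id), duration_ms)
  })
}

#' Event-driven simulation of an interacting chorus
#'
#' Every call onset by male j is a stimulus to every other male i whose
#' `resetting_enabled` is `TRUE`: if the stimulus arrives at post-call delay
#' d since i's most recent onset, i's next scheduled onset is moved to
#' `stimulus_time + reset_delay(d, params_i)`. Non-resetting males ignore
#' stimuli. Onsets coinciding within a 1e-9 ms tie tolerance are emitted
#' together and do not stimulate each other.
#'
#' @param all_params list of [oscillator_params()], one per male; names are
#'   used as caller ids (defaults `M1..Mk`).
#' @param duration_ms simulated time (ms), >= max period.
#' @param seed optional RNG seed (used for jitter).
#' @param start_offsets_ms numeric vector of virtual previous-onset times,
#'   one per male (default all 0, i.e. males start in phase).
#' @param delay_fun resetting map, a function `(d_ms, params) -> delay`;
#'   defaults to [reset_delay()].
#' @return a `call_series` containing all emitted calls, sorted by onset.
#' @export
simulate_chorus <- function(all_params, duration_ms, seed = NULL,
                            start_offsets_ms = NULL,
                            delay_fun = reset_delay) {
  if (!is.list(all_params) || length(all_params) < 1)
    stop_invalid("need at least one male")
  if (inherits(all_params, "oscillator_params"))
    all_params <- list(all_params)
  lapply(all_params, function(p) stopifnot(inherits(p, "oscillator_params")))
  k <- length(all_params)
  ids <- names(all_params)
  if (is.null(ids)) ids <- paste0("M", seq_len(k))
  names(all_params) <- ids
  maxT <- max(vapply(all_params, `[[`, 0, "free_run_period_T_ms"))
  if (!is_number(duration_ms) || duration_ms < maxT)
    stop_invalid("duration must be >= max period")
  if (is.null(start_offsets_ms)) start_offsets_ms <- rep(0, k)
  stopifnot(length(start_offsets_ms) == k)
  tie_tol <- 1e-9

  with_rng(seed, {
    sched_interval <- function(i) {
      p <- all_params[[i]]
      step <- p$free_run_period_T_ms + if (p$period_jitter_sd_ms > 0)
        rnorm(1, 0, p$period_jitter_sd_ms) else 0
      max(step, p$min_reset_delay_m_ms)
    }
    last_onset <- start_offsets_ms             # virtual previous call
    next_onset <- vapply(seq_len(k), function(i)
      start_offsets_ms[i] + sched_interval(i), 0)
    cap <- max(64, ceiling(duration_ms / min(vapply(
      all_params, `[[`, 0, "min_reset_delay_m_ms"))) * k + 8)
    out_id <- integer(cap); out_on <- numeric(cap); n_out <- 0L

    repeat {
      s <- min(next_onset)
      if (s > duration_ms) break
      callers <- which(next_onset - s <= tie_tol)     # simultaneous onsets
      for (i in callers) {
        n_out <- n_out + 1L
        out_id[n_out] <- i; out_on[n_out] <- next_onset[i]
      }
      for (i in callers) {
        last_onset[i] <- next_onset[i]
        next_onset[i] <- next_onset[i] + sched_interval(i)
      }
      # each emitted call stimulates every other (non-tied) resetting male
      for (i in setdiff(seq_len(k), callers)) {
        if (!all_params[[i]]$resetting_enabled) next
        d <- s - last_onset[i]
        if (d < 0) d <- 0   # stimulus before the virtual first call
        next_onset[i] <- s + delay_fun(d, all_params[[i]])
      }
    }
    events <- data.frame(caller_id = ids[out_id[seq_len(n_out)]],
                         onset_ms = out_on[seq_len(n_out)],
                         duration_ms = vapply(out_id[seq_len(n_out)], function(i)
                           all_params[[i]]$call_duration_ms, 0),
                         stringsAsFactors = FALSE)
    new_call_series(events, all_params, duration_ms)
  })
}

#' Classify chorus calls as synchronous, following, leading or solo
#'
#' Relative to every rival call, a call is synchronous if the onset
#' difference is within `sync_tol_ms`; otherwise following if its onset
#' falls in `(0, f_window_ms]` after a rival onset; otherwise leading if a
#' rival onset falls in `(0, f_window_ms]` after it; otherwise solo. When a
#' call qualifies under several rules against different rivals it is
#' counted once under the precedence synchronous > following > leading.
#' Pairwise phase statistics (mean phase of caller i's onsets within caller
#' j's concurrent cycle, and the circular vector strength) are attached.
#'
#' @param series a `call_series`.
#' @param f_window_ms the follower window f (ms); must exceed `sync_tol_ms`.
#' @param sync_tol_ms synchrony tolerance (ms), >= 0.
#' @return an `interaction_counts` object: per-caller data frame of counts
#'   and a per-pair phase table.
#' @export
classify_calls <- function(series, f_window_ms, sync_tol_ms = 0) {
  stopifnot(inherits(series, "call_series"))
  if (!is_number(f_window_ms) || !is_number(sync_tol_ms) ||
      sync_tol_ms < 0 || f_window_ms <= sync_tol_ms)
    stop_invalid("need f_window > sync_tol >= 0")
  ev <- series$events
  ids <- unique(ev$caller_id)
  # per caller, gap to the nearest rival onset before and after each call
  prev_gap <- rep(Inf, nrow(ev)); next_gap <- rep(Inf, nrow(ev))
  for (id in ids) {
    sel <- which(ev$caller_id == id)
    rival <- sort(ev$onset_ms[ev$caller_id != id])
    if (!length(rival)) next
    x <- ev$onset_ms[sel]
    k <- findInterval(x, rival)
    pg <- ifelse(k >= 1, x - rival[pmax(k, 1)], Inf)
    ng <- ifelse(k < length(rival), rival[pmin(k + 1, length(rival))] - x, Inf)
    prev_gap[sel] <- pg; next_gap[sel] <- ng
  }
  cls <- rep("solo", nrow(ev))
  cls[next_gap > sync_tol_ms & next_gap <= f_window_ms] <- "leading"
  cls[prev_gap > sync_tol_ms & prev_gap <= f_window_ms] <- "following"
  cls[pmin(prev_gap, next_gap) <= sync_tol_ms] <- "synchronous"
  counts <- do.call(rbind, lapply(ids, function(id) {
    ci <- cls[ev$caller_id == id]
    data.frame(caller_id = id,
               n_leading = sum(ci == "leading"),
               n_following = sum(ci == "following"),
               n_synchronous = sum(ci == "synchronous"),
               n_solo = sum(ci == "solo"),
               stringsAsFactors = FALSE)
  }))
  phases <- NULL
  if (length(ids) >= 2) {
    pairs <- expand.grid(i = ids, j = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    phases <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      oi <- ev$onset_ms[ev$caller_id == pairs$i[r]]
      oj <- sort(ev$onset_ms[ev$caller_id == pairs$j[r]])
      ph <- numeric(0)
      if (length(oj) >= 2) {
        kk <- findInterval(oi, oj)
        valid <- kk >= 1 & kk < length(oj)
        kv <- kk[valid]
        ph <- (oi[valid] - oj[kv]) / (oj[kv + 1] - oj[kv])
      }
      vs <- if (length(ph)) Mod(mean(exp(2i * pi * ph))) else NA_real_
      mph <- if (length(ph)) (Arg(mean(exp(2i * pi * ph))) / (2 * pi)) %% 1
             else NA_real_
      data.frame(caller = pairs$i[r], reference = pairs$j[r],
                 n_phases = length(ph), mean_phase = mph,
                 vector_strength = vs, stringsAsFactors = FALSE)
    }))
  }
  structure(list(counts = counts, phases = phases,
                 classification = data.frame(ev, class = cls),
                 f_window_ms = f_window_ms, sync_tol_ms = sync_tol_ms),
            class = "interaction_counts")
}

#' @export
print.interaction_counts <- function(x, ...) {
  cat("interaction_counts (f_window =", x$f_window_ms, "ms, sync_tol =",
      x$sync_tol_ms, "ms)\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Female choice between a leading and a following call
#'
#' Precedence rule: if the leader-follower onset separation is at most the
#' preference window `f_window_ms`, the leader is chosen with probability
#' `0.5 + 0.5 * pref_strength`; beyond the window the choice is random.
#'
#' @param onset_leader_ms,onset_follower_ms distinct call onsets (ms);
#'   vectorised over pairs.
#' @param f_window_ms preference window f (ms).
#' @param pref_strength preference strength in \[0, 1\].
#' @param seed optional RNG seed.
#' @return character vector, `"leader"` or `"follower"` per pair.
#' @export
precedence_choice <- function(onset_leader_ms, onset_follower_ms, f_window_ms,
                              pref_strength, seed = NULL) {
  if (any(onset_leader_ms == onset_follower_ms))
    stop_invalid("onsets must be distinct")
  if (!is_number(pref_strength) || pref_strength < 0 || pref_strength > 1)
    stop_invalid("pref_strength must be in [0, 1]")
  sep <- abs(onset_follower_ms - onset_leader_ms)
  p_leader <- ifelse(sep <= f_window_ms, 0.5 + 0.5 * pref_strength, 0.5)
  # "leader" = the earlier of the two onsets
  earlier_is_first <- onset_leader_ms < onset_follower_ms
  p_first <- ifelse(earlier_is_first, p_leader, 1 - p_leader)
  with_rng(seed, {
    u <- runif(length(sep))
    chose_first <- u < p_first
    ifelse(chose_first == earlier_is_first, "leader", "follower")
  })
}
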