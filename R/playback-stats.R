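## Estimators for the two timing parameters of the study:
##   m - a male's minimum post-stimulus call delay (mean of his 3 shortest
##       observed delays; the population m averages the male values), and
##   f - the female preference window (largest tested leader-follower
##       separation at which the preference index stays >= 50% of its
##       maximum across separations).

#' Male playback record
#'
#' Post-stimulus call delays recorded for one male during playback of a
#' synthetic call stimulus at random intervals.
#'
#' @param male_id,population identifiers.
#' @param delays_ms numeric vector of non-negative delays (ms); at least 3
#'   are needed for m estimation.
#' @return an object of class `male_playback_record`.
#' @export
male_playback_record <- function(male_id, population, delays_ms) {
  if (any(!is.finite(delays_ms)) || any(delays_ms < 0))
    stop_invalid("delays must be finite and non-negative")
  structure(list(male_id = as.character(male_id),
                 population = as.character(population),
                 delays_ms = as.numeric(delays_ms)),
            class = "male_playback_record")
}

#' Histogram of post-stimulus call delays
#'
#' Counts per half-open bin `[k*bin, (k+1)*bin)` anchored at the stimulus
#' onset (time 0). Delays on a bin edge go to the upper bin.
#'
#' @param record a [male_playback_record()].
#' @param bin_ms bin width (ms), > 0; default 50.
#' @return data frame with columns `bin_start_ms`, `bin_end_ms`, `count`;
#'   empty records give a zero-row histogram.
#' @export
delay_histogram <- function(record, bin_ms = 50) {
  stopifnot(inherits(record, "male_playback_record"))
  if (!is_number(bin_ms) || bin_ms <= 0) stop_invalid("bin_ms must be > 0")
  d <- record$delays_ms
  if (!length(d))
    return(data.frame(bin_start_ms = numeric(0), bin_end_ms = numeric(0),
                      count = integer(0)))
  idx <- floor(d / bin_ms)
  tab <- table(factor(idx, levels = 0:max(idx)))
  data.frame(bin_start_ms = as.numeric(names(tab)) * bin_ms,
             bin_end_ms = (as.numeric(names(tab)) + 1) * bin_ms,
             count = as.integer(tab))
}

#' Estimate a male's minimum post-stimulus call delay m
#'
#' A male's m is the arithmetic mean of his `k` shortest recorded delays
#' (default 3).
#'
#' @param record a [male_playback_record()].
#' @param k number of shortest delays to average; default 3.
#' @return m in ms.
#' @export
estimate_male_m <- function(record, k = 3) {
  stopifnot(inherits(record, "male_playback_record"))
  if (!is_count(k, min = 1)) stop_invalid("k must be a positive count")
  d <- record$delays_ms
  if (length(d) < k)
    stop_insufficient("need at least ", k, " delays, got ", length(d))
  mean(sort(d)[seq_len(k)])
}

#' Estimate a population's m
#'
#' The unweighted mean of the per-male m values.
#'
#' @param records list of [male_playback_record()].
#' @param k passed to [estimate_male_m()].
#' @return population m in ms.
#' @export
estimate_population_m <- function(records, k = 3) {
  if (!length(records)) stop_insufficient("no male records")
  mean(vapply(records, estimate_male_m, 0, k = k))
}

#' Choice trials from a y-maze two-stimulus playback
#'
#' Build/validate a trial table: one row per (female, separation, trial)
#' with the binary outcome `chose_leader`.
#'
#' @param df data frame with columns `female_id`, `population`,
#'   `separation_ms`, `trial`, `chose_leader`.
#' @return the validated data frame with class `choice_trials`.
#' @export
choice_trials <- function(df) {
  need <- c("female_id", "population", "separation_ms", "trial",
            "chose_leader")
  if (!all(need %in% names(df)))
    stop_invalid("missing columns: ", paste(setdiff(need, names(df)),
                                            collapse = ", "))
  if (any(df$separation_ms <= 0)) stop_invalid("separations must be > 0")
  df$chose_leader <- as.logical(df$chose_leader)
  class(df) <- c("choice_trials", "data.frame")
  df
}

#' Preference index at one call separation
#'
#' `index = (pL - 0.5) / 0.5`, where pL is the proportion of choices for
#' the leading call pooled over all trials and females at that separation.
#' Because every female completes the same number of trials, each female
#' contributes equally; females with an incomplete trial set should be
#' excluded upstream.
#'
#' @param chose_leader logical vector of trial outcomes at one separation.
#' @return index in \[-1, 1\].
#' @export
preference_index <- function(chose_leader) {
  chose_leader <- as.logical(chose_leader)
  if (!length(chose_leader) || any(is.na(chose_leader)))
    stop_insufficient("need at least one complete trial")
  pL <- mean(chose_leader)
  (pL - 0.5) / 0.5
}

#' One-tailed sign test on per-female leader preference
#'
#' Each female with per-female pL > 0.5 is labelled '+', with pL < 0.5
#' labelled '-'; ties at exactly 0.5 are excluded. The p-value is
#' `P(X >= n_plus)` for `X ~ Binomial(n_plus + n_minus, 0.5)` (upper tail,
#' testing preference for the leader).
#'
#' @param per_female_pL numeric vector of per-female proportions of
#'   leader choices.
#' @return list with `n_plus`, `n_minus`, `n_tied`, `p_value` (NA with a
#'   warning if every female is tied).
#' @export
sign_test_preference <- function(per_female_pL) {
  if (!length(per_female_pL)) stop_insufficient("no females")
  n_plus <- sum(per_female_pL > 0.5)
  n_minus <- sum(per_female_pL < 0.5)
  n_tied <- sum(per_female_pL == 0.5)
  n <- n_plus + n_minus
  p <- if (n == 0) {
    warning("all females tied at pL = 0.5; sign test undefined")
    NA_real_
  } else {
    pbinom(n_plus - 1, n, 0.5, lower.tail = FALSE)
  }
  list(n_plus = n_plus, n_minus = n_minus, n_tied = n_tied, p_value = p)
}

#' Preference curve across call separations
#'
#' Pools trials per separation into pL, the preference index, the number of
#' females, and the one-tailed sign-test p on per-female labels.
#'
#' @param trials a [choice_trials()] data frame for one population.
#' @return data frame of class `preference_curve`, one row per separation,
#'   ordered by separation.
#' @export
preference_curve <- function(trials) {
  trials <- choice_trials(as.data.frame(trials))
  seps <- sort(unique(trials$separation_ms))
  rows <- lapply(seps, function(s) {
    tr <- trials[trials$separation_ms == s, , drop = FALSE]
    pL <- mean(tr$chose_leader)
    per_f <- tapply(tr$chose_leader, tr$female_id, mean)
    st <- suppressWarnings(sign_test_preference(as.numeric(per_f)))
    data.frame(separation_ms = s, pL = pL,
               index = (pL - 0.5) / 0.5,
               n_females = length(per_f),
               n_trials = nrow(tr),
               sign_test_p = st$p_value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("preference_curve", "data.frame")
  out
}

#' Estimate the female preference window f
#'
#' f is the largest tested separation whose preference index is at least
#' 50% of the maximum index observed across all separations; no
#' interpolation between grid points is performed. With
#' `contiguous = TRUE`, f is instead the largest separation such that the
#' index stays at or above the threshold at every tested separation up to
#' and including it.
#'
#' @param curve a [preference_curve()] (or data frame with `separation_ms`
#'   and `index`).
#' @param contiguous logical; see above. Default `FALSE` (the literal
#'   maximal-separation rule).
#' @return f in ms.
#' @export
estimate_f <- function(curve, contiguous = FALSE) {
  if (!all(c("separation_ms", "index") %in% names(curve)))
    stop_invalid("curve needs separation_ms and index columns")
  curve <- curve[order(curve$separation_ms), , drop = FALSE]
  if (nrow(curve) < 2) stop_insufficient("need indices at >= 2 separations")
  mx <- max(curve$index)
  if (mx <= 0)
    stop_insufficient("no leader preference observed (max index <= 0); f undefined")
  thr <- 0.5 * mx
  ok <- curve$index >= thr
  if (contiguous) {
    run <- cumprod(ok) > 0
    if (!any(run)) stop_insufficient("index below threshold at the smallest separation")
    max(curve$separation_ms[run])
  } else {
    max(curve$separation_ms[ok])
  }
}

#' Assemble a population timing row
#'
#' Packages a population's m, f, mean syllable number and sample sizes,
#' with validity checks.
#'
#' @param population identifier.
#' @param m_ms,f_ms timing parameters (ms), > 0.
#' @param mean_syllable_number mean syllable count of the male call.
#' @param n_males,n_females sample sizes.
#' @return one-row data frame of class `population_timing`.
#' @export
assemble_population_timing <- function(population, m_ms, f_ms,
                                       mean_syllable_number = NA_real_,
                                       n_males = NA_integer_,
                                       n_females = NA_integer_) {
  if (!is_number(m_ms) || m_ms <= 0) stop_invalid("m must be > 0")
  if (!is_number(f_ms) || f_ms <= 0) stop_invalid("f must be > 0")
  out <- data.frame(population = as.character(population), m_ms = m_ms,
                    f_ms = f_ms, syl = mean_syllable_number,
                    n_males = n_males, n_females = n_females,
                    stringsAsFactors = FALSE)
  class(out) <- c("population_timing", "data.frame")
  out
}
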