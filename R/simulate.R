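#' Synthetic-cohort generator parameters
#'
#' Bundles every knob of the synthetic study generator. Defaults emulate the
#' study conditions the pipeline is designed for: 71 participants viewing a
#' 1320-s stimulus with 30 true boundaries (minimum gap 20 s), boundary-
#' locked presses with a gamma latency of mean 1.2 s / SD 0.6 s, false
#' alarms at 0.3 per minute, ASRS totals targeting mean 29.14 / SD 8.77
#' (truncated to 0..72) from a single-factor item model, within/across
#' temporal-order accuracies of about 0.86 / 0.71 with a negative
#' ASRS-by-across slope, log-normal RTs with a small planted outlier mass,
#' and semantic accuracy 0.88 over 14 three-option items.
#'
#' @param n_participants Cohort size (default 71).
#' @param duration_s Stimulus duration in seconds (default 1320).
#' @param n_true_boundaries Number of true event boundaries (default 30).
#' @param min_boundary_gap_s Minimum gap between boundaries in seconds
#'   (default 20).
#' @param salience_sd SD of the standard-normal boundary salience (mean 0).
#' @param detect_intercept,detect_salience,detect_asrs Logistic detection
#'   model coefficients: `P(detect) = plogis(intercept + salience * s +
#'   asrs * z)` with `z` the standardized ASRS total (default slope
#'   negative: higher ADHD scores detect fewer boundaries).
#' @param latency_mean_s,latency_sd_s Gamma press latency after a detected
#'   boundary (defaults 1.2 and 0.6 s); `latency_sd_s = 0` gives a constant
#'   latency.
#' @param fa_per_min Homogeneous Poisson false-alarm rate per minute
#'   (default 0.3).
#' @param asrs_mean,asrs_sd Target mean and SD of the ASRS total
#'   (defaults 29.14 and 8.77).
#' @param asrs_loading Single-factor loading of each item on the latent
#'   trait (default 0.5; gives inter-item correlations consistent with
#'   alpha near 0.83).
#' @param acc_within,acc_across Target temporal-order accuracies at the
#'   average trait level (defaults 0.86 and 0.71).
#' @param across_asrs_slope Logit slope of across-scenes accuracy on the
#'   standardized ASRS total (default -0.35).
#' @param n_trials_per_condition Temporal-order trials per condition
#'   (default 14).
#' @param rt_meanlog,rt_sdlog Log-normal parameters of in-range RTs.
#' @param p_rt_fast,p_rt_slow Planted probabilities of an RT below 0.5 s or
#'   above 15 s (defaults 0.019 and 0.009, about 2.8% together).
#' @param semantic_accuracy Per-item semantic accuracy (default 0.88).
#' @param n_semantic Semantic items (default 14).
#' @param seed Optional RNG seed recorded with the parameters.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_participants = 71,
                       duration_s = 1320,
                       n_true_boundaries = 30,
                       min_boundary_gap_s = 20,
                       salience_sd = 1,
                       detect_intercept = 1.5,
                       detect_salience = 1.2,
                       detect_asrs = -0.4,
                       latency_mean_s = 1.2,
                       latency_sd_s = 0.6,
                       fa_per_min = 0.3,
                       asrs_mean = 29.14,
                       asrs_sd = 8.77,
                       asrs_loading = 0.5,
                       acc_within = 0.86,
                       acc_across = 0.71,
                       across_asrs_slope = -0.35,
                       n_trials_per_condition = 14,
                       rt_meanlog = log(2.5),
                       rt_sdlog = 0.4,
                       p_rt_fast = 0.019,
                       p_rt_slow = 0.009,
                       semantic_accuracy = 0.88,
                       n_semantic = 14,
                       seed = NULL) {
  p <- as.list(environment())
  stopifnot(p$n_participants >= 1, p$duration_s > 0, p$n_true_boundaries >= 1,
            p$min_boundary_gap_s >= 0, p$latency_mean_s >= 0,
            p$latency_sd_s >= 0, p$fa_per_min >= 0,
            p$acc_within > 0, p$acc_within < 1,
            p$acc_across > 0, p$acc_across < 1,
            p$semantic_accuracy > 0, p$semantic_accuracy < 1,
            p$p_rt_fast >= 0, p$p_rt_slow >= 0, p$p_rt_fast + p$p_rt_slow < 1,
            p$asrs_loading > 0, p$asrs_loading < 1)
  edge <- boundary_edge_margin(p)
  if ((p$n_true_boundaries - 1) * p$min_boundary_gap_s + 2 * edge > p$duration_s) {
    abort("sim_params: boundaries cannot be packed into duration_s with this minimum gap")
  }
  structure(p, class = "sim_params")
}

boundary_edge_margin <- function(params) {
  min(10, params$duration_s / (2 * params$n_true_boundaries + 2))
}

# uniform boundary times with a minimum gap, kept off the stimulus edges
draw_boundaries <- function(params) {
  n <- params$n_true_boundaries
  edge <- boundary_edge_margin(params)
  slack <- params$duration_s - 2 * edge - (n - 1) * params$min_boundary_gap_s
  u <- sort(runif(n, 0, slack))
  tibble::tibble(
    boundary_id = sprintf("b%02d", seq_len(n)),
    time_s = edge + u + (seq_len(n) - 1) * params$min_boundary_gap_s,
    salience = rnorm(n, 0, params$salience_sd)
  )
}

# 18 ordinal items from one latent trait; totals match the target mean/SD
# analytically: items = clamp(round(a + b*(lambda*z + sqrt(1-lambda^2)*eps)))
draw_asrs_items <- function(params, z_latent) {
  n <- length(z_latent)
  lam <- params$asrs_loading
  a <- params$asrs_mean / 18
  b <- params$asrs_sd / sqrt(324 * lam^2 + 18 * (1 - lam^2))
  eps <- matrix(rnorm(n * 18), n, 18)
  raw <- a + b * (lam * z_latent + sqrt(1 - lam^2) * eps)
  items <- matrix(pmin(4L, pmax(0L, as.integer(round(raw)))), n, 18,
                  dimnames = list(NULL, asrs_item_names()))
  items
}

#' Simulate a complete synthetic cohort
#'
#' Generates, for each participant: a latent trait expressed as the
#' standardized ASRS total; 18 ASRS item scores from a single-factor ordinal
#' model; boundary presses (each true boundary detected with probability
#' `plogis(intercept + b_sal * salience + b_asrs * z)`, detected boundaries
#' pressed after a gamma latency, plus homogeneous Poisson false alarms);
#' two-condition forced-choice temporal-order trials with log-normal RTs and
#' a planted outlier mass; and a binomial semantic score. Ground truth
#' (boundaries with salience; per-participant latent quantities) is always
#' emitted alongside the data.
#'
#' @param params A [sim_params()] object; `params$seed`, when set, seeds the
#'   generator so output is byte-identical across runs.
#' @param boundaries Optional pre-drawn ground-truth boundary table (from an
#'   enclosing [simulate_study()] call); drawn from `params` when `NULL`.
#' @return A list of class `eventseg_cohort` with tibbles `presses`, `asrs`,
#'   `memory_trials`, `semantic`, `ground_truth` (list: `boundaries`,
#'   `participants`) and the `params`.
#' @export
simulate_cohort <- function(params, boundaries = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(boundaries)) boundaries <- draw_boundaries(params)
  n <- params$n_participants
  ids <- sprintf("p%02d", seq_len(n))

  z_latent <- rnorm(n)
  items <- draw_asrs_items(params, z_latent)
  total <- rowSums(items)
  z <- if (sd(total) > 0) as.numeric(scale(total)) else rep(0, n)

  presses <- purrr::map2_dfr(seq_len(n), ids, function(i, id) {
    draw_presses(params, boundaries, z[i], id)
  })
  attr(presses, "duration_s") <- params$duration_s

  asrs <- tibble::as_tibble(cbind(
    tibble::tibble(participant_id = ids), tibble::as_tibble(items)))

  memory_trials <- purrr::map2_dfr(seq_len(n), ids, function(i, id) {
    draw_memory_trials(params, z[i], id)
  })

  semantic <- tibble::tibble(
    participant_id = ids,
    n_correct = rbinom(n, params$n_semantic, params$semantic_accuracy),
    n_trials = params$n_semantic
  )

  n_press <- as.integer(table(factor(presses$participant_id, levels = ids)))
  participants <- tibble::tibble(
    participant_id = ids, z_latent = z_latent, asrs_total = as.integer(total),
    z_asrs = z, n_presses = n_press
  )

  structure(list(presses = presses, asrs = asrs,
                 memory_trials = memory_trials, semantic = semantic,
                 ground_truth = list(boundaries = boundaries,
                                     participants = participants),
                 params = params),
            class = "eventseg_cohort")
}

draw_presses <- function(params, boundaries, z, id,
                         detect_intercept = params$detect_intercept,
                         latency_mean_s = params$latency_mean_s,
                         latency_sd_s = params$latency_sd_s,
                         fa_per_min = params$fa_per_min) {
  p_detect <- plogis(detect_intercept +
                       params$detect_salience * boundaries$salience +
                       params$detect_asrs * z)
  hit <- runif(nrow(boundaries)) < p_detect
  lat <- draw_latency(sum(hit), latency_mean_s, latency_sd_s)
  times <- boundaries$time_s[hit] + lat
  n_fa <- rpois(1, fa_per_min * params$duration_s / 60)
  times <- c(times, runif(n_fa, 0, params$duration_s))
  times <- times[times >= 0 & times <= params$duration_s]
  tibble::tibble(participant_id = id, time_s = sort(times))
}

draw_latency <- function(n, mean_s, sd_s) {
  if (n == 0) return(numeric(0))
  if (mean_s == 0 || sd_s == 0) return(rep(mean_s, n))
  shape <- (mean_s / sd_s)^2
  rgamma(n, shape = shape, scale = sd_s^2 / mean_s)
}

draw_memory_trials <- function(params, z, id) {
  nt <- params$n_trials_per_condition
  one_condition <- function(cond, p_correct) {
    earlier <- sample(rep(c("left", "right"), length.out = nt))
    correct <- runif(nt) < p_correct
    response <- ifelse(correct, earlier,
                       ifelse(earlier == "left", "right", "left"))
    rt <- draw_rt(nt, params)
    tibble::tibble(participant_id = id,
                   trial_id = sprintf("%s%02d", substr(cond, 1, 1), seq_len(nt)),
                   condition = cond, earlier_side = earlier,
                   response = response, rt_s = rt)
  }
  p_within <- plogis(qlogis(params$acc_within))
  p_across <- plogis(qlogis(params$acc_across) + params$across_asrs_slope * z)
  dplyr::bind_rows(one_condition("within", p_within),
                   one_condition("across", p_across))
}

draw_rt <- function(n, params) {
  kind <- runif(n)
  rt <- rlnorm(n, params$rt_meanlog, params$rt_sdlog)
  rt <- pmin(pmax(rt, 0.55), 14.5)                 # keep the core in range
  fast <- kind < params$p_rt_fast
  slow <- kind >= params$p_rt_fast & kind < params$p_rt_fast + params$p_rt_slow
  rt[fast] <- runif(sum(fast), 0.05, 0.45)
  rt[slow] <- 15.05 + rexp(sum(slow), rate = 1 / 3)
  rt
}

#' Simulate a high-attention norming sample
#'
#' Draws press logs for an independent norming sample (default 10 viewers)
#' with a high detection probability and small latency jitter, suitable for
#' [derive_prototypical()]. With `detect_intercept = Inf` every boundary is
#' detected; with `latency_mean_s = 0, latency_sd_s = 0` presses fall
#' exactly on the true boundaries.
#'
#' @param params A [sim_params()] object (cohort-level settings reused).
#' @param n Norming sample size (default 10).
#' @param boundaries Ground-truth boundary table to respond to; drawn fresh
#'   from `params` when `NULL`.
#' @param detect_intercept Detection intercept for the norming viewers
#'   (default 3.5, i.e. near-ceiling detection).
#' @param latency_mean_s,latency_sd_s Norming press latency (defaults: the
#'   cohort latency mean, SD 0.2 s).
#' @param fa_per_min Norming false-alarm rate (default: the cohort rate).
#' @return A press tibble (`participant_id`, `time_s`) with a `duration_s`
#'   attribute; the boundary table used is attached as attribute
#'   `boundaries`.
#' @export
make_norming_sample <- function(params, n = 10, boundaries = NULL,
                                detect_intercept = 3.5,
                                latency_mean_s = params$latency_mean_s,
                                latency_sd_s = 0.2,
                                fa_per_min = params$fa_per_min) {
  stopifnot(inherits(params, "sim_params"), n >= 1)
  if (is.null(boundaries)) {
    if (!is.null(params$seed)) set.seed(params$seed)
    boundaries <- draw_boundaries(params)
  }
  ids <- sprintf("n%02d", seq_len(n))
  presses <- purrr::map_dfr(ids, function(id) {
    draw_presses(params, boundaries, z = 0, id = id,
                 detect_intercept = detect_intercept,
                 latency_mean_s = latency_mean_s,
                 latency_sd_s = latency_sd_s,
                 fa_per_min = fa_per_min)
  })
  attr(presses, "duration_s") <- params$duration_s
  attr(presses, "boundaries") <- boundaries
  presses
}

#' Snap derived boundaries to known event times
#'
#' Maps each consensus boundary to the nearest known event time within
#' `max_dist_s`, mimicking the norming procedure in which each
#' high-agreement press cluster is re-anchored to the actual scene start at
#' 100-ms precision. Clusters with no event within reach (e.g. built from
#' false alarms) are dropped with a message.
#'
#' @param proto Derived boundary tibble ([derive_prototypical()] output).
#' @param event_times_s Numeric vector of known event (scene-start) times.
#' @param max_dist_s Maximum snap distance in seconds (default 10).
#' @param resolution_s Grid to which snapped times are rounded (default 0.1).
#' @return A tibble like `proto` with snapped, deduplicated times.
#' @export
snap_to_events <- function(proto, event_times_s, max_dist_s = 10,
                           resolution_s = 0.1) {
  if (nrow(proto) == 0) return(proto)
  nearest <- vapply(proto$time_s, function(t) {
    d <- abs(event_times_s - t)
    i <- which.min(d)
    if (d[i] <= max_dist_s) event_times_s[i] else NA_real_
  }, numeric(1))
  dropped <- sum(is.na(nearest))
  if (dropped > 0) {
    message(sprintf("snap_to_events: dropped %d cluster(s) with no event within %g s",
                    dropped, max_dist_s))
  }
  out <- proto[!is.na(nearest), , drop = FALSE]
  out$time_s <- round(nearest[!is.na(nearest)] / resolution_s) * resolution_s
  out <- out[!duplicated(out$time_s), , drop = FALSE]
  dplyr::arrange(out, .data$time_s)
}

#' Simulate the complete study (cohort + norming + prototypical set)
#'
#' End-to-end seeded generator: draws the ground-truth boundaries once,
#' simulates the main cohort and the norming sample against them, derives
#' the consensus boundaries from the norming presses and snaps them to the
#' true scene starts (the synthetic analog of the experimenter re-anchoring
#' each cluster).
#'
#' @param params A [sim_params()] object.
#' @param n_norming Norming sample size (default 10).
#' @param proto_window_s,min_agree Consensus clustering parameters passed to
#'   [derive_prototypical()] (defaults 10 s and 6).
#' @return An `eventseg_cohort` list as from [simulate_cohort()] with the
#'   additional elements `norming` (press tibble) and `proto` (snapped
#'   prototypical boundary tibble).
#' @export
simulate_study <- function(params, n_norming = 10, proto_window_s = 10,
                           min_agree = 6) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  boundaries <- draw_boundaries(params)
  cohort <- simulate_cohort(strip_seed(params), boundaries = boundaries)
  norming <- make_norming_sample(strip_seed(params), n = n_norming,
                                 boundaries = boundaries)
  proto <- derive_prototypical(norming, window_s = proto_window_s,
                               min_agree = min_agree)
  proto <- snap_to_events(proto, boundaries$time_s, max_dist_s = proto_window_s)
  cohort$norming <- norming
  cohort$proto <- proto
  cohort$params <- params
  cohort
}

strip_seed <- function(params) {
  params$seed <- NULL
  params
}
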