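# Trial-level simulation: entry, allocation, latent event times, switching
# counterfactuals, censoring and observed intention-to-treat records.

# Simulate one arm. Returns parallel vectors; draws consume the current
# RNG stream in a fixed order (entry, latent event, switch-time variable,
# switching coin, dropout), so runs are reproducible given a stream.
sim_arm <- function(nn, spec, entry, dropout, sw = NULL, accel = 1) {
  v <- sample_entry(nn, entry)
  t_lat <- gg_sample(nn, spec)
  t_cf <- t_lat
  switched <- logical(nn)
  s_time <- rep(NA_real_, nn)
  if (!is.null(sw) && sw$ps > 0) {
    st <- sample_switch_times(sw, t_lat)
    coin <- stats::runif(nn) < sw$ps
    switched <- st$eligible & coin
    if (any(switched)) {
      s_time[switched] <- st$switch_time[switched]
      if (accel != 1)   # accel = 1 is the exact identity
        t_cf[switched] <- st$switch_time[switched] +
          (t_lat[switched] - st$switch_time[switched]) * accel
    }
  }
  cens <- sample_censoring(dropout, v)
  y <- pmin(t_cf, cens)
  list(entry = v, latent = t_lat, counterfactual = t_cf,
       switched = switched, switch_time = s_time, censor = cens,
       time = y, event = t_cf <= cens)
}

#' Simulate one complete trial dataset
#'
#' Generates per-subject intention-to-treat records under the design:
#' staggered entry, deterministic allocation (`n` control,
#' `round(r * n)` experimental), latent event times, switching with the
#' RPSFT counterfactual in the switching arm, dropout/administrative
#' censoring, and the observed time `min(T*, C)` with its event flag.
#'
#' @param design An [ni_design()] object with `n` set.
#' @param stream Optional RNG substream (as produced internally); by
#'   default the first substream spawned from `design$seed` is used.
#' @return A data frame of class `"ni_trial"` with columns `arm`
#'   (factor, `control`/`experimental`), `entry`, `latent`,
#'   `counterfactual`, `switched`, `switch_time`, `censor`, `time`,
#'   `event`.
#' @examples
#' d <- ni_design(n = 50, m1 = 1, m2 = 1.1, m0 = 0.5, f2 = 0.5,
#'                Ta = 3, Te = 5, censoring.prob = 0.2)
#' head(simulate_trial(d))
#' @export
simulate_trial <- function(design, stream = NULL) {
  stopifnot(inherits(design, "ni_design"))
  if (is.null(design$n)) stopf("'n' must be set to simulate a trial")
  solved <- solve_design(design)
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_rng), add = TRUE)
  if (is.null(stream)) stream <- make_streams(design$seed, 1)[[1]]
  use_stream(stream)
  to2 <- design$TXswitch == "1to2"
  a1 <- sim_arm(solved$n1, solved$spec1, solved$entry, solved$dropout,
                if (to2) solved$switch else NULL, solved$accel)
  a2 <- sim_arm(solved$n2, solved$spec2, solved$entry, solved$dropout,
                if (!to2) solved$switch else NULL, solved$accel)
  out <- data.frame(
    arm = factor(rep(c("control", "experimental"), c(solved$n1, solved$n2)),
                 levels = c("control", "experimental")),
    entry = c(a1$entry, a2$entry),
    latent = c(a1$latent, a2$latent),
    counterfactual = c(a1$counterfactual, a2$counterfactual),
    switched = c(a1$switched, a2$switched),
    switch_time = c(a1$switch_time, a2$switch_time),
    censor = c(a1$censor, a2$censor),
    time = c(a1$time, a2$time),
    event = c(a1$event, a2$event))
  class(out) <- c("ni_trial", "data.frame")
  out
}

#' Export / import a simulated trial as a tab-separated table
#'
#' Writes one row per subject with columns `arm`, `entry`, `time`,
#' `event`, `switched`, `switch_time` — the format accepted by the
#' standalone [drmst_test()] path.
#'
#' @param trial A data frame from [simulate_trial()].
#' @param file Path of the TSV file.
#' @export
write_trial <- function(trial, file) {
  cols <- c("arm", "entry", "time", "event", "switched", "switch_time")
  utils::write.table(as.data.frame(trial)[, cols], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trial
#' @export
read_trial <- function(file) {
  out <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out$arm <- factor(out$arm, levels = unique(out$arm))
  out
}
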