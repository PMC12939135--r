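#' Default synthetic-cohort configuration
#'
#' Returns the study-shaped design: two groups (motor execution, ME, and
#' motor imagery, MI) of 10 subjects each, sessions of 750 trials in 5
#' blocks of 150, a 2000 ms response window and a per-trial miss/error
#' probability of 0.001. The planted effects are demonstration defaults
#' chosen to mirror the qualitative pattern such experiments report — the
#' MI group improves across blocks while the ME group improves only within
#' blocks, and both groups differentiate event types — and are fully
#' overridable through `...`.
#'
#' Effect fields, all in milliseconds:
#' \describe{
#'   \item{baseline_ms}{per-group mean RT (imagery durations run much longer
#'     than execution RTs).}
#'   \item{block_effect_ms}{per-group additive trend across blocks (vector of
#'     length `n_blocks`).}
#'   \item{within_block_slope_ms}{per-group-and-block additive change per
#'     50-trial sub-block step.}
#'   \item{event_offset_ms}{per-group offset for each event type F1, F2, V2,
#'     V3.}
#'   \item{lastvar_interaction_ms}{per-group 4 x 2 matrix (event x last
#'     variable event V2/V3) of crossed offsets.}
#'   \item{subject_sd_ms, noise_sd_ms}{between-subject intercept SD and
#'     trial noise SD.}
#' }
#' The trial-noise family is lognormal by default (reaction times are
#' right-skewed); `noise_family = "gaussian"` gives symmetric noise for
#' analytic checks. The anticipatory window (500 ms) and stimulus duration
#' (220 ms) are carried as documentation only: RT is defined from stimulus
#' end, so they never enter generation.
#'
#' @param ... named overrides of any configuration field.
#' @return an object of class `srt_config` (a validated list).
#' @seealso [null_config()], [simulate_cohort()].
#' @export
default_config <- function(...) {
  cfg <- list(
    n_per_group = 10L,
    n_blocks = 5L,
    block_len = 150L,
    sub_block_len = 50L,
    groups = c("ME", "MI"),
    baseline_ms = c(ME = 450, MI = 900),
    block_effect_ms = list(ME = rep(0, 5),
                           MI = c(0, -30, -60, -90, -120)),
    within_block_slope_ms = list(ME = c(-10, -15, -10, 0, 0),
                                 MI = c(-20, -10, -5, 0, 0)),
    event_offset_ms = list(ME = c(F1 = 0, F2 = 30, V2 = 60, V3 = 10),
                           MI = c(F1 = 0, F2 = 5, V2 = 110, V3 = 40)),
    lastvar_interaction_ms = list(
      ME = matrix(c(-15, 15,
                     15, -15,
                      0,   0,
                      0,   0), nrow = 4, byrow = TRUE,
                  dimnames = list(c("F1", "F2", "V2", "V3"), c("V2", "V3"))),
      MI = matrix(c(  0,   0,
                      0,   0,
                    -25,  25,
                     25, -25), nrow = 4, byrow = TRUE,
                  dimnames = list(c("F1", "F2", "V2", "V3"), c("V2", "V3")))),
    subject_sd_ms = 50,
    noise_sd_ms = 150,
    noise_family = "lognormal",
    error_rate = 0.001,
    rt_ceiling_ms = 2000,
    shared_sequence = FALSE,
    anticipatory_ms = 500,   # documentation only
    stimulus_ms = 220,       # documentation only
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  # resize default block-wise trend vectors when n_blocks is overridden
  for (fld in c("block_effect_ms", "within_block_slope_ms")) {
    if (fld %in% names(over)) next
    cfg[[fld]] <- lapply(cfg[[fld]], function(v) {
      if (length(v) >= cfg$n_blocks) v[seq_len(cfg$n_blocks)] else
        c(v, rep(v[length(v)], cfg$n_blocks - length(v)))
    })
  }
  class(cfg) <- "srt_config"
  validate_config(cfg)
  cfg
}

#' Null (no-effect) configuration
#'
#' The default configuration with every planted effect — block trends,
#' within-block slopes, event offsets and last-variable interactions —
#' set to zero. Only the group baselines, between-subject intercepts and
#' trial noise remain, so any downstream rejection of a within-subject
#' effect is a type-I error. Used by the calibration harness.
#'
#' @inheritParams default_config
#' @return an `srt_config`.
#' @export
null_config <- function(...) {
  cfg <- default_config(...)
  zero4x2 <- matrix(0, 4, 2,
                    dimnames = list(c("F1", "F2", "V2", "V3"), c("V2", "V3")))
  for (g in cfg$groups) {
    cfg$block_effect_ms[[g]] <- rep(0, cfg$n_blocks)
    cfg$within_block_slope_ms[[g]] <- rep(0, cfg$n_blocks)
    cfg$event_offset_ms[[g]][] <- 0
    cfg$lastvar_interaction_ms[[g]] <- zero4x2
  }
  over <- list(...)
  if (length(over)) cfg[names(over)] <- over
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "srt_config"))
  fail <- function(msg) stop("invalid config: ", msg, call. = FALSE)
  if (cfg$n_per_group < 2) fail("n_per_group must be >= 2")
  if (cfg$n_blocks < 1 || cfg$block_len < 1) fail("empty design")
  if (cfg$block_len %% cfg$sub_block_len != 0) {
    fail("block_len must be divisible by the 50-trial sub-block length")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) fail("error_rate not in [0,1)")
  if (cfg$rt_ceiling_ms <= 0) fail("rt_ceiling_ms must be positive")
  if (cfg$noise_sd_ms < 0 || cfg$subject_sd_ms < 0) fail("negative SD")
  if (!cfg$noise_family %in% c("gaussian", "lognormal")) {
    fail("noise_family must be 'gaussian' or 'lognormal'")
  }
  for (g in cfg$groups) {
    if (is.null(cfg$baseline_ms[[g]]) || cfg$baseline_ms[[g]] <= 0) {
      fail(sprintf("group '%s' needs a positive baseline", g))
    }
    if (length(cfg$block_effect_ms[[g]]) != cfg$n_blocks ||
        length(cfg$within_block_slope_ms[[g]]) != cfg$n_blocks) {
      fail(sprintf("group '%s': block effect/slope length != n_blocks", g))
    }
    mu_block <- cfg$baseline_ms[[g]] + cfg$block_effect_ms[[g]]
    if (any(mu_block + min(0, min(cfg$event_offset_ms[[g]])) <= 0)) {
      fail(sprintf("group '%s': planted cell means must stay positive", g))
    }
  }
  invisible(cfg)
}

#' @export
print.srt_config <- function(x, ...) {
  cat(sprintf(
    "SRT synthetic-cohort config: %d groups x %d subjects, %d blocks x %d trials\n",
    length(x$groups), x$n_per_group, x$n_blocks, x$block_len))
  cat(sprintf("  baselines: %s; noise %s sd %g ms; subject sd %g ms\n",
              paste(sprintf("%s=%g", x$groups, x$baseline_ms[x$groups]),
                    collapse = ", "),
              x$noise_family, x$noise_sd_ms, x$subject_sd_ms))
  cat(sprintf("  response window %g ms; error rate %g; seed %d\n",
              x$rt_ceiling_ms, x$error_rate, x$seed))
  invisible(x)
}

# zero-mean noise with the requested SD; lognormal uses a fixed shape
# (sdlog = 0.5) and a scale solved so that the SD matches.
.draw_noise <- function(n, sd, family) {
  if (sd == 0) return(rep(0, n))
  if (family == "gaussian") return(stats::rnorm(n, 0, sd))
  s <- 0.5
  m <- log(sd / sqrt(exp(s^2) - 1)) - s^2 / 2
  stats::rlnorm(n, m, s) - exp(m + s^2 / 2)
}

#' Simulate one subject's session
#'
#' Generates the stimulus sequence from the packaged context tree, labels
#' events and last-variable events, then builds each trial's RT as
#' baseline + subject intercept + block effect + within-block sub-block
#' trend + event offset + last-variable interaction + trial noise. Draws
#' falling outside (0, `rt_ceiling_ms`) are redrawn up to 100 times and the
#' trial is marked incorrect if still outside (this avoids a point mass at
#' the window edge). Incorrect trials keep their RT — the task waited for
#' the correct response — and are excluded downstream, not here.
#'
#' @param config an `srt_config`.
#' @param group group label (must appear in `config$groups`).
#' @param subject_id subject identifier string.
#' @param seq_seed,rt_seed integer seeds for the stimulus sequence and for
#'   the response model respectively.
#' @return data.frame with columns `subject_id, group, block,
#'   trial_in_block, stimulus, event, last_var, rt_ms, correct`.
#' @export
simulate_subject <- function(config, group, subject_id = group,
                             seq_seed = config$seed,
                             rt_seed = config$seed + 1L) {
  validate_config(config)
  if (!group %in% config$groups) stop("unknown group: ", group)
  n <- config$n_blocks * config$block_len
  sym <- generate_sequence(srt_tree(), n, seed = seq_seed, initial = "1")
  ev <- label_events(srt_tree(), sym)
  lv <- annotate_last_variable(ev)
  block <- rep(seq_len(config$n_blocks), each = config$block_len)
  tib <- rep(seq_len(config$block_len), config$n_blocks)
  sub_block <- ceiling(tib / config$sub_block_len)

  mu <- config$baseline_ms[[group]] +
    config$block_effect_ms[[group]][block] +
    config$within_block_slope_ms[[group]][block] * (sub_block - 1) +
    config$event_offset_ms[[group]][ev]
  li <- config$lastvar_interaction_ms[[group]]
  haslv <- lv %in% colnames(li) & ev %in% rownames(li)
  mu[haslv] <- mu[haslv] + li[cbind(ev[haslv], lv[haslv])]

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rt_seed)
  intercept <- stats::rnorm(1L, 0, config$subject_sd_ms)
  rt <- mu + intercept + .draw_noise(n, config$noise_sd_ms,
                                     config$noise_family)
  failed <- rep(FALSE, n)
  out_of_window <- function(x) x <= 0 | x >= config$rt_ceiling_ms
  bad <- which(out_of_window(rt))
  tries <- 0L
  while (length(bad) && tries < 100L) {
    rt[bad] <- mu[bad] + intercept +
      .draw_noise(length(bad), config$noise_sd_ms, config$noise_family)
    bad <- bad[out_of_window(rt[bad])]
    tries <- tries + 1L
  }
  if (length(bad)) {
    failed[bad] <- TRUE
    rt[bad] <- pmin(pmax(rt[bad], 1), config$rt_ceiling_ms)
  }
  correct <- stats::runif(n) >= config$error_rate & !failed

  data.frame(subject_id = subject_id, group = group, block = block,
             trial_in_block = tib, stimulus = sym, event = ev,
             last_var = lv, rt_ms = rt, correct = correct,
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Simulates `n_per_group` subjects for every group in the configuration,
#' with per-subject seeds derived deterministically from `config$seed`
#' (identical configurations therefore reproduce byte-identical datasets).
#' When `config$shared_sequence` is TRUE all subjects hear the same stimulus
#' realization; otherwise each subject gets an independent one.
#'
#' @param config an `srt_config`.
#' @return an `srt_cohort` data.frame of stacked subject sessions, with the
#'   configuration and seed attached as attributes.
#' @examples
#' cohort <- simulate_cohort(default_config(n_per_group = 2, block_len = 50))
#' summary(cohort)
#' @export
simulate_cohort <- function(config = default_config()) {
  validate_config(config)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  n_subj <- length(config$groups) * config$n_per_group
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_subj),
                  ncol = 2L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out <- vector("list", n_subj)
  i <- 0L
  for (g in config$groups) {
    for (s in seq_len(config$n_per_group)) {
      i <- i + 1L
      sid <- sprintf("%s%02d", g, s)
      seq_seed <- if (isTRUE(config$shared_sequence)) config$seed else
        seeds[i, 1L]
      out[[i]] <- simulate_subject(config, g, sid,
                                   seq_seed = seq_seed,
                                   rt_seed = seeds[i, 2L])
    }
  }
  cohort <- do.call(rbind, out)
  attr(cohort, "config") <- config
  attr(cohort, "seed") <- config$seed
  class(cohort) <- c("srt_cohort", "data.frame")
  cohort
}

#' @export
summary.srt_cohort <- function(object, ...) {
  cat(sprintf("SRT cohort: %d subjects, %d trials\n",
              length(unique(object$subject_id)), nrow(object)))
  tab <- tapply(object$rt_ms, list(object$group, object$event), mean)
  cat("mean RT (ms) by group x event:\n")
  print(round(tab, 1))
  cat(sprintf("incorrect/missed fraction: %.4f\n", mean(!object$correct)))
  invisible(object)
}

#' Write / read a trial-level cohort CSV
#'
#' The single interchange format for all downstream stages: columns
#' `subject_id, group, block, trial_in_block, stimulus, event, last_var,
#' rt_ms, correct`. Writing then reading reproduces the data exactly
#' (RTs are serialized at full double precision).
#'
#' @param cohort a trial data.frame.
#' @param path file path.
#' @return `read_cohort` returns the data.frame; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  need <- c("subject_id", "group", "block", "trial_in_block", "stimulus",
            "event", "last_var", "rt_ms", "correct")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(cohort)[, need]
  df$rt_ms <- sprintf("%.17g", df$rt_ms)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       group = "character",
                                       stimulus = "character",
                                       event = "character",
                                       last_var = "character",
                                       rt_ms = "numeric",
                                       correct = "logical"))
  df
}
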