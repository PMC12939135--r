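#' Pooled rank transform
#'
#' Ranks a pooled collection of cell means (1..N, average ranks for ties;
#' the Conover-Iman RT-1 convention). Running a classical ANOVA on these
#' ranks gives the rank-transformed ANOVA, robust to monotone
#' transformations and heavy tails of the raw values.
#'
#' @param values numeric vector of finite values.
#' @return numeric vector of ranks aligned with the input.
#' @examples
#' rank_transform(c(10, 10, 30))  # 1.5 1.5 3
#' @export
rank_transform <- function(values) {
  if (!length(values)) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  rank(values, ties.method = "average")
}

# orthonormal contrast matrix (k-1 x k) spanning the space orthogonal to
# the unit vector; built from Helmert contrasts
.ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2L, sqrt(colSums(C^2)), "/")
  t(C)
}

# Greenhouse-Geisser epsilon and Mauchly's sphericity test for a within
# effect, from a subjects x cells matrix and a contrast matrix M (d x cells).
# df_err is the degrees of freedom of the covariance estimate (n - 1 for a
# pure within design, N - g pooled across groups in a split-plot).
.sphericity <- function(M, S, df_err) {
  d <- nrow(M)
  V <- M %*% S %*% t(M)
  eps <- sum(diag(V))^2 / (d * sum(V * V))
  eps <- min(max(eps, 1 / d), 1)
  W <- p <- NA_real_
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (df_err > d && all(ev > .Machine$double.eps * max(ev) * d)) {
    W <- exp(sum(log(ev)) - d * log(mean(ev)))
    # asymptotic expansion with the standard second-order term
    rho <- 1 - (2 * d^2 + d + 2) / (6 * d * df_err)
    z <- -df_err * rho * log(W)
    f <- d * (d + 1) / 2 - 1
    w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
      (288 * (df_err * d * rho)^2)
    pr1 <- stats::pchisq(z, f, lower.tail = FALSE)
    pr2 <- stats::pchisq(z, f + 4, lower.tail = FALSE)
    p <- pr1 + w2 * (pr2 - pr1)
  }
  list(epsilon = eps, W = W, p = p)
}

# F ratio with the degenerate conventions: a zero effect mean square gives
# F = 0 (e.g. constant data), a zero error mean square with a positive
# effect gives Inf
.f_ratio <- function(ss_eff, df_eff, ss_err, df_err) {
  ms_eff <- ss_eff / df_eff
  ms_err <- ss_err / df_err
  if (ms_eff <= 1e-300) return(0)
  if (ms_err <= 0) return(Inf)
  ms_eff / ms_err
}

# complete-case reduction: keep subjects holding exactly one value in every
# cell of the crossing; warn about the dropped ones
.complete_cases <- function(data, subject, cells) {
  tab <- table(data[[subject]], cells)
  ok <- rownames(tab)[apply(tab, 1L, function(r) all(r == 1L))]
  dropped <- setdiff(rownames(tab), ok)
  if (length(dropped)) {
    warning("dropping subject(s) without a complete cell set: ",
            paste(dropped, collapse = ", "))
  }
  if (length(ok) < 2L) stop("fewer than 2 complete-case subjects")
  data[data[[subject]] %in% ok, , drop = FALSE]
}

.new_anova_table <- function(rows, n_subjects, note = NULL) {
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  structure(out, class = c("srt_anova", "data.frame"),
            n_subjects = n_subjects, note = note)
}

#' @export
print.srt_anova <- function(x, digits = 4, ...) {
  note <- attr(x, "note")
  cat(sprintf("ANOVA (%d subjects%s)\n", attr(x, "n_subjects"),
              if (is.null(note)) "" else paste0("; ", note)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  if (any(!is.na(x$p_gg) & x$correction_applied)) {
    cat("p_gg: Greenhouse-Geisser corrected p (applied where Mauchly p < 0.05)\n")
  }
  invisible(x)
}

#' Two-way repeated-measures ANOVA
#'
#' Classical balanced two-way repeated-measures decomposition on per-subject
#' cell means: each within effect is tested against its own
#' subject-by-effect error stratum. For effects with more than one
#' numerator degree of freedom, Mauchly's sphericity test is run and a
#' Greenhouse-Geisser corrected p-value is reported alongside the raw one;
#' `correction_applied` flags effects where Mauchly's p < 0.05. With
#' `use_ranks = TRUE` the analysis runs on the pooled rank transform of the
#' cell means (the robust variant used for block-by-event designs).
#'
#' Subjects missing any cell of the crossing are removed (complete-case)
#' with a warning.
#'
#' @param data cell-mean data.frame (e.g. from [cell_means()]).
#' @param within character vector of the two within-subject factor columns.
#' @param dv name of the value column (default `"mean_rt"`).
#' @param subject name of the subject id column.
#' @param use_ranks run on pooled ranks of the dv.
#' @return an `srt_anova` data.frame: one row per effect with `F`, `df_num`,
#'   `df_den`, `p`, `epsilon_gg`, `p_gg`, `mauchly_W`, `mauchly_p`,
#'   `correction_applied`.
#' @examples
#' cfg <- default_config(n_per_group = 4, block_len = 50)
#' cm <- cell_means(filter_trials(simulate_cohort(cfg))$trials)
#' rm_anova2(cm[cm$group == "MI", ], within = c("block", "event"),
#'           use_ranks = TRUE)
#' @export
rm_anova2 <- function(data, within = c("block", "event"), dv = "mean_rt",
                      subject = "subject_id", use_ranks = FALSE) {
  stopifnot(length(within) == 2L)
  miss <- setdiff(c(subject, within, dv), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  f1 <- factor(data[[within[1]]])
  f2 <- factor(data[[within[2]]])
  a <- nlevels(f1); b <- nlevels(f2)
  if (a < 2L || b < 2L) stop("each within factor needs >= 2 levels")
  cells <- interaction(f1, f2, drop = FALSE)
  data <- .complete_cases(data, subject, cells)
  f1 <- factor(data[[within[1]]]); f2 <- factor(data[[within[2]]])
  subj <- factor(data[[subject]])
  n <- nlevels(subj)
  y <- data[[dv]]
  if (any(!is.finite(y))) stop("non-finite values in dv")
  if (use_ranks) y <- rank_transform(y)

  Y <- array(NA_real_, c(n, a, b))
  Y[cbind(as.integer(subj), as.integer(f1), as.integer(f2))] <- y
  gm <- mean(Y)
  m_s <- apply(Y, 1L, mean); m_a <- apply(Y, 2L, mean)
  m_b <- apply(Y, 3L, mean)
  m_sa <- apply(Y, c(1L, 2L), mean); m_sb <- apply(Y, c(1L, 3L), mean)
  m_ab <- apply(Y, c(2L, 3L), mean)

  ss_a  <- n * b * sum((m_a - gm)^2)
  ss_b  <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + gm)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + gm)^2)
  ss_s  <- a * b * sum((m_s - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_as - ss_bs - ss_s

  eff <- function(name, ss_eff, df_eff, ss_err, df_err, sph) {
    Fv <- .f_ratio(ss_eff, df_eff, ss_err, df_err)
    p <- stats::pf(Fv, df_eff, df_err, lower.tail = FALSE)
    eps <- if (is.null(sph)) NA_real_ else sph$epsilon
    p_gg <- if (is.null(sph)) NA_real_ else
      stats::pf(Fv, eps * df_eff, eps * df_err, lower.tail = FALSE)
    list(effect = name, df_num = df_eff, df_den = df_err, F = Fv, p = p,
         epsilon_gg = eps, p_gg = p_gg,
         mauchly_W = if (is.null(sph)) NA_real_ else sph$W,
         mauchly_p = if (is.null(sph)) NA_real_ else sph$p,
         correction_applied = !is.null(sph) && !is.na(sph$p) && sph$p < 0.05)
  }
  Yc <- matrix(Y, n, a * b)              # cells vary: f1 fastest
  S <- stats::cov(Yc)
  Ma <- .ortho_contrasts(a); Mb <- .ortho_contrasts(b)
  avg_b <- kronecker(matrix(1 / b, b, 1), diag(a))  # (ab x a) average over f2
  avg_a <- kronecker(diag(b), matrix(1 / a, 1, a))
  sph_a <- if (a > 2) .sphericity(Ma %*% t(avg_b), S, n - 1) else NULL
  sph_b <- if (b > 2) .sphericity(Mb %*% avg_a, S, n - 1) else NULL
  sph_ab <- if (a > 2 || b > 2) {
    .sphericity(kronecker(Mb, Ma), S, n - 1)
  } else NULL

  .new_anova_table(list(
    eff(within[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1), sph_a),
    eff(within[2], ss_b, b - 1, ss_bs, (b - 1) * (n - 1), sph_b),
    eff(paste(within, collapse = ":"), ss_ab, (a - 1) * (b - 1),
        ss_abs, (a - 1) * (b - 1) * (n - 1), sph_ab)),
    n_subjects = n,
    note = paste0("repeated measures",
                  if (use_ranks) ", rank-transformed"))
}

#' Two-way mixed (split-plot) ANOVA
#'
#' One between-subjects factor (e.g. group) crossed with one
#' within-subjects factor (e.g. event type), on per-subject cell means.
#' The between effect is tested against subjects-within-groups; the within
#' effect and the interaction are tested against the within-subject error
#' stratum. Sphericity of the within factor is assessed with Mauchly's test
#' on the covariance matrix pooled across groups, with Greenhouse-Geisser
#' corrected p-values reported as in [rm_anova2()].
#'
#' @param data cell-mean data.frame.
#' @param between name of the between-subjects factor column.
#' @param within name of the within-subjects factor column.
#' @inheritParams rm_anova2
#' @return an `srt_anova` table with rows for the between effect, the
#'   within effect and their interaction.
#' @export
mixed_anova <- function(data, between = "group", within = "event",
                        dv = "mean_rt", subject = "subject_id",
                        use_ranks = FALSE) {
  miss <- setdiff(c(subject, between, within, dv), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  w <- factor(data[[within]])
  k <- nlevels(w)
  if (k < 2L) stop("within factor needs >= 2 levels")
  data <- .complete_cases(data, subject, w)
  gtab <- unique(data[c(subject, between)])
  if (anyDuplicated(gtab[[subject]])) {
    stop("each subject must belong to exactly one between level")
  }
  w <- factor(data[[within]])
  g <- factor(data[[between]])
  if (nlevels(g) < 2L) stop("between factor needs >= 2 levels")
  subj <- factor(data[[subject]])
  y <- data[[dv]]
  if (any(!is.finite(y))) stop("non-finite values in dv")
  if (use_ranks) y <- rank_transform(y)

  N <- nlevels(subj); ng <- nlevels(g)
  # subjects x within matrix plus each subject's group
  Y <- matrix(NA_real_, N, k, dimnames = list(levels(subj), levels(w)))
  Y[cbind(as.integer(subj), as.integer(w))] <- y
  grp <- factor(gtab[[between]][match(levels(subj), gtab[[subject]])],
                levels = levels(g))
  n_g <- as.integer(table(grp))
  gm <- mean(Y)
  m_subj <- rowMeans(Y)
  m_g <- tapply(m_subj, grp, mean)
  m_w <- colMeans(Y)
  m_gw <- apply(Y, 2L, function(col) tapply(col, grp, mean))  # g x k

  ss_g  <- k * sum(n_g * (m_g - gm)^2)
  ss_sg <- k * sum((m_subj - m_g[as.integer(grp)])^2)
  ss_w  <- N * sum((m_w - gm)^2)
  ss_gw <- sum(n_g * (m_gw - outer(m_g, rep(1, k)) -
                        outer(rep(1, ng), m_w) + gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_res <- ss_tot - ss_g - ss_sg - ss_w - ss_gw

  df_g <- ng - 1L; df_sg <- N - ng
  df_w <- k - 1L; df_gw <- (ng - 1L) * (k - 1L)
  df_res <- (k - 1L) * (N - ng)

  sph <- NULL
  if (k > 2) {
    Sp <- matrix(0, k, k)
    for (gl in levels(grp)) {
      rows <- Y[grp == gl, , drop = FALSE]
      if (nrow(rows) > 1L) Sp <- Sp + (nrow(rows) - 1L) * stats::cov(rows)
    }
    Sp <- Sp / df_sg
    sph <- .sphericity(.ortho_contrasts(k), Sp, df_sg)
  }

  eff <- function(name, ss_eff, df_eff, ss_err, df_err, s) {
    Fv <- .f_ratio(ss_eff, df_eff, ss_err, df_err)
    p <- stats::pf(Fv, df_eff, df_err, lower.tail = FALSE)
    eps <- if (is.null(s)) NA_real_ else s$epsilon
    list(effect = name, df_num = df_eff, df_den = df_err, F = Fv, p = p,
         epsilon_gg = eps,
         p_gg = if (is.null(s)) NA_real_ else
           stats::pf(Fv, eps * df_eff, eps * df_err, lower.tail = FALSE),
         mauchly_W = if (is.null(s)) NA_real_ else s$W,
         mauchly_p = if (is.null(s)) NA_real_ else s$p,
         correction_applied = !is.null(s) && !is.na(s$p) && s$p < 0.05)
  }
  .new_anova_table(list(
    eff(between, ss_g, df_g, ss_sg, df_sg, NULL),
    eff(within, ss_w, df_w, ss_res, df_res, sph),
    eff(paste(between, within, sep = ":"), ss_gw, df_gw, ss_res, df_res,
        sph)),
    n_subjects = N, note = "mixed (split-plot)")
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Follow-up t-tests for all level pairs of a factor: paired t-tests on
#' subject-aligned cell means for within-subject factors, Welch two-sample
#' t-tests for between-subject factors. Adjusted p-values are
#' `min(1, m * p)` with `m` the number of comparisons in the family (the
#' number of rows returned); significance tiers follow the usual figure
#' convention (`p<0.05`, `p<0.01`, `ns`). With `split_by`, comparisons are
#' run separately within each level of another factor (simple effects) and
#' the family spans all of them.
#'
#' @param data cell-mean data.frame.
#' @param factor_name column whose levels are compared.
#' @param dv,subject value and subject id columns.
#' @param paired use paired t-tests (subjects aligned across levels).
#' @param split_by optional column defining simple-effect strata.
#' @return a `data.frame` with class `srt_pairwise`: one row per comparison
#'   with `t`, `df`, `p_raw`, `p_bonf`, `m`, `tier` (`zero_variance` flags
#'   degenerate pairs whose p is undefined).
#' @export
pairwise_bonferroni <- function(data, factor_name, dv = "mean_rt",
                                subject = "subject_id", paired = TRUE,
                                split_by = NULL) {
  miss <- setdiff(c(factor_name, dv, subject, split_by), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lv <- levels(factor(data[[factor_name]]))
  if (length(lv) < 2L) stop("need >= 2 levels to compare")
  strata <- if (is.null(split_by)) list(all = data) else
    split(data, data[[split_by]])
  rows <- list()
  for (sname in names(strata)) {
    d <- strata[[sname]]
    for (i in seq_len(length(lv) - 1L)) {
      for (j in (i + 1L):length(lv)) {
        x <- d[d[[factor_name]] == lv[i], c(subject, dv)]
        y <- d[d[[factor_name]] == lv[j], c(subject, dv)]
        if (paired) {
          common <- intersect(x[[subject]], y[[subject]])
          xv <- x[[dv]][match(common, x[[subject]])]
          yv <- y[[dv]][match(common, y[[subject]])]
          diffs <- xv - yv
          if (length(diffs) < 2L || stats::sd(diffs) == 0) {
            tt <- NULL
          } else tt <- stats::t.test(xv, yv, paired = TRUE)
        } else {
          xv <- x[[dv]]; yv <- y[[dv]]
          if (length(xv) < 2L || length(yv) < 2L ||
              (stats::sd(xv) == 0 && stats::sd(yv) == 0)) {
            tt <- NULL
          } else tt <- stats::t.test(xv, yv)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = sname, level_1 = lv[i], level_2 = lv[j],
          mean_diff = mean(xv) - mean(yv),
          t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
          df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
          p_raw = if (is.null(tt)) NA_real_ else tt$p.value,
          zero_variance = is.null(tt))
      }
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$m <- m
  out$p_bonf <- pmin(1, m * out$p_raw)
  out$tier <- ifelse(is.na(out$p_bonf), NA_character_,
                     ifelse(out$p_bonf < 0.01, "p<0.01",
                            ifelse(out$p_bonf < 0.05, "p<0.05", "ns")))
  if (is.null(split_by)) out$stratum <- NULL
  rownames(out) <- NULL
  class(out) <- c("srt_pairwise", "data.frame")
  out
}

#' Within-block learning: sub-block slopes and one-sample t-tests
#'
#' For every subject and block, fits an ordinary least-squares line to the
#' mean RTs of the consecutive 50-trial sub-blocks (regressor 1, 2, 3) and
#' keeps its slope (ms per sub-block). Then, per group and block, runs a
#' two-sided one-sample t-test of the subjects' slopes against zero
#' (df = n_subjects - 1). Negative mean slopes indicate RTs shrinking
#' towards the end of a block, i.e. within-block learning.
#'
#' @param table sub-block mean table from [subblock_means()].
#' @param dv value column (default `"mean_rt"`).
#' @return list of class `srt_slopes` with `slopes` (subject x block OLS
#'   slopes) and `tests` (per group x block: mean slope, t, df, p;
#'   zero-variance slope sets are flagged with `p = NA`).
#' @export
subblock_slope_test <- function(table, dv = "mean_rt") {
  miss <- setdiff(c("subject_id", "group", "block", "sub_block", dv),
                  names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ols_slope <- function(x, y) {
    xc <- x - mean(x)
    if (sum(xc^2) == 0) return(NA_real_)   # a single sub-block has no slope
    sum(xc * (y - mean(y))) / sum(xc^2)
  }
  sl <- do.call(rbind, lapply(
    split(table, table[c("subject_id", "block")], drop = TRUE),
    function(d) data.frame(subject_id = d$subject_id[1L],
                           group = d$group[1L], block = d$block[1L],
                           slope = ols_slope(d$sub_block, d[[dv]]))))
  rownames(sl) <- NULL
  sl <- sl[order(sl$group, sl$block, sl$subject_id), ]
  tests <- do.call(rbind, lapply(
    split(sl, sl[c("group", "block")], drop = TRUE),
    function(d) {
      degenerate <- nrow(d) < 2L || anyNA(d$slope) ||
        stats::sd(d$slope) == 0
      tt <- if (!degenerate) stats::t.test(d$slope, mu = 0)
      data.frame(group = d$group[1L], block = d$block[1L],
                 n = nrow(d), mean_slope = mean(d$slope),
                 t = if (degenerate) NA_real_ else unname(tt$statistic),
                 df = nrow(d) - 1L,
                 p = if (degenerate) NA_real_ else tt$p.value,
                 zero_variance = degenerate)
    }))
  rownames(tests) <- NULL
  tests <- tests[order(tests$group, tests$block), ]
  structure(list(slopes = sl, tests = tests), class = "srt_slopes")
}

#' @export
print.srt_slopes <- function(x, digits = 4, ...) {
  cat("Per-subject sub-block slopes: one-sample two-sided t-tests vs 0\n")
  df <- x$tests
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Event-by-last-variable-event repeated-measures ANOVA
#'
#' The conditioning analysis: per-subject mean RTs for each event type given
#' the immediately preceding variable event (V2 or V3) enter a two-way
#' repeated-measures ANOVA with factors event and last variable event. For
#' 10 subjects and 4 events the design yields df (3, 27) for event, (1, 9)
#' for the last variable event and (3, 27) for their interaction.
#'
#' @param data cell-mean data.frame keyed by subject, `event` and
#'   `last_var` (from `cell_means(..., factors = c("event", "last_var"))`).
#' @inheritParams rm_anova2
#' @return an `srt_anova` table.
#' @export
lastvar_rm_anova <- function(data, dv = "mean_rt", subject = "subject_id",
                             use_ranks = FALSE) {
  rm_anova2(data, within = c("event", "last_var"), dv = dv,
            subject = subject, use_ranks = use_ranks)
}
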