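# Independent brute-force oracles for the ANOVA decompositions: fit the full
# general linear model with lm() and assemble the F ratios from its
# sequential sums of squares (orthogonal for the balanced designs used
# here). These never touch the package's own sums-of-squares code path.

oracle_rm2 <- function(data, within, dv = "mean_rt",
                       subject = "subject_id", use_ranks = FALSE) {
  y <- data[[dv]]
  if (use_ranks) y <- rank(y, ties.method = "average")
  S <- factor(data[[subject]])
  A <- factor(data[[within[1]]])
  B <- factor(data[[within[2]]])
  tab <- suppressWarnings(anova(lm(y ~ S * A * B)))
  ss <- stats::setNames(tab[["Sum Sq"]], rownames(tab))
  df <- stats::setNames(tab[["Df"]], rownames(tab))
  eff <- function(e, err) {
    Fv <- (ss[[e]] / df[[e]]) / (ss[[err]] / df[[err]])
    c(F = Fv, df_num = df[[e]], df_den = df[[err]],
      p = pf(Fv, df[[e]], df[[err]], lower.tail = FALSE))
  }
  rbind(eff("A", "S:A"), eff("B", "S:B"), eff("A:B", "S:A:B"))
}

oracle_mixed <- function(data, between = "group", within = "event",
                         dv = "mean_rt", subject = "subject_id") {
  y <- data[[dv]]
  G <- factor(data[[between]])
  W <- factor(data[[within]])
  S <- factor(data[[subject]])
  tab <- suppressWarnings(anova(lm(y ~ G * W + G:S)))
  ss <- stats::setNames(tab[["Sum Sq"]], rownames(tab))
  df <- stats::setNames(tab[["Df"]], rownames(tab))
  eff <- function(e, err) {
    Fv <- (ss[[e]] / df[[e]]) / (ss[[err]] / df[[err]])
    c(F = Fv, df_num = df[[e]], df_den = df[[err]],
      p = pf(Fv, df[[e]], df[[err]], lower.tail = FALSE))
  }
  rbind(eff("G", "G:S"), eff("W", "Residuals"), eff("G:W", "Residuals"))
}

# random balanced cell-mean tables for oracle comparisons
random_rm_table <- function(n, a, b) {
  grid <- expand.grid(subject_id = sprintf("s%02d", seq_len(n)),
                      w1 = paste0("a", seq_len(a)),
                      w2 = paste0("b", seq_len(b)),
                      stringsAsFactors = FALSE)
  grid$mean_rt <- rnorm(nrow(grid), 500, 80)
  grid
}

random_mixed_table <- function(n_per_group, w) {
  grid <- expand.grid(subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
                      event = paste0("e", seq_len(w)),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("s", "", grid$subject_id)) <=
                         n_per_group, "ME", "MI")
  grid$mean_rt <- rnorm(nrow(grid), 600, 90)
  grid
}
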