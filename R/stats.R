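# Condition-level inference: one-way repeated-measures ANOVA with
# participant as the random effect, and Sidak-corrected paired post hoc
# t-tests. For a complete, balanced one-way within-subject design the
# classical decomposition is identical to the mixed-model ANOVA:
# F = MS_condition / MS_(condition x participant), with degrees of freedom
# (k - 1) and (k - 1)(n - 1).

#' Repeated-measures one-way ANOVA
#'
#' @param data Long-format data frame.
#' @param value,participant,condition Column names (strings) of the
#'   outcome, participant id and condition factor.
#' @return Object of class `rm_anova`: list with `F`, `df1`, `df2`, `p`,
#'   the condition means, and the sums of squares. Requires a complete
#'   crossed design (every participant observed once per condition); an
#'   incomplete design is an error, never silently imputed.
#' @export
#' @examples
#' d <- emit_cohort(6, outcomes_only = TRUE, seed = 42)
#' rm_anova(d)
rm_anova <- function(data, value = "value", participant = "participant",
                     condition = "condition") {
  y <- data[[value]]
  pid <- factor(data[[participant]])
  cond <- factor(data[[condition]])
  if (is.null(y) || is.null(pid) || is.null(cond))
    stop("`data` must contain the value, participant and condition columns.")
  tab <- table(pid, cond)
  if (any(tab != 1L))
    stop("incomplete or unbalanced design: every participant must be observed exactly once per condition.")
  n <- nlevels(pid); k <- nlevels(cond)
  if (n < 2L || k < 2L)
    stop("need at least 2 participants and 2 conditions.")
  gm <- mean(y)
  cond_means <- tapply(y, cond, mean)
  subj_means <- tapply(y, pid, mean)
  ss_cond <- n * sum((cond_means - gm)^2)
  ss_subj <- k * sum((subj_means - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_cond / ms_err else
    ifelse(ms_cond > 0, Inf, 0)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(F = f, df1 = df1, df2 = df2, p = p,
                 condition_means = cond_means,
                 ss = c(condition = ss_cond, participant = ss_subj,
                        error = ss_err, total = ss_tot),
                 n_participants = n, n_conditions = k),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Sidak-corrected paired post hoc t-tests
#'
#' All `k (k - 1) / 2` pairwise paired t-tests on participant-wise
#' differences, with Sidak adjustment `p_adj = 1 - (1 - p)^m` where `m` is
#' the number of comparisons. By default the tests are gated on a
#' significant ANOVA main effect at `alpha`; set `gated = FALSE` to run
#' them regardless.
#'
#' @inheritParams rm_anova
#' @param anova Optional precomputed [rm_anova()] result for this outcome.
#' @param alpha Gate significance level, default 0.05.
#' @param gated Run post hoc tests only when the main effect is
#'   significant, default `TRUE`.
#' @return Data frame with one row per pair: `condition_a`, `condition_b`,
#'   `difference` (mean of a - b), `t`, `p_raw`, `p_sidak`, and
#'   `zero_variance` (flagged when the paired differences have zero
#'   variance, in which case p is reported as exactly 1 for identically
#'   zero differences and 0 otherwise). Empty (zero rows) when gated and
#'   the main effect is not significant.
#' @export
posthoc_sidak <- function(data, value = "value", participant = "participant",
                          condition = "condition", anova = NULL,
                          alpha = 0.05, gated = TRUE) {
  if (is.null(anova))
    anova <- rm_anova(data, value, participant, condition)
  empty <- data.frame(condition_a = character(), condition_b = character(),
                      difference = numeric(), t = numeric(),
                      p_raw = numeric(), p_sidak = numeric(),
                      zero_variance = logical())
  if (gated && anova$p > alpha) return(empty)
  y <- data[[value]]
  pid <- factor(data[[participant]])
  cond <- factor(data[[condition]])
  lev <- levels(cond)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ya <- y[cond == a][order(pid[cond == a])]
    yb <- y[cond == b][order(pid[cond == b])]
    d <- ya - yb
    if (stats::sd(d) == 0) {
      praw <- if (all(d == 0)) 1 else 0
      tval <- if (all(d == 0)) 0 else Inf * sign(mean(d))
      zv <- TRUE
    } else {
      tt <- stats::t.test(d)
      praw <- tt$p.value
      tval <- unname(tt$statistic)
      zv <- FALSE
    }
    data.frame(condition_a = a, condition_b = b, difference = mean(d),
               t = tval, p_raw = praw,
               p_sidak = 1 - (1 - praw)^m, zero_variance = zv)
  })
  do.call(rbind, rows)
}
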