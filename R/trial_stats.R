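# The trial's statistical layer: normality checks, the 2 (group) x 2 (time)
# mixed-design ANOVA with a generic Greenhouse-Geisser guard, Bonferroni
# post-hoc cell contrasts, and bias-corrected standardized mean differences.
#
# With one between-subjects factor (group) and a two-level within-subjects
# factor (time) the classical sums of squares have closed forms in terms of
# per-subject means m_ij = (y_ij,W0 + y_ij,W3)/2 and half-differences
# c_ij = (y_ij,W3 - y_ij,W0)/2:
#   between-subject stratum: SS_G = 2 * sum_i n_i (mbar_i - mbar)^2,
#                            SS_errB = 2 * sum_ij (m_ij - mbar_i)^2
#   within-subject stratum:  SS_T = 2 N cbar^2,
#                            SS_GxT = 2 * sum_i n_i (cbar_i - cbar)^2,
#                            SS_errW = 2 * sum_ij (c_ij - cbar_i)^2
# (N subjects in total; time is orthogonal to the between design because
# every subject contributes both timepoints, so these equal the sequential
# sums of squares of the classical aov decomposition.) Computing them
# directly keeps a single fit O(N), which matters for the type-I-error
# calibration simulations.

#' Shapiro-Wilk normality check
#'
#' @param sample numeric vector, n >= 3, non-constant.
#' @return list with `W` and `p`.
#' @export
check_normality <- function(sample) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 3L) stop_domain("need at least 3 values")
  if (var(sample) == 0) stop_domain("sample is constant; normality undefined")
  s <- shapiro.test(sample)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Greenhouse-Geisser sphericity correction factor
#'
#' Generic for any number of within-subject levels; with two levels there
#' is a single within-subject contrast and epsilon is exactly 1, so the
#' correction is a no-op in a W0/W3 design.
#'
#' @param S covariance matrix (k x k) of the within-subject measures.
#' @return epsilon in \[1/(k-1), 1\].
#' @export
gg_epsilon <- function(S) {
  k <- nrow(S)
  if (k < 2L) stop_domain("need at least two within-subject levels")
  M <- qr.Q(qr(stats::contr.helmert(k)))  # orthonormal contrasts
  E <- t(M) %*% S %*% M
  (sum(diag(E)))^2 / ((k - 1) * sum(E^2))
}

#' Two-by-two mixed-design ANOVA (group x time)
#'
#' Classical repeated-measures ANOVA with a between-subjects group factor
#' and a two-level within-subjects time factor, computed from the closed-form
#' sums-of-squares decomposition above. Subjects missing a timepoint are
#' excluded with a warning. Bonferroni-adjusted post-hoc cell contrasts
#' (within-group W0 vs W3, paired; between-group at each timepoint, pooled
#' two-sample; family size 4) are always reported, flagged for use when the
#' interaction is significant.
#'
#' @param table a [trial_table()].
#' @param outcome outcome column name.
#' @param alpha significance level used only to flag the interaction.
#' @return an object of class `anova_result`: `effects` (data.frame with
#'   rows G, T, GxT: F, df1, df2, p, epsilon), `posthoc` (data.frame of the
#'   four contrasts with raw and adjusted p), `n_per_group`, `outcome`,
#'   `interaction_significant`.
#' @export
mixed_anova_2x2 <- function(table, outcome, alpha = 0.05) {
  if (!outcome %in% names(table)) stop_domain("unknown outcome: ", outcome)
  w0 <- table[table$timepoint == "W0", c("subject_id", "group", outcome)]
  w3 <- table[table$timepoint == "W3", c("subject_id", "group", outcome)]
  m <- merge(w0, w3, by = c("subject_id", "group"),
             suffixes = c("_w0", "_w3"))
  m <- m[complete.cases(m), , drop = FALSE]
  n_all <- length(unique(table$subject_id))
  if (nrow(m) < n_all)
    warning(n_all - nrow(m), " subject(s) without both timepoints excluded",
            call. = FALSE)
  groups <- sort(unique(m$group))
  if (length(groups) != 2L)
    stop_domain("need exactly 2 groups; found: ",
                paste(groups, collapse = ", "))
  n_i <- table(factor(m$group, levels = groups))
  if (any(n_i < 2L)) stop_domain("need at least 2 subjects per group")
  y0 <- m[[paste0(outcome, "_w0")]]; y3 <- m[[paste0(outcome, "_w3")]]
  g <- factor(m$group, levels = groups)
  N <- nrow(m)
  mm <- (y0 + y3) / 2; cc <- (y3 - y0) / 2
  mbar_i <- tapply(mm, g, mean); cbar_i <- tapply(cc, g, mean)
  mbar <- mean(mm); cbar <- mean(cc)
  n_vec <- as.numeric(n_i)
  ss_g <- 2 * sum(n_vec * (mbar_i - mbar)^2)
  ss_errb <- 2 * sum((mm - mbar_i[g])^2)
  ss_t <- 2 * N * cbar^2
  ss_gt <- 2 * sum(n_vec * (cbar_i - cbar)^2)
  ss_errw <- 2 * sum((cc - cbar_i[g])^2)
  df_err <- N - 2L
  eps <- gg_epsilon(stats::cov(cbind(y0, y3)))  # identically 1 for 2 levels
  Fv <- c(G = ss_g / (ss_errb / df_err),
          T = ss_t / (ss_errw / df_err),
          `GxT` = ss_gt / (ss_errw / df_err))
  p <- pf(Fv, 1 * eps, df_err * eps, lower.tail = FALSE)
  effects <- data.frame(effect = c("G", "T", "GxT"), F = unname(Fv),
                        df1 = 1, df2 = df_err, p = unname(p), epsilon = eps,
                        ss = c(ss_g, ss_t, ss_gt),
                        ss_error = c(ss_errb, ss_errw, ss_errw))
  posthoc <- rbind(
    posthoc_paired(paste0("W0 vs W3 (", groups[1], ")"),
                   y0[g == groups[1]], y3[g == groups[1]]),
    posthoc_paired(paste0("W0 vs W3 (", groups[2], ")"),
                   y0[g == groups[2]], y3[g == groups[2]]),
    posthoc_twosample(paste0(groups[1], " vs ", groups[2], " at W0"),
                      y0[g == groups[1]], y0[g == groups[2]]),
    posthoc_twosample(paste0(groups[1], " vs ", groups[2], " at W3"),
                      y3[g == groups[1]], y3[g == groups[2]]))
  posthoc$p_adj <- pmin(1, 4 * posthoc$p)
  res <- list(effects = effects, posthoc = posthoc,
              n_per_group = setNames(n_vec, groups), outcome = outcome,
              interaction_significant = unname(p["GxT"] < alpha))
  class(res) <- "anova_result"
  res
}

posthoc_paired <- function(label, a, b) {
  d <- b - a
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  data.frame(contrast = label, estimate = mean(d), t = t,
             df = length(d) - 1L,
             p = 2 * pt(-abs(t), length(d) - 1L))
}

posthoc_twosample <- function(label, a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  data.frame(contrast = label, estimate = mean(a) - mean(b), t = t,
             df = na + nb - 2L, p = 2 * pt(-abs(t), na + nb - 2L))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> outcome %s (n = %s)\n", x$outcome,
              paste(x$n_per_group, collapse = "/")))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-4s F(%g, %g) = %8.3f, p = %.4g\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i]))
  invisible(x)
}

#' Bias-corrected standardized mean difference (Hedges' g)
#'
#' Pooled-SD standardized difference of two samples multiplied by the
#' small-sample correction 1 - 3/(4 df - 1), df = n_a + n_b - 2; labelled
#' small (|g| < 0.20), large (|g| >= 0.50) or medium. Antisymmetric under
#' swapping the samples. Typically applied to pre-post change scores of
#' the two groups.
#'
#' @param group_a,group_b numeric vectors, n >= 2 each.
#' @return list of class `effect_size`: `g`, `label`, `correction`,
#'   `defined` (FALSE when the pooled SD is zero).
#' @export
hedges_g <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop_domain("need at least 2 values per group")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / df
  J <- 1 - 3 / (4 * df - 1)
  if (sp2 == 0)
    return(structure(list(g = NA_real_, label = NA_character_,
                          correction = J, defined = FALSE),
                     class = "effect_size"))
  g <- J * (mean(group_a) - mean(group_b)) / sqrt(sp2)
  label <- if (abs(g) < 0.20) "small" else if (abs(g) >= 0.50) "large"
           else "medium"
  structure(list(g = g, label = label, correction = J, defined = TRUE),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> g = %.3f (%s)\n", x$g, x$label))
  invisible(x)
}

#' Group x time summary table with trial statistics
#'
#' Mean +/- SD per group and timepoint for each outcome, with the three
#' mixed-ANOVA p-values (group, time, group x time) and the bias-corrected
#' effect size of the between-group difference in pre-post change.
#'
#' @param cohort a [trial_table()].
#' @param outcomes outcome columns to include (default all).
#' @param digits significant digits for the mean +/- SD strings.
#' @return a data.frame, one row per outcome.
#' @export
build_table1 <- function(cohort, outcomes = NULL, digits = 3) {
  if (nrow(cohort) == 0L) stop_domain("empty cohort")
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2L)
    stop_domain("cohort must contain both groups; found only: ",
                paste(groups, collapse = ", "))
  outcomes <- outcomes %||% trial_outcomes(cohort)
  units <- attr(cohort, "units")
  fmt_cell <- function(v) {
    sprintf("%s ± %s", signif(mean(v), digits),
            signif(sd(v), max(digits - 1, 1)))
  }
  rows <- lapply(outcomes, function(oc) {
    an <- mixed_anova_2x2(cohort, oc)
    cells <- sapply(groups, function(gr) sapply(c("W0", "W3"), function(tp) {
      v <- cohort[[oc]][cohort$group == gr & cohort$timepoint == tp]
      fmt_cell(v[is.finite(v)])
    }))
    delta <- function(gr) {
      w0 <- cohort[cohort$group == gr & cohort$timepoint == "W0",
                   c("subject_id", oc)]
      w3 <- cohort[cohort$group == gr & cohort$timepoint == "W3",
                   c("subject_id", oc)]
      mm <- merge(w0, w3, by = "subject_id")
      mm[[3L]] - mm[[2L]]
    }
    es <- hedges_g(delta(groups[1L]), delta(groups[2L]))
    p <- setNames(an$effects$p, an$effects$effect)
    data.frame(outcome = oc, unit = unname(units[oc]),
               comb_w0 = cells[1, 1], comb_w3 = cells[2, 1],
               mict_w0 = cells[1, 2], mict_w3 = cells[2, 2],
               p_G = p[["G"]], p_T = p[["T"]], p_GxT = p[["GxT"]],
               es = if (es$defined) es$g else NA_real_,
               es_label = if (es$defined) es$label else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[3:6] <- c(paste0(groups[1L], c("_W0", "_W3")),
                       paste0(groups[2L], c("_W0", "_W3")))
  rownames(out) <- NULL
  out
}
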