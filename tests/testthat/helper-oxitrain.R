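# Shared fixtures, built in code.

# Constant-valued gas series of `minutes` minutes at `dt`-second sampling.
constant_series <- function(vo2, vco2, minutes, dt = 5, hr = NULL, ...) {
  n <- minutes * 60 / dt
  gas_series(t = seq(0, by = dt, length.out = n),
             vo2 = rep(vo2, n), vco2 = rep(vco2, n),
             hr = if (is.null(hr)) NULL else rep_len(hr, n),
             dt_nominal = dt, ...)
}

# Minimal graded_result stub for prescription tests.
fake_graded_result <- function(intensity, hr, vo2peak, hrpeak = max(hr),
                               rest_hr = NA_real_) {
  structure(list(vo2peak = vo2peak, hrpeak = hrpeak, rest_hr = rest_hr,
                 stages = data.frame(intensity = intensity, hr = hr)),
            class = "graded_result")
}

# Small random long-format trial table (balanced or not).
random_trial_table <- function(n_comb, n_mict, mu = 0) {
  n <- n_comb + n_mict
  data <- data.frame(
    subject_id = rep(sprintf("s%03d", seq_len(n)), each = 2),
    group = rep(c(rep("COMB", n_comb), rep("MICT", n_mict)), each = 2),
    timepoint = rep(c("W0", "W3"), n),
    y = rnorm(2 * n, mu))
  trial_table(data, c(y = "unit"))
}

# Independent brute-force oracle for the 2x2 mixed ANOVA: explicit design
# matrices solved through the normal equations, F statistics from nested
# residual sums of squares (within-subject stratum) and from the subject-sum
# regression (between-subject stratum). Shares no code with the package.
anova22_oracle <- function(table, outcome = "y") {
  w0 <- table[table$timepoint == "W0", ]
  w3 <- table[table$timepoint == "W3", ]
  w3 <- w3[match(w0$subject_id, w3$subject_id), ]
  y <- c(w0[[outcome]], w3[[outcome]])
  n <- nrow(w0)
  subj <- factor(rep(seq_len(n), 2L))
  tim <- rep(c(-1, 1), each = n)
  grp <- rep(ifelse(w0$group == "COMB", -1, 1), 2L)
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  Xs <- stats::model.matrix(~ subj - 1)
  r_s <- rss(Xs)
  r_st <- rss(cbind(Xs, tim))
  r_full <- rss(cbind(Xs, tim, tim * grp))
  df_err <- n - 2L
  F_T <- (r_s - r_st) / (r_full / df_err)
  F_GT <- (r_st - r_full) / (r_full / df_err)
  s_sum <- w0[[outcome]] + w3[[outcome]]
  g1 <- ifelse(w0$group == "COMB", -1, 1)
  rssb <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, s_sum))
    sum((s_sum - X %*% beta)^2)
  }
  r0 <- rssb(matrix(1, n, 1))
  r1 <- rssb(stats::model.matrix(~ factor(g1)))
  F_G <- (r0 - r1) / (r1 / df_err)
  c(G = F_G, T = F_T, GxT = F_GT)
}

noiseless <- function(seed = NULL) noise_model(gas_cv = 0, hr_sd = 0,
                                               seed = seed)
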