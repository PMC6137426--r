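# small-scale experiment builder used across tests
tiny_config <- function(preset = "exp1b", blocks = 2, tpb = 3, ...) {
  experiment_config(preset, blocks_per_condition = blocks,
                    trials_per_condition_per_block = tpb, ...)
}

# a hand-assembled response log with given signed errors, one cell
log_with_errors <- function(errors, observer = "obs1", segment = "post",
                            scope = "SR") {
  n <- length(errors)
  tibble::tibble(
    observer = observer, experiment = "exp1a", stimulus_condition = "dur800",
    block = 1L, trial = seq_len(n), segment = segment, scope = scope,
    set_size = 3L, duration_ms = 800, cue_delay_ms = 0, disk_id = 1L,
    report_order = 1L, true_dir_deg = 0,
    reported_dir_deg = errors %% 360, error_deg = errors, tp = tp(errors)
  )
}

# explicit sums-of-squares arithmetic for a two-factor fully-within design,
# independent of the lm-based implementation path
rm_anova_oracle <- function(d) {
  gm <- mean(d$y)
  m_s <- tapply(d$y, d$s, mean)
  m_a <- tapply(d$y, d$a, mean)
  m_b <- tapply(d$y, d$b, mean)
  m_sa <- tapply(d$y, list(d$s, d$a), mean)
  m_sb <- tapply(d$y, list(d$s, d$b), mean)
  m_ab <- tapply(d$y, list(d$a, d$b), mean)
  ns <- length(m_s); na <- length(m_a); nb <- length(m_b)
  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_sa <- nb * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + gm)^2)
  ss_sb <- na * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + gm)^2)
  ss_ab <- ns * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  resid <- d$y
  for (i in seq_len(nrow(d))) {
    resid[i] <- d$y[i] - m_ab[d$a[i], d$b[i]] - m_sa[d$s[i], d$a[i]] -
      m_sb[d$s[i], d$b[i]] + m_a[d$a[i]] + m_b[d$b[i]] + m_s[d$s[i]] - gm
  }
  ss_abs <- sum(resid^2)
  list(
    a = c(F = (ss_a / (na - 1)) / (ss_sa / ((ns - 1) * (na - 1))),
          df1 = na - 1, df2 = (ns - 1) * (na - 1),
          eta = ss_a / (ss_a + ss_sa)),
    b = c(F = (ss_b / (nb - 1)) / (ss_sb / ((ns - 1) * (nb - 1))),
          df1 = nb - 1, df2 = (ns - 1) * (nb - 1),
          eta = ss_b / (ss_b + ss_sb)),
    ab = c(F = (ss_ab / ((na - 1) * (nb - 1))) /
             (ss_abs / ((ns - 1) * (na - 1) * (nb - 1))),
           df1 = (na - 1) * (nb - 1), df2 = (ns - 1) * (na - 1) * (nb - 1),
           eta = ss_ab / (ss_ab + ss_abs))
  )
}
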