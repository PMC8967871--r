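# Independent oracles and fixture builders shared across tests.

# ---- split-plot sums-of-squares oracle --------------------------------
# Brute-force computation of the 2(group) x 2(session) x 2(approach)
# mixed ANOVA from cell means, for BALANCED groups, using textbook
# marginal-mean formulas. Independent of stats::aov.
split_plot_oracle <- function(cells, dv = "bi") {
  d <- cells
  d$y <- d[[dv]]
  ids <- unique(d$participant_id)
  N <- length(ids)
  groups <- vapply(ids, function(p) d$group[d$participant_id == p][1], "")
  stopifnot(length(unique(table(groups))) == 1)  # balanced oracle only
  n <- N / 2

  y <- function(p, s, a) d$y[d$participant_id == p & d$session == s &
                               d$approach == a]
  S <- c("pre", "post"); A <- c("rule", "plan"); G <- unique(groups)

  m <- mean(d$y)
  m_i <- vapply(ids, function(p) mean(d$y[d$participant_id == p]), 0)
  m_g <- vapply(G, function(g) mean(d$y[d$group == g]), 0)
  m_s <- vapply(S, function(s) mean(d$y[d$session == s]), 0)
  m_a <- vapply(A, function(a) mean(d$y[d$approach == a]), 0)
  m_gs <- outer(G, S, Vectorize(function(g, s)
    mean(d$y[d$group == g & d$session == s])))
  m_ga <- outer(G, A, Vectorize(function(g, a)
    mean(d$y[d$group == g & d$approach == a])))
  m_sa <- outer(S, A, Vectorize(function(s, a)
    mean(d$y[d$session == s & d$approach == a])))
  m_gsa <- array(0, c(2, 2, 2))
  for (gi in 1:2) for (si in 1:2) for (ai in 1:2)
    m_gsa[gi, si, ai] <- mean(d$y[d$group == G[gi] & d$session == S[si] &
                                    d$approach == A[ai]])
  m_is <- outer(ids, S, Vectorize(function(p, s)
    mean(d$y[d$participant_id == p & d$session == s])))
  m_ia <- outer(ids, A, Vectorize(function(p, a)
    mean(d$y[d$participant_id == p & d$approach == a])))

  gi_of <- match(groups, G)

  ss_g <- 4 * n * sum((m_g - m)^2)
  ss_subj <- 4 * sum((m_i - m_g[gi_of])^2)

  ss_s <- 2 * N * sum((m_s - m)^2)
  ss_gs <- 2 * n * sum((m_gs - outer(m_g, rep(1, 2)) -
                          outer(rep(1, 2), m_s) + m)^2)
  ss_s_err <- 2 * sum((m_is - m_i - m_gs[gi_of, ] + m_g[gi_of])^2)

  ss_a <- 2 * N * sum((m_a - m)^2)
  ss_ga <- 2 * n * sum((m_ga - outer(m_g, rep(1, 2)) -
                          outer(rep(1, 2), m_a) + m)^2)
  ss_a_err <- 2 * sum((m_ia - m_i - m_ga[gi_of, ] + m_g[gi_of])^2)

  ss_sa <- N * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, 2), m_a) + m)^2)
  ss_gsa <- 0
  for (gi in 1:2) for (si in 1:2) for (ai in 1:2)
    ss_gsa <- ss_gsa + n * (m_gsa[gi, si, ai] - m_gs[gi, si] - m_ga[gi, ai] -
                              m_sa[si, ai] + m_g[gi] + m_s[si] + m_a[ai] - m)^2
  ss_sa_err <- 0
  for (ii in seq_along(ids)) for (si in 1:2) for (ai in 1:2) {
    gi <- gi_of[ii]
    e <- y(ids[ii], S[si], A[ai]) - m_is[ii, si] - m_ia[ii, ai] + m_i[ii] -
      (m_gsa[gi, si, ai] - m_gs[gi, si] - m_ga[gi, ai] + m_g[gi])
    ss_sa_err <- ss_sa_err + e^2
  }

  df2 <- N - 2
  data.frame(
    effect = c("group", "session", "group x session", "approach",
               "group x approach", "session x approach",
               "group x session x approach"),
    F = c(ss_g / (ss_subj / df2),
          ss_s / (ss_s_err / df2), ss_gs / (ss_s_err / df2),
          ss_a / (ss_a_err / df2), ss_ga / (ss_a_err / df2),
          ss_sa / (ss_sa_err / df2), ss_gsa / (ss_sa_err / df2)),
    stringsAsFactors = FALSE)
}

# ---- generalized ESD oracle -------------------------------------------
# Naive step-by-step transliteration of Rosner's published procedure:
# recompute mean/SD from scratch each round, tabulate every R_i and
# lambda_i, then flag the largest i with R_i > lambda_i.
esd_oracle <- function(x, alpha = 0.05, k = 1) {
  n <- length(x)
  idx <- seq_len(n)
  work <- x
  removed <- integer(0)
  R <- lam <- numeric(k)
  for (i in 1:k) {
    mu <- sum(work) / length(work)
    s2 <- sum((work - mu)^2) / (length(work) - 1)
    if (s2 <= 0) { R[i] <- NA; lam[i] <- Inf; next }
    dev <- abs(work - mu)
    w <- which.max(dev)
    R[i] <- dev[w] / sqrt(s2)
    p <- 1 - alpha / (2 * (n - i + 1))
    tv <- qt(p, n - i - 1)
    lam[i] <- (n - i) * tv / sqrt((n - i - 1 + tv^2) * (n - i + 1))
    removed <- c(removed, idx[w])
    work <- work[-w]
    idx <- idx[-w]
  }
  n_out <- max(c(0, which(!is.na(R) & R > lam)))
  mask <- rep(FALSE, n)
  if (n_out > 0) mask[removed[1:n_out]] <- TRUE
  mask
}

# ---- fixture builders -------------------------------------------------

beats_df <- function(rr_ms, t0 = 0) {
  data.frame(participant_id = "X",
             beat_time_s = t0 + cumsum(rr_ms) / 1000,
             rr_ms = rr_ms, stringsAsFactors = FALSE)
}

# Minimal trial table: one row per (participant, session, approach,
# trial) with chosen RT/correct patterns.
trials_df <- function(participant_id, session, approach, rt_ms,
                      correct = TRUE, mt_ms = rt_ms + 200,
                      group = "control", technical = FALSE) {
  data.frame(participant_id = participant_id, group = group,
             session = session, approach = approach,
             trial_index = seq_along(rt_ms), rt_ms = rt_ms, mt_ms = mt_ms,
             correct = correct, technical_error = technical,
             outlier = FALSE, stringsAsFactors = FALSE)
}

# Random complete cell table for the mixed ANOVA (balanced groups).
random_cells <- function(n_per_group, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("S%02d", 1:(2 * n_per_group))
    grid <- expand.grid(participant_id = ids,
                        session = c("pre", "post"),
                        approach = c("rule", "plan"),
                        stringsAsFactors = FALSE)
    grid$group <- ifelse(match(grid$participant_id, ids) <= n_per_group,
                         "stress", "control")
    grid$bi <- rnorm(nrow(grid))
    grid
  })
}

quick_design <- function(n_stress = 4, n_control = 4, seed = 1,
                         trials = 16) {
  design_config(n_stress = n_stress, n_control = n_control,
                trials_per_session = trials, rng_seed = seed)
}
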