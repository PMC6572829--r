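# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# random Hill curve in the generator's realistic regime
rand_curve <- function(top = 10) {
  hill_curve(e0 = 100, e_inf = runif(1, 25, 50),
             ec50 = exp(runif(1, log(top / 8), log(top / 2))),
             h = runif(1, 0.8, 3))
}

# observation fixture: many combinations, few cells each (the shape of a
# large sparse screen), iid scores unless effects are injected
make_obs_fixture <- function(n_combos = 50, n_cells = 10, seed = 4,
                             mean = 12, sd = 25) {
  set.seed(seed)
  data.frame(combo_id = rep(sprintf("C%03d", seq_len(n_combos)),
                            each = n_cells),
             cell_id = rep(sprintf("CL%02d", seq_len(n_cells)), n_combos),
             score = rnorm(n_combos * n_cells, mean, sd),
             stringsAsFactors = FALSE)
}

as_pred <- function(obs, values) {
  data.frame(combo_id = obs$combo_id, cell_id = obs$cell_id,
             prediction = values, stringsAsFactors = FALSE)
}

# zero-noise screen experiment with a known injected synergy amplitude
make_bump_experiment <- function(delta, seed = 1, top = 10) {
  set.seed(seed)
  d <- dose_series(top)
  ca <- rand_curve(top); cb <- rand_curve(top)
  surf <- loewe_surface(ca, cb, d, d)
  v <- surf
  v[2:6, 2:6] <- v[2:6, 2:6] - combobench:::synergy_bump(delta, d, d)
  v <- pmin(pmax(v, 0), 120)
  attr(v, "fallback") <- NULL
  dose_response_matrix("C001", "CL01", d, d, v)
}

# brute-force two-sided exact rank-sum p by full enumeration of C(n, m)
# group assignments (doubling convention for two-sidedness)
exact_ranksum_p <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  idx <- utils::combn(length(all), length(x))
  ws <- apply(idx, 2, function(i) {
    sum(rank(all)[i]) - length(x) * (length(x) + 1) / 2
  })
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# nested-RSS sequential F-test oracle from explicit design matrices
anova_oracle_p <- function(obs, x) {
  dc <- stats::model.matrix(~ 0 + factor(obs$combo_id))
  cl <- stats::model.matrix(~ 0 + factor(obs$cell_id))[, -1, drop = FALSE]
  X0 <- cbind(dc, cl)
  X1 <- cbind(X0, x = x)
  rss <- function(X, y) {
    q <- qr(X)
    sum((y - X %*% qr.coef(q, y))^2)
  }
  r0 <- rss(X0, obs$score); r1 <- rss(X1, obs$score)
  df1 <- nrow(X1) - qr(X1)$rank
  Fo <- (r0 - r1) / (r1 / df1)
  stats::pf(Fo, 1, df1, lower.tail = FALSE)
}

# conditionally independent classifier panel plus its labels
make_sml_fixture <- function(n_teams = 15, n_exp = 1000, seed = 1,
                             bac_range = c(0.5, 0.9), prevalence = 0.3) {
  set.seed(seed)
  labels <- rbinom(n_exp, 1, prevalence)
  bac <- runif(n_teams, bac_range[1], bac_range[2])
  preds <- simulate_classifier_teams(labels, bac, seed = seed + 1000L)
  list(labels = labels, bac = bac, preds = preds)
}
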