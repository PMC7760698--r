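# small in-code fixtures and independent oracle implementations

toy_table <- function(abundance = NULL, n_features = 3,
                      roles = c("biological", "biological", "blank", "qc"),
                      mode = "HILIC+") {
  n_s <- length(roles)
  feats <- tibble::tibble(
    feature_id = paste0("F", seq_len(n_features)),
    neutral_mass = 100 + seq_len(n_features),
    rt = seq_len(n_features) / 2,
    mode = mode
  )
  smp <- tibble::tibble(
    sample_id = paste0("S", seq_len(n_s)),
    role = roles,
    dose_uM = ifelse(roles == "biological", 0, NA_real_),
    experiment_id = "E1",
    injection_order = seq_len(n_s),
    protocol = NA_character_
  )
  if (is.null(abundance)) {
    abundance <- matrix(seq_len(n_features * n_s) * 10,
                        n_features, n_s)
  }
  feature_table(feats, smp, abundance)
}

# table with a dose series and QCs, direct construction (no generator)
dose_table <- function(values_by_dose, doses = c(0, 1, 10, 100),
                       n_rep = NULL, experiment_id = "E1") {
  stopifnot(length(values_by_dose) == length(doses))
  n_rep <- n_rep %||% length(values_by_dose[[1]])
  vals <- unlist(values_by_dose)
  smp <- tibble::tibble(
    sample_id = sprintf("%s_S%02d", experiment_id, seq_along(vals)),
    role = "biological",
    dose_uM = rep(doses, each = n_rep),
    experiment_id = experiment_id,
    injection_order = seq_along(vals),
    protocol = NA_character_
  )
  feats <- tibble::tibble(feature_id = "F1", neutral_mass = 200,
                          rt = 1, mode = "HILIC+")
  feature_table(feats, smp, matrix(vals, nrow = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

welch_oracle_p <- function(a, b) {
  m1 <- mean(a); m2 <- mean(b); v1 <- var(a); v2 <- var(b)
  n1 <- length(a); n2 <- length(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

spearman_oracle <- function(v, d) {
  r <- stats::cor(rank(v), rank(d))
  n <- length(v)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(rs = r, p = 2 * stats::pt(-abs(t), n - 2))
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

cv_oracle <- function(x) {
  x <- x[!is.na(x)]
  stats::sd(x) / mean(x)
}

# tricube-weighted local polynomial regression evaluated at x0
local_reg_oracle <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- min(n, floor(span * n + 1e-9))
  vapply(x0, function(p) {
    d <- abs(x - p)
    h <- sort(d)[q]
    w <- (1 - pmin(1, d / h)^3)^3
    X <- outer(x - p, 0:degree, `^`)
    stats::lm.wfit(X, y, w)$coefficients[1]
  }, numeric(1))
}
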