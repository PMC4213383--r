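# Independent numeric inversion of the ratio-of-means t statistic, used as
# the oracle for the closed-form Fieller interval. Finds the roots of
#   g(rho) = (xbar - rho*ybar)^2 - t(rho)^2 * (s2x/nx + rho^2*s2y/ny)
# by bracketed root search around the point estimate. df_mode "fixed"
# evaluates the Satterthwaite df at the point estimate (the closed form's
# convention); "local" recomputes it at every rho.
oracle_fieller <- function(x, y, alpha = 0.05, df_mode = c("fixed", "local")) {
  df_mode <- match.arg(df_mode)
  xbar <- mean(x); ybar <- mean(y)
  s2x <- var(x); s2y <- var(y)
  nx <- length(x); ny <- length(y)
  rho_hat <- xbar / ybar
  ws_df <- function(rho) {
    ((s2x / nx + rho^2 * s2y / ny)^2) /
      ((s2x / nx)^2 / (nx - 1) + (rho^2 * s2y / ny)^2 / (ny - 1))
  }
  g <- function(rho) {
    df <- if (df_mode == "fixed") ws_df(rho_hat) else ws_df(rho)
    (xbar - rho * ybar)^2 -
      qt(1 - alpha / 2, df)^2 * (s2x / nx + rho^2 * s2y / ny)
  }
  stopifnot(g(rho_hat) < 0)
  span <- abs(rho_hat) + 1
  lo_br <- rho_hat - span
  tries <- 0
  while (g(lo_br) < 0 && tries < 60) { lo_br <- lo_br - span; span <- span * 2; tries <- tries + 1 }
  if (g(lo_br) < 0) return(list(ci_low = -Inf, ci_high = Inf))
  span <- abs(rho_hat) + 1
  hi_br <- rho_hat + span
  tries <- 0
  while (g(hi_br) < 0 && tries < 60) { hi_br <- hi_br + span; span <- span * 2; tries <- tries + 1 }
  if (g(hi_br) < 0) return(list(ci_low = -Inf, ci_high = Inf))
  list(
    ci_low = uniroot(g, c(lo_br, rho_hat), tol = 1e-12)$root,
    ci_high = uniroot(g, c(rho_hat, hi_br), tol = 1e-12)$root
  )
}

# Minimal feature table: matrix of areas with injection columns, default
# metadata unless overridden.
make_table <- function(mat, mz = NULL, rt = NULL, mode = "positive",
                       ids = NULL) {
  n <- nrow(mat)
  feature_table(
    data.frame(
      feature_id = if (is.null(ids)) sprintf("F%03d", seq_len(n)) else ids,
      mz = if (is.null(mz)) seq(100, by = 50, length.out = n) else mz,
      rt = if (is.null(rt)) rep(300, n) else rt,
      ion_mode = rep_len(mode, n),
      stringsAsFactors = FALSE
    ),
    mat
  )
}

# Exact-group recovery fraction against a simulation ground truth.
group_recovery <- function(groups, truth) {
  truth_parts <- split(truth$ions$feature_id, truth$ions$metabolite_id)
  got_keys <- vapply(groups, function(g) paste(sort(g$members), collapse = ","), "")
  mean(vapply(truth_parts,
              function(m) paste(sort(m), collapse = ",") %in% got_keys,
              logical(1)))
}

zero_noise_spec <- function(seed = 3, ...) {
  metabolome_sim_spec(seed = seed, biological_rsd_percent = c(A = 0, B = 0),
                      analytical_rsd_percent = 0, mz_noise_ppm = 0,
                      rt_jitter_s = 0, rt_drift_s = 0, ...)
}
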