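# Fixture builders shared across test files. All data are generated in code.

make_profile <- function(time, conc, route = "PO_gavage", dose = 3,
                         matrix = "plasma", arm = "arm1", blq = NULL,
                         analyte = metarrestin()) {
  if (is.null(blq)) blq <- rep(FALSE, length(time))
  conc_profile(arm, matrix,
               dose_regimen(route, dose),
               data.frame(time = time,
                          conc = ifelse(blq, NA_real_, conc),
                          blq = blq, n = 3L),
               analyte = analyte)
}

# monoexponential samples, exact
monoexp <- function(c0, lambda, times) c0 * exp(-lambda * times)

# write a profiles CSV from a long data.frame, returning the path
write_profile_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

profile_rows <- function(arm, matrix, route, dose, time, conc, blq = 0,
                         n = 3) {
  data.frame(arm = arm, matrix = matrix, route = route,
             dose_mg_per_kg = dose, time_h = time, conc = conc,
             blq = blq, n = n, stringsAsFactors = FALSE)
}

# Independent brute-force re-evaluation of the terminal-window search:
# enumerate every suffix of the positive post-Tmax samples, fit ln C ~ t by a
# hand-rolled least-squares formula, apply the same selection rule.
oracle_lambda_best_fit <- function(time, conc, min_points = 3,
                                   tie_tol = 1e-4) {
  keep <- conc > 0
  time <- time[keep]; conc <- conc[keep]
  i_max <- which.max(conc)
  time <- time[-seq_len(i_max)]; conc <- conc[-seq_len(i_max)]
  n <- length(time)
  best <- NULL
  for (k in seq(min_points, n)) {
    idx <- seq(n - k + 1, n)
    x <- time[idx]; y <- log(conc[idx])
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    yhat <- mean(y) + slope * (x - mean(x))
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum((y - yhat)^2) / ss_tot else 1
    r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (slope >= 0) next
    cand <- list(lambda = -slope, k = k, r2a = r2a)
    if (is.null(best) || r2a > best$r2a + tie_tol ||
        (r2a >= best$r2a - tie_tol && k > best$k)) {
      best <- cand
    }
  }
  best
}

# Brute-force per-record marker filter: evaluates each predicate on each
# record in an explicit loop, independent of the vectorized implementation.
oracle_select_markers <- function(records, criteria) {
  sel <- character()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ok <- abs(r$fc_tm_tv) >= criteria$min_abs_fc_tm_tv
    ok <- ok && abs(r$fc_pm_pv) < criteria$max_abs_fc_pm_pv
    ok <- ok && (r$fc_tm_tv * r$fc_pv_tv > criteria$min_product)
    ok <- ok && (r$p_value < criteria$max_p_value)
    if (ok) sel <- c(sel, as.character(r$gene_id))
  }
  sel
}

# random signed fold-change table under the signed convention
random_fc_table <- function(n, seed) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%05d", seq_len(n)),
             fc_tm_tv = sample(c(-1, 1), n, TRUE) * stats::runif(n, 1, 10),
             fc_pm_pv = sample(c(-1, 1), n, TRUE) * stats::runif(n, 1, 4),
             fc_pv_tv = sample(c(-1, 1), n, TRUE) * stats::runif(n, 1, 10),
             p_value = stats::runif(n)^2,
             stringsAsFactors = FALSE)
}
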