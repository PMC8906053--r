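# Shared test helpers: quiet logging, event matching, small constructed
# fixtures. All fixtures are built in code; no binary data.

options(cardioquant.quiet = TRUE)

# Match detected event times to true event times within a tolerance;
# returns counts for sensitivity/precision.
match_events <- function(detected, truth, lo = -0.1, hi = 0.45) {
  matched <- logical(length(detected))
  tp <- fn <- 0L
  for (ts in truth) {
    j <- which(!matched & detected >= ts + lo & detected <= ts + hi)
    if (length(j)) {
      matched[j[1L]] <- TRUE
      tp <- tp + 1L
    } else {
      fn <- fn + 1L
    }
  }
  list(tp = tp, fn = fn, fp = sum(!matched))
}

# Independent two-sided Fisher p oracle: exhaustive enumeration over the
# hypergeometric support, summing the probabilities of all tables at
# most as probable as the observed one (R's near-tie rule).
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A two-group long table from two value vectors.
group_table <- function(v1, v2, metric = "m",
                        groups = c("UT", "TTR_fibril")) {
  tibble::tibble(
    group = rep(groups, c(length(v1), length(v2))),
    metric = metric,
    value = c(v1, v2))
}

# A small dipole adhesion set used across TFM tests.
dipole_adhesions <- function(f = 60, sep = 40, centre = 64, radius = 4) {
  data.frame(x_um = c(centre - sep / 2, centre + sep / 2),
             y_um = c(centre, centre),
             fx_nn = c(f, -f), fy_nn = c(0, 0), radius_um = radius)
}

# Pooled R^2 of a predicted vector field against truth.
field_r2 <- function(pred_x, pred_y, true_x, true_y) {
  ss_res <- sum((pred_x - true_x)^2 + (pred_y - true_y)^2)
  ss_tot <- sum((true_x - mean(true_x))^2 + (true_y - mean(true_y))^2)
  1 - ss_res / ss_tot
}
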