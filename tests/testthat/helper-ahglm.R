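# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# a small hand-made volume table with fully controlled covariates
make_toy_table <- function(n_per_group = 10, seed = 1,
                           effect_ml = 0, age_slope = 0, tiv_slope = 0,
                           noise_sd = 1, baseline = 50) {
  set.seed(seed)
  n <- 2 * n_per_group
  subj <- data.frame(
    id = sprintf("S%02d", seq_len(n)),
    med = rep(c(0, 1), each = n_per_group),
    age = runif(n, 21, 63),
    sex = rep(c("F", "M"), length.out = n),
    tiv_ml = rnorm(n, 1450, 120),
    stringsAsFactors = FALSE
  )
  y <- baseline + effect_ml * subj$med +
    age_slope * (subj$age - mean(subj$age)) +
    tiv_slope * (subj$tiv_ml - mean(subj$tiv_ml)) +
    rnorm(n, 0, noise_sd)
  vols <- matrix(pmax(y, 0.01), ncol = 1, dimnames = list(NULL, "region"))
  roi_volume_table(subj, vols)
}

# independent brute-force masked-sum oracle: explicit triple loop
triple_loop_volume <- function(values, mask, voxel_volume_mm3) {
  d <- dim(values)
  acc <- 0
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        if (mask[i, j, k]) acc <- acc + values[i, j, k]
  acc * voxel_volume_mm3 / 1000
}

# independent normal-equations OLS oracle
normal_equations_beta <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
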