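# Fixture builders shared across the suite. Everything is generated in code;
# no data files are read from disk except those the tests write themselves.

# a balanced M-materials x 2-treatments x R-replicates study table with
# explicit metric values (recycled over samples if needed)
make_design <- function(n_materials = 2, n_reps = 2, values = NULL,
                        metric = "m") {
  n <- n_materials * 2 * n_reps
  material <- rep(paste0("mat", seq_len(n_materials)), each = 2 * n_reps)
  treatment <- rep(rep(c("dried", "frozen"), each = n_reps), n_materials)
  if (is.null(values)) values <- seq_len(n)
  metrics <- stats::setNames(data.frame(rep_len(values, n)), metric)
  study_table(sprintf("s%02d", seq_len(n)), material, treatment, metrics)
}

# a small proportions feature table with fixed dimnames
make_prop_table <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  feature_table(m, "proportions")
}

# independent brute-force oracle for the stratified ratio test: enumerates
# every within-material assignment by explicit nested iteration and returns
# the two-sided (log-scale) exhaustive p-value. Deliberately written with a
# different code path from the package (explicit loops, no outer()).
oracle_ratio_p <- function(values_by_material, k_by_material, observed_avg) {
  combo_ratios <- lapply(seq_along(values_by_material), function(i) {
    v <- values_by_material[[i]]
    k <- k_by_material[[i]]
    sets <- utils::combn(length(v), k, simplify = FALSE)
    vapply(sets, function(ix) mean(v[ix]) / mean(v[-ix]), numeric(1))
  })
  grid <- expand.grid(lapply(combo_ratios, seq_along))
  avgs <- apply(grid, 1, function(row)
    mean(mapply(function(r, i) r[[i]], combo_ratios, row)))
  o <- abs(log(observed_avg))
  sum(abs(log(avgs)) >= o - 1e-12 * max(1, o)) / length(avgs)
}

# closed-form Pearson r^2 of log-vectors, written out from the raw-sums
# formula (independent of stats::cor)
oracle_log_r2 <- function(x, y) {
  lx <- log(x); ly <- log(y); n <- length(lx)
  num <- n * sum(lx * ly) - sum(lx) * sum(ly)
  den <- sqrt((n * sum(lx^2) - sum(lx)^2) * (n * sum(ly^2) - sum(ly)^2))
  (num / den)^2
}

# independent PERMANOVA pseudo-F from first principles (explicit loops)
oracle_permanova_f <- function(d, groups) {
  n <- nrow(d)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    acc <- 0
    if (length(ix) > 1)
      for (ii in seq_len(length(ix) - 1)) for (jj in (ii + 1):length(ix))
        acc <- acc + d[ix[ii], ix[jj]]^2
    ss_w <- ss_w + acc / length(ix)
  }
  a <- length(unique(groups))
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}
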