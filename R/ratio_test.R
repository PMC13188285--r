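# Material-stratified ratio-of-means statistic and its permutation null.
#
# For metric x, material m and treatments (num, den):
#   ratio_m = mean(x | m, num) / mean(x | m, den)
#   average ratio = mean over materials (arithmetic, or geometric on request).
# The null shuffles treatment labels within each material (preserving group
# sizes), which breaks any metric-treatment association while controlling for
# baseline differences between materials.

ratio_strata <- function(study, metric, numerator_treatment,
                         denominator_treatment) {
  stopifnot(inherits(study, "study_table"))
  if (!metric %in% study_metrics(study))
    stop("metric '", metric, "' not found; available: ",
         paste(study_metrics(study), collapse = ", "))
  trts <- c(numerator_treatment, denominator_treatment)
  if (!all(trts %in% study$treatment))
    stop("treatment(s) not present: ",
         paste(setdiff(trts, study$treatment), collapse = ", "))
  keep <- study$treatment %in% trts
  v <- study[[metric]][keep]
  material <- study$material[keep]
  is_num <- study$treatment[keep] == numerator_treatment
  n_dropped <- sum(is.na(v))
  ok <- !is.na(v)
  v <- v[ok]; material <- material[ok]; is_num <- is_num[ok]
  materials <- unique(material)
  strata <- lapply(materials, function(m) {
    idx <- which(material == m)
    k <- sum(is_num[idx])
    if (k == 0L || k == length(idx))
      stop("material '", m, "' lacks non-missing values in one treatment")
    # numerator-treatment values first, so the observed assignment is 1..k
    list(values = c(v[idx][is_num[idx]], v[idx][!is_num[idx]]), k = k)
  })
  names(strata) <- materials
  list(strata = strata, n_dropped = n_dropped)
}

# average ratio for one assignment: each stratum's first k values (after
# reordering by `pick`) play the numerator role
stratum_ratio <- function(values, num_idx) {
  den_idx <- setdiff(seq_along(values), num_idx)
  mean(values[num_idx]) / mean(values[den_idx])
}

combine_ratios <- function(ratios, mean_type) {
  if (mean_type == "geometric") exp(mean(log(ratios))) else mean(ratios)
}

#' Material-wise treatment ratio of means
#'
#' For each material, computes the ratio of the metric's mean in the
#' numerator treatment to its mean in the denominator treatment, then
#' averages those ratios across materials. An average ratio above (below) 1
#' indicates an overall positive (negative) effect of the numerator
#' treatment. Samples with a missing value for the metric are dropped.
#'
#' @param study a [study_table()].
#' @param metric name of the metric column to analyze.
#' @param numerator_treatment,denominator_treatment the two treatment labels;
#'   the numerator plays the "dried" role of a drying-vs-freezing comparison.
#' @param mean_type how per-material ratios are averaged: \code{"arithmetic"}
#'   (plain mean, the default) or \code{"geometric"} (symmetric under
#'   swapping numerator and denominator).
#' @return List with \code{per_material_ratios} (named numeric),
#'   \code{average_ratio}, and \code{n_dropped} (samples dropped for
#'   missingness).
#' @examples
#' st <- study_table(paste0("s", 1:6),
#'                   material  = c("A", "A", "A", "A", "B", "B"),
#'                   treatment = c("dried", "dried", "frozen", "frozen",
#'                                 "dried", "frozen"),
#'                   metrics = data.frame(yield = c(2, 2, 4, 4, 1, 4)))
#' average_ratio(st, "yield", "dried", "frozen")  # ratios 0.5, 0.25; avg 0.375
#' @export
average_ratio <- function(study, metric, numerator_treatment,
                          denominator_treatment,
                          mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  prep <- ratio_strata(study, metric, numerator_treatment,
                       denominator_treatment)
  ratios <- numeric(length(prep$strata))
  names(ratios) <- names(prep$strata)
  for (m in names(prep$strata)) {
    s <- prep$strata[[m]]
    den <- mean(s$values[-seq_len(s$k)])
    if (den == 0) stop("zero denominator mean in material '", m, "'")
    ratios[[m]] <- mean(s$values[seq_len(s$k)]) / den
  }
  list(per_material_ratios = ratios,
       average_ratio = combine_ratios(ratios, mean_type),
       n_dropped = prep$n_dropped)
}

#' Number of distinct stratified label assignments
#'
#' The stratified permutation null draws uniformly from the product, over
#' materials, of the ways to choose which samples carry the numerator label:
#' prod over materials of choose(n_m, k_m). When this count is small the test
#' can enumerate the null exhaustively.
#'
#' @inheritParams average_ratio
#' @return The assignment count as a double (may be astronomically large).
#' @export
count_stratified_assignments <- function(study, metric,
                                         numerator_treatment,
                                         denominator_treatment) {
  if (nrow(study) == 0) return(1)
  prep <- ratio_strata(study, metric, numerator_treatment,
                       denominator_treatment)
  prod(vapply(prep$strata,
              function(s) choose(length(s$values), s$k), numeric(1)))
}

# ties count as "at least as extreme" (conservative); comparisons use a
# tiny relative tolerance so that mathematically tied statistics reached by
# different floating-point routes still register as ties
extremity_count <- function(null_stats, observed, sidedness) {
  eps <- function(x) 1e-12 * pmax(1, abs(x))
  switch(sidedness,
         two_sided = {
           o <- abs(suppressWarnings(log(observed)))
           n <- abs(suppressWarnings(log(null_stats)))
           sum(is.nan(n) | n >= o - eps(o))
         },
         less = sum(null_stats <= observed + eps(observed)),
         greater = sum(null_stats >= observed - eps(observed)))
}

#' Stratified permutation test for a treatment-effect ratio
#'
#' Tests whether the material-averaged ratio of treatment means (see
#' [average_ratio()]) deviates from 1 more than expected when treatment
#' labels are shuffled at random within each material. Two-sided extremity is
#' measured on the log scale: a null average ratio r is at least as extreme
#' as the observed r_obs when |ln r| >= |ln r_obs|. When the number of
#' distinct stratified assignments is at most \code{exhaustive_limit} the
#' null is enumerated exhaustively and the exact tail fraction is reported;
#' otherwise Monte-Carlo permutations are drawn and the
#' p = (1 + b) / (1 + n_perm) estimator is used, so p is never zero.
#'
#' @inheritParams average_ratio
#' @param n_perm number of Monte-Carlo permutations (ignored in exhaustive
#'   mode).
#' @param sidedness \code{"two_sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @param seed integer seed for the Monte-Carlo draw; NULL leaves the RNG
#'   state alone.
#' @param exhaustive_limit switch to full enumeration when the assignment
#'   count does not exceed this.
#' @return Object of class \code{ratio_test}: per-material ratios, average
#'   ratio, p-value, permutation count, mode (\code{"exhaustive"} or
#'   \code{"monte_carlo"}), sidedness, and a null-distribution summary
#'   (mean, sd, quantiles).
#' @export
ratio_permutation_test <- function(study, metric,
                                   numerator_treatment, denominator_treatment,
                                   n_perm = 9999,
                                   sidedness = c("two_sided", "less", "greater"),
                                   seed = NULL,
                                   exhaustive_limit = 1e5,
                                   mean_type = c("arithmetic", "geometric")) {
  sidedness <- match.arg(sidedness)
  mean_type <- match.arg(mean_type)
  if (n_perm < 1) stop("n_perm must be >= 1")
  prep <- ratio_strata(study, metric, numerator_treatment,
                       denominator_treatment)
  strata <- prep$strata
  obs <- average_ratio(study, metric, numerator_treatment,
                       denominator_treatment, mean_type)
  n_assign <- prod(vapply(strata,
                          function(s) choose(length(s$values), s$k),
                          numeric(1)))
  M <- length(strata)
  if (n_assign <= exhaustive_limit) {
    mode <- "exhaustive"
    # per-stratum ratio value of every numerator-subset choice
    per_stratum <- lapply(strata, function(s) {
      combos <- utils::combn(length(s$values), s$k)
      apply(combos, 2, function(ix) stratum_ratio(s$values, ix))
    })
    # cross-product of per-stratum choices via iterated outer sums of
    # (log-)ratios; length equals n_assign
    if (mean_type == "geometric") {
      acc <- 0
      for (r in per_stratum) acc <- as.vector(outer(acc, log(r), "+"))
      null_stats <- exp(acc / M)
    } else {
      acc <- 0
      for (r in per_stratum) acc <- as.vector(outer(acc, r, "+"))
      null_stats <- acc / M
    }
    b <- extremity_count(null_stats, obs$average_ratio, sidedness)
    p <- b / length(null_stats)
    n_used <- length(null_stats)
  } else {
    mode <- "monte_carlo"
    if (!is.null(seed)) set.seed(seed)
    null_stats <- vapply(seq_len(n_perm), function(i) {
      ratios <- vapply(strata, function(s) {
        ix <- sample.int(length(s$values), s$k)
        stratum_ratio(s$values, ix)
      }, numeric(1))
      combine_ratios(ratios, mean_type)
    }, numeric(1))
    b <- extremity_count(null_stats, obs$average_ratio, sidedness)
    p <- (1 + b) / (1 + n_perm)
    n_used <- n_perm
  }
  finite_null <- null_stats[is.finite(null_stats)]
  structure(list(metric = metric,
                 numerator = numerator_treatment,
                 denominator = denominator_treatment,
                 per_material_ratios = obs$per_material_ratios,
                 average_ratio = obs$average_ratio,
                 p_value = p,
                 n_permutations = n_used,
                 mode = mode,
                 sidedness = sidedness,
                 mean_type = mean_type,
                 n_dropped = prep$n_dropped,
                 null_summary = list(
                   mean = mean(finite_null),
                   sd = stats::sd(finite_null),
                   quantiles = stats::quantile(finite_null,
                                               c(0.025, 0.25, 0.5, 0.75, 0.975)))),
            class = "ratio_test")
}

#' @export
print.ratio_test <- function(x, ...) {
  cat("Stratified ratio permutation test\n")
  cat(sprintf("  metric: %s   (%s / %s)\n", x$metric, x$numerator,
              x$denominator))
  cat("  per-material ratios:\n")
  print(round(x$per_material_ratios, 4))
  cat(sprintf("  average ratio: %.4g  (%s mean)\n", x$average_ratio,
              x$mean_type))
  cat(sprintf("  p-value: %.4g  (%s, %s, %d permutations)\n",
              x$p_value, x$sidedness, x$mode, x$n_permutations))
  if (x$n_dropped > 0)
    cat(sprintf("  note: %d sample(s) dropped for missing '%s'\n",
                x$n_dropped, x$metric))
  invisible(x)
}

#' Benjamini-Hochberg adjustment across metrics
#'
#' Convenience wrapper around \code{stats::p.adjust(method = "BH")} for
#' correcting a family of per-metric ratio-test p-values. Off by default in
#' all analyses: results are reported per metric unless the user opts in.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
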