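# Treatment-consistency test on feature proportions within one material:
# Pearson r^2 of log-transformed per-treatment mean proportions, against a
# permutation null that reshuffles treatment labels among the material's
# samples (group sizes preserved). A significantly LOW r^2 means the two
# treatments yield less consistent composition estimates than expected from
# replicate-level noise alone.

#' Per-treatment mean feature proportions within one material
#'
#' For each feature, computes the arithmetic mean of its proportion across
#' the material's samples of each treatment.
#'
#' @param t a \code{feature_table} of kind \code{"proportions"} whose columns
#'   cover the material's samples.
#' @param study a [study_table()] mapping samples to material and treatment.
#' @param material the material to analyze.
#' @param treatments length-2 character vector naming the treatments; the
#'   first is conventionally the "dried" (treated) group.
#' @return List with \code{mean1} and \code{mean2} (named numeric vectors
#'   aligned to the feature ids, one per treatment), \code{treatments}, and
#'   \code{sample_ids} used.
#' @export
treatment_mean_proportions <- function(t, study, material,
                                       treatments = NULL) {
  stopifnot(inherits(t, "feature_table"), inherits(study, "study_table"))
  if (!material %in% study$material)
    stop("material '", material, "' absent from study; available: ",
         paste(unique(study$material), collapse = ", "))
  sub <- subset(study, materials = material)
  if (is.null(treatments)) treatments <- unique(sub$treatment)
  if (length(treatments) != 2)
    stop("exactly two treatments required; got ",
         paste(treatments, collapse = ", "))
  ids1 <- sub$sample_id[sub$treatment == treatments[1]]
  ids2 <- sub$sample_id[sub$treatment == treatments[2]]
  if (length(ids1) == 0 || length(ids2) == 0)
    stop("material '", material, "' lacks samples in one treatment")
  missing_ids <- setdiff(c(ids1, ids2), colnames(t$values))
  if (length(missing_ids))
    stop("sample(s) absent from feature table: ",
         paste(missing_ids, collapse = ", "))
  m1 <- rowMeans(t$values[, ids1, drop = FALSE])
  m2 <- rowMeans(t$values[, ids2, drop = FALSE])
  list(mean1 = m1, mean2 = m2, treatments = treatments,
       sample_ids = list(ids1, ids2))
}

# zero-adjust a pair of mean-proportion vectors per policy; returns the
# usable (x, y) pair on the original scale plus the number of features dropped
zero_adjust <- function(x, y, zero_policy) {
  if (zero_policy == "drop") {
    keep <- x > 0 & y > 0
    list(x = x[keep], y = y[keep], n_dropped = sum(!keep))
  } else {  # half_min_pseudocount
    nz <- c(x[x > 0], y[y > 0])
    if (!length(nz)) stop("all mean proportions are zero")
    pseudo <- min(nz) / 2
    list(x = ifelse(x > 0, x, pseudo), y = ifelse(y > 0, y, pseudo),
         n_dropped = 0L)
  }
}

#' Squared Pearson correlation of log-transformed proportion vectors
#'
#' The consistency statistic: r^2 of (ln x, ln y) across features. In the
#' ideal noise- and effect-free case both treatments give identical mean
#' proportions, all points sit on the diagonal and r^2 = 1. Zeros are handled
#' per \code{zero_policy}: \code{"half_min_pseudocount"} (default) replaces
#' zero means by half the smallest nonzero mean of the compared pair,
#' \code{"drop"} excludes features with a zero mean in either vector.
#'
#' @param x,y aligned nonnegative mean-proportion vectors (length >= 3 after
#'   zero handling).
#' @param zero_policy \code{"half_min_pseudocount"} or \code{"drop"}.
#' @return The squared Pearson correlation, in [0, 1].
#' @export
log_r2 <- function(x, y, zero_policy = c("half_min_pseudocount", "drop")) {
  zero_policy <- match.arg(zero_policy)
  if (length(x) != length(y)) stop("x and y must be aligned")
  adj <- zero_adjust(x, y, zero_policy)
  if (length(adj$x) < 3)
    stop("fewer than 3 usable features after zero handling")
  lx <- log(adj$x); ly <- log(adj$y)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0)
    stop("zero variance in a log-mean vector; r^2 undefined")
  stats::cor(lx, ly)^2
}

#' Permutation test of composition consistency between treatments
#'
#' Within one material, compares per-feature mean proportions between the two
#' treatments via the log-scale Pearson r^2 ([log_r2()]), and asks how often
#' a null model that reshuffles treatment labels among the material's samples
#' (preserving group sizes) produces an even lower r^2. A low p-value means
#' the treatments are less consistent than expected from replicate noise.
#'
#' Features are first restricted to the material's samples and filtered with
#' [threshold_filter()] at \code{min_prop}. When the number of distinct label
#' assignments choose(n, k) is at most \code{exhaustive_limit}, the null is
#' enumerated exhaustively and p = (1 + #\{strictly lower among the other
#' assignments\}) / n_assignments (the observed assignment counting as its own
#' extreme, so p is in (0, 1]); otherwise Monte-Carlo with
#' p = (1 + #\{lower\}) / (1 + n_perm). Ties never count as lower.
#'
#' @inheritParams treatment_mean_proportions
#' @param min_prop abundance threshold passed to [threshold_filter()]
#'   (e.g. 1e-4 for the 0.01\% OTU threshold, 1e-5 for the 0.001\% gene
#'   threshold); 0 disables filtering.
#' @param n_perm Monte-Carlo permutation count.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param zero_policy zero-handling policy for [log_r2()].
#' @param exhaustive_limit enumeration switch, as assignments.
#' @return Object of class \code{consistency_test} with fields
#'   \code{r_squared}, \code{n_features}, \code{p_value},
#'   \code{n_permutations}, \code{mode}, \code{mean1}, \code{mean2},
#'   \code{treatments}, \code{material}, \code{zero_policy},
#'   \code{n_zero_dropped}.
#' @export
consistency_permutation_test <- function(t, study, material,
                                         treatments = NULL,
                                         min_prop = 1e-4,
                                         n_perm = 999,
                                         seed = NULL,
                                         zero_policy = c("half_min_pseudocount",
                                                         "drop"),
                                         exhaustive_limit = 1e5) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(t, "feature_table"), inherits(study, "study_table"))
  if (t$kind != "proportions")
    stop("consistency test expects a proportions table")
  sub <- subset(study, materials = material)
  if (is.null(treatments)) treatments <- unique(sub$treatment)
  if (length(treatments) != 2) stop("exactly two treatments required")
  ids1 <- sub$sample_id[sub$treatment == treatments[1]]
  ids2 <- sub$sample_id[sub$treatment == treatments[2]]
  if (length(ids1) == 0 || length(ids2) == 0)
    stop("material '", material, "' lacks samples in one treatment")
  tt <- subset(t, samples = c(ids1, ids2))
  if (min_prop > 0) tt <- threshold_filter(tt, min_prop)
  if (nrow(tt$values) < 3)
    stop("fewer than 3 features pass the abundance threshold")
  vals <- tt$values
  n1 <- length(ids1); n <- n1 + length(ids2)

  r2_of <- function(num_idx) {
    m1 <- rowMeans(vals[, num_idx, drop = FALSE])
    m2 <- rowMeans(vals[, -num_idx, drop = FALSE])
    log_r2(m1, m2, zero_policy)
  }
  obs_adj <- zero_adjust(rowMeans(vals[, seq_len(n1), drop = FALSE]),
                         rowMeans(vals[, -seq_len(n1), drop = FALSE]),
                         zero_policy)
  r2_obs <- r2_of(seq_len(n1))

  n_assign <- choose(n, n1)
  if (n_assign <= exhaustive_limit) {
    mode <- "exhaustive"
    combos <- utils::combn(n, n1)
    null_r2 <- apply(combos, 2, r2_of)
    # exact lower-tail fraction over the full enumeration. Ties are not
    # "lower" (a tiny relative tolerance keeps floating-point near-ties from
    # counting); the floor 1/n_assign keeps p positive at the resolution of
    # the enumeration when the observed r2 is the minimum
    tol <- 1e-12 * max(1, r2_obs)
    lower <- sum(null_r2 < r2_obs - tol)
    p <- max(lower, 1) / n_assign
    n_used <- n_assign
  } else {
    mode <- "monte_carlo"
    if (!is.null(seed)) set.seed(seed)
    null_r2 <- vapply(seq_len(n_perm),
                      function(i) r2_of(sample.int(n, n1)), numeric(1))
    tol <- 1e-12 * max(1, r2_obs)
    p <- (1 + sum(null_r2 < r2_obs - tol)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(material = material,
                 treatments = treatments,
                 r_squared = r2_obs,
                 n_features = nrow(vals),
                 p_value = p,
                 n_permutations = n_used,
                 mode = mode,
                 min_prop = min_prop,
                 zero_policy = zero_policy,
                 n_zero_dropped = obs_adj$n_dropped,
                 mean1 = rowMeans(vals[, seq_len(n1), drop = FALSE]),
                 mean2 = rowMeans(vals[, -seq_len(n1), drop = FALSE])),
            class = "consistency_test")
}

#' @export
print.consistency_test <- function(x, ...) {
  cat("Composition-consistency permutation test\n")
  cat(sprintf("  material: %s   treatments: %s vs %s\n", x$material,
              x$treatments[1], x$treatments[2]))
  cat(sprintf("  r^2 = %.4f over %d features (threshold %g, zeros: %s",
              x$r_squared, x$n_features, x$min_prop, x$zero_policy))
  if (x$n_zero_dropped > 0) cat(sprintf(", %d dropped", x$n_zero_dropped))
  cat(")\n")
  cat(sprintf("  p = %.4g  (lower tail, %s, %d permutations)\n",
              x$p_value, x$mode, x$n_permutations))
  invisible(x)
}
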