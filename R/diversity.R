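#' Per-sample feature richness
#'
#' Counts, for each sample, the number of features present (value > 0).
#'
#' @param t a \code{feature_table} (counts or proportions).
#' @return Named numeric vector, one value per sample.
#' @export
richness <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  colSums(t$values > 0)
}

#' Per-sample Shannon diversity
#'
#' Computes H = -sum(p_i * log(p_i, base)) over the features with positive
#' proportion in each sample. Counts tables are normalized to proportions
#' internally, so the result is invariant to rescaling a sample's counts.
#'
#' @param t a \code{feature_table}; every sample column must have positive sum.
#' @param base logarithm base; natural log by default (ecological convention).
#' @return Named numeric vector of diversities, one per sample; H >= 0.
#' @export
shannon <- function(t, base = exp(1)) {
  stopifnot(inherits(t, "feature_table"))
  cs <- colSums(t$values)
  if (any(cs <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(t$values)[cs <= 0], collapse = ", "))
  p <- sweep(t$values, 2, cs, "/")
  plogp <- ifelse(p > 0, p * log(p, base = base), 0)
  h <- -colSums(plogp)
  # clamp tiny negative round-off
  pmax(h, 0)
}

#' Abundance-threshold feature filter
#'
#' Keeps the features whose proportion reaches \code{min_prop} in at least one
#' sample (mode \code{"per_sample"}) or whose group-mean proportion reaches
#' \code{min_prop} in at least one group (mode \code{"per_group_mean"}, used
#' for gene-level comparisons where means across replicates are thresholded).
#' Columns are NOT renormalized afterwards: retained values remain
#' interpretable as proportions of the original, unfiltered community.
#'
#' @param t a \code{feature_table} of kind \code{"proportions"}.
#' @param min_prop threshold as a fraction in [0, 1); e.g. 1e-4 for 0.01\%.
#' @param mode how "in at least one compared sample" is interpreted:
#'   per individual sample column (default) or per group mean.
#' @param groups for \code{"per_group_mean"}: a vector of group labels
#'   aligned to the sample columns.
#' @return The filtered \code{feature_table} (kind stays \code{"proportions"};
#'   columns may sum to less than 1).
#' @export
threshold_filter <- function(t, min_prop,
                             mode = c("per_sample", "per_group_mean"),
                             groups = NULL) {
  stopifnot(inherits(t, "feature_table"))
  mode <- match.arg(mode)
  if (t$kind != "proportions")
    stop("threshold_filter expects a proportions table; see to_proportions()")
  if (!is.numeric(min_prop) || length(min_prop) != 1 ||
      min_prop < 0 || min_prop >= 1)
    stop("min_prop must lie in [0, 1)")
  if (mode == "per_sample") {
    keep <- apply(t$values, 1, max) >= min_prop
  } else {
    if (is.null(groups) || length(groups) != ncol(t$values))
      stop("per_group_mean mode needs one group label per sample")
    gm <- t(rowsum(t(t$values), group = groups) /
              as.vector(table(groups)[sort(unique(as.character(groups)))]))
    keep <- apply(gm, 1, max) >= min_prop
  }
  out <- t
  out$values <- t$values[keep, , drop = FALSE]
  out
}
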