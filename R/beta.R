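# Abundance-weighted Bray-Curtis dissimilarities, one-way PERMANOVA on a
# distance matrix, and 2-D metric MDS by majorization (SMACOF) of raw stress
# with Kruskal stress-1 reported.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i), in [0, 1]; 0 for identical
#' vectors, 1 for disjoint supports. Abundance-weighted: each taxon
#' contributes in proportion to its abundance.
#'
#' @param x,y aligned nonnegative vectors, each with at least one positive
#'   entry.
#' @return The dissimilarity, a scalar in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be aligned")
  if (any(x < 0) || any(y < 0)) stop("abundances must be nonnegative")
  s <- sum(x) + sum(y)
  if (sum(x) == 0 || sum(y) == 0)
    stop("Bray-Curtis undefined for an all-zero vector")
  sum(abs(x - y)) / s
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' Normalizes the table to proportions and computes all pairwise
#' [bray_curtis()] dissimilarities between sample columns.
#'
#' @param t a \code{feature_table}; counts are normalized via
#'   [to_proportions()] first.
#' @return Object of class \code{dist_matrix}: a symmetric matrix with zero
#'   diagonal and entries in [0, 1], sample ids as dimnames.
#' @export
dissimilarity_matrix <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (t$kind != "proportions") t <- to_proportions(t)
  v <- t$values
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- bray_curtis(v[, i], v[, j])
  structure(d, class = c("dist_matrix", "matrix"))
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  d
}

# PERMANOVA sums of squares from squared distances and a grouping
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    ss_within <- ss_within + sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

permanova_f <- function(d2, groups, a, n) {
  ss <- permanova_ss(d2, groups)
  if (ss[["within"]] == 0) return(Inf)
  (ss[["between"]] / (a - 1)) / (ss[["within"]] / (n - a))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance via the pseudo-F
#' statistic. With N samples in a groups, SS_total = (1/N) sum_\{i<j\} d_ij^2,
#' SS_within = sum over groups g of (1/n_g) sum_\{i<j in g\} d_ij^2,
#' SS_between = SS_total - SS_within, and
#' F = (SS_between / (a - 1)) / (SS_within / (N - a)). Significance comes
#' from uniform permutation of the group labels:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm). A significantly high F means
#' between-group dissimilarities are detectably larger than within-group
#' ones. The standardized effect size is
#' SES = (F_obs - mean F_null) / sd F_null.
#'
#' @param d a symmetric distance matrix (a \code{dist_matrix}, plain matrix,
#'   or \code{dist}).
#' @param groups group label per sample, aligned to the matrix rows; at
#'   least 2 groups with at least 2 samples each.
#' @param n_perm number of Monte-Carlo label permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @param exhaustive_limit when the number of distinct label arrangements
#'   (the multinomial coefficient N! / prod n_g!) does not exceed this, the
#'   null is enumerated exhaustively and the exact tail fraction
#'   #\{F >= F_obs\} / n_arrangements is reported (the identity arrangement is
#'   among them, so p > 0). Default 5000; set 0 to force Monte-Carlo.
#' @return Object of class \code{permanova_test} with \code{pseudo_F},
#'   \code{r_squared} (SS_between / SS_total), \code{p_value}, \code{ses},
#'   \code{n_perm}, \code{mode}, \code{n_groups}, and the SS decomposition.
#' @export
permanova <- function(d, groups, n_perm = 10000, seed = NULL,
                      exhaustive_limit = 5000) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) stop("at least 2 groups required")
  if (any(tab < 2))
    stop("every group needs >= 2 samples; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  a <- length(tab)
  d2 <- d^2
  ss <- permanova_ss(d2, groups)
  f_obs <- if (ss[["within"]] == 0) Inf else
    (ss[["between"]] / (a - 1)) / (ss[["within"]] / (n - a))
  n_arrange <- factorial(n) / prod(factorial(tab))
  if (n_arrange <= exhaustive_limit) {
    mode <- "exhaustive"
    assignments <- enumerate_label_arrangements(groups)
    f_null <- apply(assignments, 1,
                    function(g) permanova_f(d2, g, a, n))
    tol <- 1e-12 * max(1, abs(f_obs))
    p <- sum(f_null >= f_obs - tol) / length(f_null)
    n_used <- length(f_null)
  } else {
    mode <- "monte_carlo"
    if (!is.null(seed)) set.seed(seed)
    f_null <- vapply(seq_len(n_perm),
                     function(i) permanova_f(d2, sample(groups), a, n),
                     numeric(1))
    tol <- 1e-12 * max(1, abs(f_obs))
    p <- (1 + sum(f_null >= f_obs - tol)) / (1 + n_perm)
    n_used <- n_perm
  }
  finite <- f_null[is.finite(f_null)]
  ses <- if (length(finite) >= 2 && stats::sd(finite) > 0)
    (f_obs - mean(finite)) / stats::sd(finite) else NA_real_
  structure(list(pseudo_F = f_obs,
                 r_squared = ss[["between"]] / ss[["total"]],
                 p_value = p,
                 ses = ses,
                 n_perm = n_used,
                 mode = mode,
                 n_groups = a,
                 ss = ss),
            class = "permanova_test")
}

# all distinct arrangements of a label multiset over positions 1..n,
# one arrangement per row; feasible only for small designs
enumerate_label_arrangements <- function(groups) {
  labels <- unique(groups)
  counts <- as.vector(table(factor(groups, levels = labels)))
  n <- length(groups)
  rec <- function(positions, labels, counts) {
    if (length(labels) == 1)
      return(matrix(labels, 1, length(positions)))
    sets <- utils::combn(positions, counts[1], simplify = FALSE)
    do.call(rbind, lapply(sets, function(s) {
      rest <- rec(setdiff(positions, s), labels[-1], counts[-1])
      full <- matrix(NA_character_, nrow(rest), length(positions))
      full[, match(s, positions)] <- labels[1]
      full[, match(setdiff(positions, s), positions)] <- rest
      full
    }))
  }
  rec(seq_len(n), labels, counts)
}

#' @export
print.permanova_test <- function(x, ...) {
  cat("PERMANOVA (one-way, pseudo-F)\n")
  cat(sprintf("  F = %.4g   R^2 = %.4f   SES = %.3g\n",
              x$pseudo_F, x$r_squared, x$ses))
  cat(sprintf("  p = %.4g   (%d permutations, %d groups)\n",
              x$p_value, x$n_perm, x$n_groups))
  invisible(x)
}

# Kruskal stress-1 of configuration X against target distances d
kruskal_stress1 <- function(d, delta_hat) {
  sqrt(sum((d - delta_hat)^2) / sum(d^2))
}

# one SMACOF run from a given start; returns list(X, raw_stress, iters,
# converged)
smacof_run <- function(d, X, tol, max_iter) {
  n <- nrow(d)
  delta <- as.matrix(stats::dist(X))
  raw <- sum((d[upper.tri(d)] - delta[upper.tri(delta)])^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Guttman transform: X_new = (1/n) B(X) X with b_ij = -d_ij / delta_ij
    w <- ifelse(delta > 0, d / delta, 0)
    B <- -w
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    delta <- as.matrix(stats::dist(X))
    raw_new <- sum((d[upper.tri(d)] - delta[upper.tri(delta)])^2)
    if (raw - raw_new <= tol * max(raw, .Machine$double.eps)) {
      raw <- raw_new
      converged <- TRUE
      break
    }
    raw <- raw_new
  }
  list(X = X, raw = raw, iters = it, converged = converged)
}

#' Metric multidimensional scaling by Kruskal-stress minimization
#'
#' Embeds samples in k dimensions so that embedded Euclidean distances match
#' the input dissimilarities, minimizing raw stress
#' sum_\{i<j\} (d_ij - dhat_ij)^2 by iterative majorization (SMACOF, whose
#' Guttman update never increases raw stress). The first start is classical
#' scaling (principal coordinates); the remaining \code{n_restarts - 1}
#' starts are random. The best run is returned, with the normalized Kruskal
#' stress-1 sqrt(sum (d - dhat)^2 / sum d^2) reported.
#'
#' @param d a symmetric distance matrix.
#' @param k embedding dimension (default 2).
#' @param n_restarts total starts, classical + random (default 10).
#' @param tol relative raw-stress decrease below which a run stops
#'   (default 1e-9).
#' @param max_iter iteration cap per run (default 1000).
#' @param seed integer seed for the random starts.
#' @return Object of class \code{mmds_ordination}: \code{coordinates}
#'   (N x k, sample ids as rownames), \code{stress} (Kruskal stress-1),
#'   \code{raw_stress}, \code{n_restarts_used}, \code{converged}.
#' @export
mmds <- function(d, k = 2, n_restarts = 10, tol = 1e-9, max_iter = 1000,
                 seed = NULL) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 samples")
  if (all(d == 0)) stop("degenerate all-zero distance matrix")
  if (!is.null(seed)) set.seed(seed)
  starts <- vector("list", n_restarts)
  cs <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(cs) < k)  # rank-deficient classical solution: pad with zeros
    cs <- cbind(cs, matrix(0, n, k - ncol(cs)))
  starts[[1]] <- cs
  scale0 <- max(d)
  if (n_restarts > 1)
    for (r in 2:n_restarts)
      starts[[r]] <- matrix(stats::rnorm(n * k, sd = scale0), n, k)
  best <- NULL
  for (st in starts) {
    run <- smacof_run(d, st, tol, max_iter)
    if (is.null(best) || run$raw < best$raw) best <- run
  }
  X <- best$X
  X <- sweep(X, 2, colMeans(X))  # center for presentation
  rownames(X) <- rownames(d)
  colnames(X) <- paste0("axis", seq_len(k))
  delta_hat <- as.matrix(stats::dist(X))
  structure(list(coordinates = X,
                 stress = kruskal_stress1(d[upper.tri(d)],
                                          delta_hat[upper.tri(delta_hat)]),
                 raw_stress = best$raw,
                 n_restarts_used = n_restarts,
                 converged = best$converged),
            class = "mmds_ordination")
}

#' @export
print.mmds_ordination <- function(x, ...) {
  cat(sprintf("MMDS ordination: %d samples in %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat(sprintf("  Kruskal stress-1 = %.6g  (%d restarts, converged: %s)\n",
              x$stress, x$n_restarts_used, x$converged))
  invisible(x)
}

#' @export
plot.mmds_ordination <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$coordinates[, 1], x$coordinates[, 2], col = col,
                 pch = 19, xlab = "axis 1", ylab = "axis 2",
                 main = sprintf("MMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}
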