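# Synthetic study designs with the statistical structure the analyses
# assume: M materials x 2 treatments x R replicates, material-specific
# baselines, a multiplicative treatment effect on the "dried" group, and
# log-normal replicate noise (metrics) or log-normal abundance variation
# with multinomial sequencing (communities).

#' Simulate a scalar-metric study table
#'
#' Generates a complete M materials x 2 treatments x R replicates design.
#' The metric value for a sample of material m under treatment t is
#' baseline_m * delta^[t == dried] * exp(sigma * z) with z standard normal,
#' so with sigma = 0 the material-averaged dried/frozen ratio equals delta
#' exactly, and delta = 1 is an exact null.
#'
#' @param n_materials number of source materials.
#' @param n_replicates replicates per material per treatment.
#' @param material_baselines positive baseline per material; defaults to
#'   log-spaced values between 1 and 10 (materials differ substantially, as
#'   real source materials do).
#' @param delta multiplicative treatment effect on the dried group (> 0);
#'   1 means no effect.
#' @param sigma log-normal replicate noise sd (>= 0).
#' @param treatments the two treatment labels; the first receives the effect.
#' @param metric_name name of the generated metric column.
#' @param seed integer seed; same seed, same table.
#' @return A [study_table()] with n_materials * 2 * n_replicates records.
#' @export
simulate_metric_table <- function(n_materials = 6, n_replicates = 5,
                                  material_baselines = NULL,
                                  delta = 1, sigma = 0.2,
                                  treatments = c("dried", "frozen"),
                                  metric_name = "metric",
                                  seed = NULL) {
  stopifnot(n_materials >= 1, n_replicates >= 1, delta > 0, sigma >= 0,
            length(treatments) == 2)
  if (is.null(material_baselines))
    material_baselines <- exp(seq(0, log(10), length.out = n_materials))
  if (length(material_baselines) != n_materials || any(material_baselines <= 0))
    stop("material_baselines must be ", n_materials, " positive values")
  if (!is.null(seed)) set.seed(seed)
  material <- rep(paste0("material_", seq_len(n_materials)),
                  each = 2 * n_replicates)
  treatment <- rep(rep(treatments, each = n_replicates), n_materials)
  baseline <- rep(material_baselines, each = 2 * n_replicates)
  effect <- ifelse(treatment == treatments[1], delta, 1)
  z <- stats::rnorm(length(material))
  value <- baseline * effect * exp(sigma * z)
  metrics <- stats::setNames(data.frame(value), metric_name)
  study_table(sprintf("s%03d", seq_along(material)), material, treatment,
              metrics)
}

#' Simulate compositional community data
#'
#' Generates a multinomial count table over a design of materials x 2
#' treatments x replicates. Per taxon: a base log-abundance ~ N(0, 1); per
#' (material, taxon): an offset ~ N(0, material_divergence); for dried
#' samples, a fixed random subset (\code{affected_fraction} of taxa, chosen
#' once per simulation) receives an extra \code{effect_log_fc} log
#' fold-change; per (sample, taxon): replicate noise ~ N(0, replicate_sd).
#' Counts are multinomial(depth, softmax of the summed log-abundances).
#' With affected_fraction = 0 and material_divergence = 0 all samples are
#' exchangeable (an exact null for the permutation tests).
#'
#' @param n_materials,n_replicates design size (replicates per treatment).
#' @param n_taxa number of taxa (>= 3).
#' @param material_divergence sd of per-material log-abundance offsets
#'   (>= 0); larger values separate materials more strongly.
#' @param affected_fraction fraction of taxa perturbed in dried samples,
#'   in [0, 1].
#' @param effect_log_fc log fold-change added to affected taxa in dried
#'   samples (e.g. log(4)).
#' @param depth sequencing depth (reads per sample).
#' @param replicate_sd sd of per-sample replicate noise (default 0.1).
#' @param treatments the two treatment labels; the first is perturbed.
#' @param seed integer seed; same seed, same data.
#' @return List with \code{counts} (a \code{feature_table} of kind counts,
#'   taxa x samples), \code{study} (the matching [study_table()]), and
#'   \code{affected_taxa} (ids of the perturbed taxa).
#' @export
simulate_communities <- function(n_materials = 3, n_replicates = 5,
                                 n_taxa = 100,
                                 material_divergence = 1,
                                 affected_fraction = 0,
                                 effect_log_fc = 0,
                                 depth = 1e4,
                                 replicate_sd = 0.1,
                                 treatments = c("dried", "frozen"),
                                 seed = NULL) {
  stopifnot(n_taxa >= 3, affected_fraction >= 0, affected_fraction <= 1,
            depth >= 1, material_divergence >= 0, replicate_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  base <- stats::rnorm(n_taxa)
  n_affected <- round(affected_fraction * n_taxa)
  affected <- sort(sample.int(n_taxa, n_affected))
  materials <- paste0("material_", seq_len(n_materials))
  offsets <- matrix(stats::rnorm(n_taxa * n_materials,
                                 sd = material_divergence),
                    n_taxa, n_materials, dimnames = list(taxa, materials))
  n_samples <- n_materials * 2 * n_replicates
  material <- rep(materials, each = 2 * n_replicates)
  treatment <- rep(rep(treatments, each = n_replicates), n_materials)
  ids <- sprintf("s%03d", seq_len(n_samples))
  counts <- matrix(0L, n_taxa, n_samples, dimnames = list(taxa, ids))
  for (j in seq_len(n_samples)) {
    la <- base + offsets[, material[j]] +
      stats::rnorm(n_taxa, sd = replicate_sd)
    if (treatment[j] == treatments[1] && n_affected > 0)
      la[affected] <- la[affected] + effect_log_fc
    p <- exp(la - max(la))
    counts[, j] <- stats::rmultinom(1, size = depth, prob = p / sum(p))
  }
  list(counts = feature_table(counts, "counts"),
       study = study_table(ids, material, treatment),
       affected_taxa = taxa[affected])
}
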