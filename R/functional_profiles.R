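# Gene-centric functional profile arithmetic. Inputs are tabular outputs of
# an upstream assembly/annotation pipeline (read mapping at MAPQ >= 30 and
# HMM annotation at E <= 1e-10 happen upstream): per-contig mapped-read
# counts and lengths, PCG->contig, PCG->KO and KO->KEGG-level-C maps.
# All steps are pure proportion arithmetic:
#   coverage_c = reads_c / length_c; contig proportions = coverage / sum;
#   PCG inherits its host contig's proportion, renormalized to sum 1;
#   KO proportion = sum of its PCGs' proportions (no renormalization);
#   KEGG-C group proportion = sum of its member KOs' proportions, with the
#   eight non-functional catch-all groups excluded.

#' KEGG level-C groups excluded from functional profiles
#'
#' These catch-all labels are not defined by biological function and are
#' dropped from group-level profiles (case-insensitive match).
#' @export
kegg_excluded_groups <- c(
  "brite hierarchies",
  "enzymes with ec numbers",
  "not included in pathway or brite",
  "poorly characterized",
  "general function prediction only",
  "others",
  "unclassified viral proteins",
  "function unknown")

#' Construct a contig coverage table
#'
#' @param contig_ids character vector of contig identifiers.
#' @param lengths positive integer contig lengths (bp).
#' @param counts nonnegative matrix of mapped-read counts
#'   (contigs x samples), already filtered upstream to MAPQ >= 30.
#' @return Object of class \code{contig_coverage}.
#' @export
contig_coverage_table <- function(contig_ids, lengths, counts) {
  counts <- as.matrix(counts)
  if (length(contig_ids) != length(lengths) ||
      length(contig_ids) != nrow(counts))
    stop("contig_ids, lengths and count rows must align")
  if (anyDuplicated(contig_ids)) stop("duplicate contig ids")
  if (any(lengths < 1)) stop("contig lengths must be >= 1")
  if (any(counts < 0)) stop("read counts must be nonnegative")
  rownames(counts) <- contig_ids
  structure(list(contig_ids = as.character(contig_ids),
                 lengths = as.numeric(lengths),
                 counts = counts),
            class = "contig_coverage")
}

#' Read a contig coverage table from TSV
#'
#' Expected columns: \code{contig_id}, \code{length}, then one read-count
#' column per sample.
#' @param path path to the tab-delimited file.
#' @return A [contig_coverage_table()].
#' @export
read_contig_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("contig_id", "length"))
    if (!col %in% names(df))
      stop("contig table is missing required column '", col, "'")
  cnt <- as.matrix(df[setdiff(names(df), c("contig_id", "length"))])
  contig_coverage_table(df$contig_id, df$length, cnt)
}

#' Construct a feature map
#'
#' Bundles the mapping tables connecting protein-coding genes (PCGs) to
#' their host contigs, to KEGG orthologs (KOs), and KOs to KEGG level-C
#' functional groups.
#'
#' @param pcg_to_contig data frame with columns \code{pcg_id},
#'   \code{contig_id} (one host contig per PCG).
#' @param pcg_to_ko optional data frame with columns \code{pcg_id},
#'   \code{ko_id}; a PCG may map to several KOs.
#' @param ko_to_group optional data frame with columns \code{ko_id},
#'   \code{group}; a KO may belong to several groups.
#' @param excluded_groups group labels removed from group-level output
#'   (case-insensitive); defaults to [kegg_excluded_groups].
#' @return Object of class \code{feature_map}.
#' @export
feature_map <- function(pcg_to_contig, pcg_to_ko = NULL, ko_to_group = NULL,
                        excluded_groups = kegg_excluded_groups) {
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df)))
      stop(what, " needs columns ", paste(cols, collapse = ", "))
    df[cols]
  }
  pcg_to_contig <- need(pcg_to_contig, c("pcg_id", "contig_id"),
                        "pcg_to_contig")
  if (anyDuplicated(pcg_to_contig$pcg_id))
    stop("each PCG must map to exactly one host contig")
  if (!is.null(pcg_to_ko))
    pcg_to_ko <- unique(need(pcg_to_ko, c("pcg_id", "ko_id"), "pcg_to_ko"))
  if (!is.null(ko_to_group))
    ko_to_group <- unique(need(ko_to_group, c("ko_id", "group"),
                               "ko_to_group"))
  structure(list(pcg_to_contig = pcg_to_contig,
                 pcg_to_ko = pcg_to_ko,
                 ko_to_group = ko_to_group,
                 excluded_groups = tolower(excluded_groups)),
            class = "feature_map")
}

#' Read two-column mapping TSVs into a feature map
#'
#' @param pcg_to_contig_path TSV with columns \code{pcg_id}, \code{contig_id}.
#' @param pcg_to_ko_path optional TSV with columns \code{pcg_id}, \code{ko_id}.
#' @param ko_to_group_path optional TSV with columns \code{ko_id},
#'   \code{group}.
#' @param excluded_groups as in [feature_map()].
#' @return A [feature_map()].
#' @export
read_feature_map <- function(pcg_to_contig_path, pcg_to_ko_path = NULL,
                             ko_to_group_path = NULL,
                             excluded_groups = kegg_excluded_groups) {
  rd <- function(p) if (is.null(p)) NULL else
    utils::read.delim(p, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  feature_map(rd(pcg_to_contig_path), rd(pcg_to_ko_path),
              rd(ko_to_group_path), excluded_groups)
}

#' Per-contig proportions for one sample
#'
#' Coverage is reads mapped divided by contig length; proportions are
#' coverages normalized to sum 1 within the sample.
#'
#' @param cov a [contig_coverage_table()].
#' @param sample sample (column) name.
#' @return Named numeric vector of contig proportions (sums to 1).
#' @export
contig_proportions <- function(cov, sample) {
  stopifnot(inherits(cov, "contig_coverage"))
  if (!sample %in% colnames(cov$counts))
    stop("unknown sample '", sample, "'")
  coverage <- cov$counts[, sample] / cov$lengths
  s <- sum(coverage)
  if (s <= 0) stop("sample '", sample, "' has no mapped reads")
  stats::setNames(coverage / s, cov$contig_ids)
}

#' Per-PCG proportions from contig proportions
#'
#' Each PCG inherits the proportion of its host contig; the resulting vector
#' is renormalized to sum 1.
#'
#' @param contig_props named contig-proportion vector
#'   (from [contig_proportions()]).
#' @param fmap a [feature_map()].
#' @return Named numeric vector of PCG proportions (sums to 1).
#' @export
pcg_proportions <- function(contig_props, fmap) {
  stopifnot(inherits(fmap, "feature_map"))
  map <- fmap$pcg_to_contig
  unknown <- setdiff(map$contig_id, names(contig_props))
  if (length(unknown))
    stop("PCG(s) mapped to unknown contig(s): ",
         paste(unique(unknown), collapse = ", "))
  raw <- contig_props[map$contig_id]
  s <- sum(raw)
  if (s <= 0) stop("no PCG lies on a contig with positive proportion")
  stats::setNames(raw / s, map$pcg_id)
}

#' Per-KO proportions from PCG proportions
#'
#' A KO's proportion is the sum of the proportions of all PCGs mapped to it.
#' Unannotated PCGs contribute to no KO, so the KO vector may sum to less
#' than 1; no renormalization is applied. With \code{multi_ko = "all"}
#' (default) a PCG with several KO hits contributes its full proportion to
#' each; \code{"first"} keeps only each PCG's first listed KO.
#'
#' @param pcg_props named PCG-proportion vector (from [pcg_proportions()]).
#' @param fmap a [feature_map()] with a \code{pcg_to_ko} table.
#' @param multi_ko \code{"all"} or \code{"first"}.
#' @return Named numeric vector of KO proportions.
#' @export
ko_proportions <- function(pcg_props, fmap, multi_ko = c("all", "first")) {
  multi_ko <- match.arg(multi_ko)
  stopifnot(inherits(fmap, "feature_map"))
  map <- fmap$pcg_to_ko
  if (is.null(map)) stop("feature map has no pcg_to_ko table")
  if (multi_ko == "first")
    map <- map[!duplicated(map$pcg_id), , drop = FALSE]
  map <- map[map$pcg_id %in% names(pcg_props), , drop = FALSE]
  if (nrow(map) == 0) return(stats::setNames(numeric(0), character(0)))
  v <- rowsum(pcg_props[map$pcg_id], group = map$ko_id)
  stats::setNames(as.vector(v), rownames(v))
}

#' KEGG level-C group proportions from KO proportions
#'
#' A group's proportion is the sum of its member KOs' proportions; a KO
#' belonging to several groups contributes to each. Groups on the exclusion
#' list (case-insensitive) are removed from the output.
#'
#' @param ko_props named KO-proportion vector (from [ko_proportions()]).
#' @param fmap a [feature_map()] with a \code{ko_to_group} table.
#' @return Named numeric vector of group proportions.
#' @export
kegg_group_proportions <- function(ko_props, fmap) {
  stopifnot(inherits(fmap, "feature_map"))
  map <- fmap$ko_to_group
  if (is.null(map)) stop("feature map has no ko_to_group table")
  map <- map[!tolower(map$group) %in% fmap$excluded_groups, , drop = FALSE]
  map <- map[map$ko_id %in% names(ko_props), , drop = FALSE]
  if (nrow(map) == 0) return(stats::setNames(numeric(0), character(0)))
  v <- rowsum(ko_props[map$ko_id], group = map$group)
  stats::setNames(as.vector(v), rownames(v))
}

#' Full gene-centric profile for all samples
#'
#' Convenience wrapper running contig -> PCG -> KO (-> KEGG-C group)
#' proportions for every sample and assembling [feature_table()] objects.
#'
#' @param cov a [contig_coverage_table()].
#' @param fmap a [feature_map()].
#' @param level \code{"contig"}, \code{"pcg"}, \code{"ko"} or \code{"group"}.
#' @param multi_ko passed to [ko_proportions()].
#' @return A \code{feature_table} of per-sample proportions at the requested
#'   level. Contig and PCG tables sum to 1 per sample and carry kind
#'   \code{"proportions"}. KO and group values are proportions of the full
#'   community and may sum to less than 1 (unannotated PCGs contribute to no
#'   KO), so those tables carry kind \code{"counts"}; pass them through
#'   [to_proportions()] before analyses that require exact unit sums.
#' @export
functional_profile <- function(cov, fmap,
                               level = c("ko", "group", "pcg", "contig"),
                               multi_ko = "all") {
  level <- match.arg(level)
  samples <- colnames(cov$counts)
  per_sample <- lapply(samples, function(s) {
    cp <- contig_proportions(cov, s)
    if (level == "contig") return(cp)
    pp <- pcg_proportions(cp, fmap)
    if (level == "pcg") return(pp)
    kp <- ko_proportions(pp, fmap, multi_ko)
    if (level == "ko") return(kp)
    kegg_group_proportions(kp, fmap)
  })
  ids <- sort(unique(unlist(lapply(per_sample, names))))
  m <- matrix(0, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) m[names(per_sample[[j]]), j] <- per_sample[[j]]
  feature_table(m, if (level %in% c("contig", "pcg")) "proportions"
                else "counts")
}
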