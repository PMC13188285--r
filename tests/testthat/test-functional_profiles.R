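make_fmap <- function(pcg_contig, pcg_ko = NULL, ko_group = NULL, ...) {
  feature_map(
    data.frame(pcg_id = names(pcg_contig), contig_id = unname(pcg_contig)),
    if (!is.null(pcg_ko))
      data.frame(pcg_id = rep(names(pcg_ko), lengths(pcg_ko)),
                 ko_id = unlist(pcg_ko, use.names = FALSE)),
    if (!is.null(ko_group))
      data.frame(ko_id = rep(names(ko_group), lengths(ko_group)),
                 group = unlist(ko_group, use.names = FALSE)),
    ...)
}

test_that("contig proportions are length-normalized coverages summing to 1", {
  cov <- contig_coverage_table(c("c1", "c2"), c(1000, 4000),
                               matrix(c(10, 20), 2, 1,
                                      dimnames = list(NULL, "s1")))
  p <- contig_proportions(cov, "s1")
  # coverages 0.01 and 0.005 -> proportions 2/3, 1/3
  expect_equal(unname(p), c(2 / 3, 1 / 3))
  expect_equal(sum(p), 1, tolerance = 1e-9)

  one <- contig_coverage_table("c1", 500,
                               matrix(7, 1, 1, dimnames = list(NULL, "s1")))
  expect_equal(unname(contig_proportions(one, "s1")), 1)

  # equal coverages over n contigs -> 1/n each
  eq <- contig_coverage_table(paste0("c", 1:5), rep(100, 5) * (1:5),
                              matrix(2 * (1:5), 5, 1,
                                     dimnames = list(NULL, "s1")))
  expect_equal(unname(contig_proportions(eq, "s1")), rep(0.2, 5))

  zero <- contig_coverage_table("c1", 100,
                                matrix(0, 1, 1, dimnames = list(NULL, "s1")))
  expect_error(contig_proportions(zero, "s1"), "no mapped reads")
})

test_that("PCG proportions inherit host-contig proportions, renormalized", {
  # contigs A (0.8, 3 PCGs) and B (0.2, 1 PCG)
  cp <- c(A = 0.8, B = 0.2)
  fmap <- make_fmap(c(p1 = "A", p2 = "A", p3 = "A", p4 = "B"))
  pp <- pcg_proportions(cp, fmap)
  expect_equal(unname(pp), c(0.8, 0.8, 0.8, 0.2) / 2.6, tolerance = 1e-12)
  expect_equal(sum(pp), 1, tolerance = 1e-9)

  # 2 PCGs on a single contig of proportion 1 -> 0.5 each
  pp2 <- pcg_proportions(c(X = 1), make_fmap(c(g1 = "X", g2 = "X")))
  expect_equal(unname(pp2), c(0.5, 0.5))

  # 1 PCG per contig -> PCG proportions equal contig proportions
  pp3 <- pcg_proportions(c(A = 0.3, B = 0.7), make_fmap(c(u = "A", v = "B")))
  expect_equal(unname(pp3), c(0.3, 0.7))

  expect_error(pcg_proportions(c(A = 1), make_fmap(c(p1 = "Z"))),
               "unknown contig")
})

test_that("KO proportions sum mapped PCGs and conserve annotated mass", {
  pp <- c(p1 = 0.6, p2 = 0.4)
  # both PCGs map to the same KO
  kp <- ko_proportions(pp, make_fmap(c(p1 = "A", p2 = "A"),
                                     pcg_ko = list(p1 = "K1", p2 = "K1")))
  expect_equal(unname(kp), 1.0)

  # distinct KOs: KO vector equals the PCG vector
  kp2 <- ko_proportions(pp, make_fmap(c(p1 = "A", p2 = "A"),
                                      pcg_ko = list(p1 = "K1", p2 = "K2")))
  expect_equal(unname(kp2[c("K1", "K2")]), c(0.6, 0.4))

  # unannotated PCGs contribute nothing: sum(KO) <= 1
  pp3 <- c(p1 = 0.5, p2 = 0.5)
  kp3 <- ko_proportions(pp3, make_fmap(c(p1 = "A", p2 = "A"),
                                       pcg_ko = list(p1 = "K1")))
  expect_equal(sum(kp3), 0.5)

  # multi-KO PCG: full proportion to each KO, or first hit only
  fm <- make_fmap(c(p1 = "A"), pcg_ko = list(p1 = c("K1", "K2")))
  expect_equal(unname(ko_proportions(c(p1 = 0.3), fm)[c("K1", "K2")]),
               c(0.3, 0.3))
  expect_equal(sum(ko_proportions(c(p1 = 0.3), fm, multi_ko = "first")), 0.3)
})

test_that("KEGG group proportions sum member KOs and apply the exclusions", {
  kp <- c(K1 = 0.2, K2 = 0.3, K3 = 0.5)
  fm <- make_fmap(c(p1 = "A"),
                  ko_group = list(K1 = c("Metabolism", "Transport"),
                                  K2 = "Metabolism",
                                  K3 = "Function Unknown"))
  gp <- kegg_group_proportions(kp, fm)
  expect_equal(gp[["Metabolism"]], 0.5)
  expect_equal(gp[["Transport"]], 0.2)  # multimap: K1 counted in both
  # "function unknown" excluded case-insensitively, whatever its content
  expect_false("Function Unknown" %in% names(gp))

  # one all-encompassing group, nothing excluded
  fm2 <- make_fmap(c(p1 = "A"),
                   ko_group = list(K1 = "All", K2 = "All", K3 = "All"),
                   excluded_groups = character(0))
  expect_equal(kegg_group_proportions(kp, fm2)[["All"]], sum(kp))

  expect_length(kegg_excluded_groups, 8)
})

test_that("the profile pipeline is scale-free in sample read counts", {
  counts <- matrix(c(10, 20, 5, 40, 80, 20), 3, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  cov1 <- contig_coverage_table(c("c1", "c2", "c3"), c(100, 400, 50), counts)
  cov2 <- contig_coverage_table(c("c1", "c2", "c3"), c(100, 400, 50),
                                counts * 13L)
  fmap <- make_fmap(c(p1 = "c1", p2 = "c2", p3 = "c3", p4 = "c3"),
                    pcg_ko = list(p1 = "K1", p2 = "K2", p3 = "K2"))
  for (s in c("s1", "s2")) {
    cp1 <- contig_proportions(cov1, s)
    cp2 <- contig_proportions(cov2, s)
    expect_equal(cp1, cp2, tolerance = 1e-12)
    pp <- pcg_proportions(cp1, fmap)
    expect_equal(sum(pp), 1, tolerance = 1e-9)
    kp1 <- ko_proportions(pp, fmap)
    expect_equal(kp1, ko_proportions(pcg_proportions(cp2, fmap), fmap),
                 tolerance = 1e-12)
    # single-KO mapping: KO mass equals mass of annotated PCGs
    expect_equal(sum(kp1), sum(pp[c("p1", "p2", "p3")]), tolerance = 1e-12)
  }
})

test_that("profile tables read from TSV reproduce the in-memory pipeline", {
  dir <- withr::local_tempdir()
  writeLines(c("contig_id\tlength\ts1\ts2",
               "c1\t1000\t10\t30",
               "c2\t4000\t20\t10"),
             file.path(dir, "contigs.tsv"))
  writeLines(c("pcg_id\tcontig_id", "p1\tc1", "p2\tc1", "p3\tc2"),
             file.path(dir, "pcg.tsv"))
  writeLines(c("pcg_id\tko_id", "p1\tK1", "p2\tK2", "p3\tK2"),
             file.path(dir, "ko.tsv"))
  writeLines(c("ko_id\tgroup", "K1\tMetabolism", "K2\tMetabolism",
               "K2\tbrite hierarchies"),
             file.path(dir, "grp.tsv"))
  cov <- read_contig_table(file.path(dir, "contigs.tsv"))
  fmap <- read_feature_map(file.path(dir, "pcg.tsv"),
                           file.path(dir, "ko.tsv"),
                           file.path(dir, "grp.tsv"))
  prof <- functional_profile(cov, fmap, level = "ko")
  cp <- contig_proportions(cov, "s1")
  pp <- pcg_proportions(cp, fmap)
  expect_equal(prof$values[, "s1"],
               ko_proportions(pp, fmap)[rownames(prof$values)],
               tolerance = 1e-12)
  grp <- functional_profile(cov, fmap, level = "group")
  expect_equal(rownames(grp$values), "Metabolism")  # brite excluded
  expect_equal(unname(colSums(functional_profile(cov, fmap,
                                                 level = "pcg")$values)),
               c(1, 1), tolerance = 1e-9)
})
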