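test_that("regulatory boundary: window, containing loop, tie-breaks", {
  g <- list(gene_id = "g1", chrom = "chr1", tss = 2e6, strand = "+")
  no_loops <- tibble::tibble(chrom = character(), span_start = integer(),
                             span_end = integer())
  b <- regulatory_boundary(g, no_loops)
  expect_equal(c(b$start, b$end), c(1e6, 3e6))
  # clipping at 0 for a TSS near the chromosome start
  b0 <- regulatory_boundary(list(chrom = "chr1", tss = 4e5), no_loops)
  expect_equal(b0$start, 0)

  loops <- tibble::tibble(chrom = "chr1",
                          span_start = c(1.5e6, 1.0e6),
                          span_end = c(2.2e6, 2.9e6))
  b1 <- regulatory_boundary(g, loops)
  expect_equal(c(b1$start, b1$end), c(1.5e6, 2.2e6))  # smallest containing loop
  # a loop wider than the window does not shrink it
  wide <- tibble::tibble(chrom = "chr1", span_start = 0, span_end = 5e6)
  b2 <- regulatory_boundary(g, wide)
  expect_equal(c(b2$start, b2$end), c(1e6, 3e6))
  # tie on span: leftmost start wins
  tie <- tibble::tibble(chrom = "chr1",
                        span_start = c(1.8e6, 1.9e6),
                        span_end = c(2.3e6, 2.4e6))
  b3 <- regulatory_boundary(g, tie)
  expect_equal(b3$start, 1.8e6)
  # loop not containing the TSS is ignored
  off <- tibble::tibble(chrom = "chr1", span_start = 0, span_end = 1.5e6)
  b4 <- regulatory_boundary(g, off)
  expect_equal(c(b4$start, b4$end), c(1e6, 3e6))
})

test_that("candidate REs: mark intersection plus strand-aware promoters", {
  genes <- tibble::tibble(gene_id = c("gp", "gm"), chrom = "chr1",
                          tss = c(10000L, 5000L), strand = c("+", "-"))
  # disjoint marks -> promoters only
  a <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L)
  b <- tibble::tibble(chrom = "chr1", start = 400L, end = 500L)
  got <- build_candidate_res(a, b, genes)
  expect_true(all(got$class == "promoter"))
  expect_equal(got$start[got$gene_id == "gp"], 8000)   # [TSS-2k, TSS) on +
  expect_equal(got$end[got$gene_id == "gp"], 10000)
  expect_equal(got$start[got$gene_id == "gm"], 5000)   # [TSS, TSS+2k) on -
  expect_equal(got$end[got$gene_id == "gm"], 7000)

  # overlapping marks: intersection interval [200, 300)
  b2 <- tibble::tibble(chrom = "chr1", start = 200L, end = 400L)
  got2 <- build_candidate_res(a, b2, genes)
  distal <- got2[got2$class == "distal", ]
  expect_equal(nrow(distal), 1L)
  expect_equal(c(distal$start, distal$end), c(200, 300))
})

test_that("candidate map matches hand enumeration and respects boundaries", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                          tss = c(1e6, 3e6, 5e6), strand = "+")
  res <- tibble::tibble(
    re_id = c("prom_g1", "prom_g2", "prom_g3", "d1", "d2", "d3"),
    chrom = "chr1",
    start = c(1e6 - 2000, 3e6 - 2000, 5e6 - 2000, 1.5e6, 2.5e6, 9e6),
    end   = c(1e6, 3e6, 5e6, 1.5e6 + 500, 2.5e6 + 500, 9e6 + 500),
    class = c(rep("promoter", 3), rep("distal", 3)),
    gene_id = c("g1", "g2", "g3", NA, NA, NA))
  no_loops <- tibble::tibble(chrom = character(), span_start = integer(),
                             span_end = integer())
  boundaries <- regulatory_boundaries(genes, no_loops)
  map <- candidate_map(res, genes, boundaries)
  I <- split(map$re_id, map$gene_id)
  expect_setequal(I$g1, c("prom_g1", "d1"))                 # within [0, 2e6)
  expect_setequal(I$g2, c("prom_g2", "d2"))                 # within [2e6, 4e6)
  expect_setequal(I$g3, "prom_g3")                          # d3 at 9 Mb is outside
  expect_false("d3" %in% map$re_id)
  # every candidate overlaps its gene's boundary
  for (i in seq_len(nrow(map))) {
    b <- boundaries[boundaries$gene_id == map$gene_id[i], ]
    r <- res[res$re_id == map$re_id[i], ]
    expect_true(r$start < b$end && r$end > b$start)
  }
  # a gene with no promoter RE is skipped with a warning
  expect_warning(
    m2 <- candidate_map(res[res$re_id != "prom_g3", ], genes, boundaries),
    "no promoter")
  expect_false("g3" %in% m2$gene_id)
})

test_that("openness: fold change of reads per bp over the genome average", {
  counts <- matrix(c(10, 20), 1, 2, dimnames = list("r1", c("s1", "s2")))
  got <- openness_scores(counts, re_lengths = 100,
                         library_sizes = c(1000, 1000), genome_len = 10000)
  expect_equal(got["r1", "s1"], 1.0)    # (10/100)/(1000/10000)
  expect_equal(got["r1", "s2"], 2.0)    # count doubled -> score doubled
  # uniform coverage gives 1 everywhere
  cu <- matrix(c(50, 150), 2, 1, dimnames = list(c("a", "b"), "s1"))
  ou <- openness_scores(cu, re_lengths = c(100, 300),
                        library_sizes = 5000, genome_len = 10000)
  expect_equal(unname(ou[, 1]), c(1, 1))
  # invariance to joint library rescaling
  o2 <- openness_scores(counts * 7, 100, c(7000, 7000), 10000)
  expect_equal(o2, got)
  expect_error(openness_scores(counts, 100, c(0, 1000), 1e4), "library size")
})

test_that("replicate-consistency filter drops all-zero and inconsistent rows", {
  design <- flat_design(n_rep = 1)  # 2 samples, one group per population
  d5 <- toy_design(n_rep = 5, times = "0h")   # 5 reps x 2 populations
  m <- rbind(
    zero = rep(0, 10),
    bad  = c(1, 600, 2, 3, 4, 1, 1, 1, 1, 1),     # adaptive group 600/1 > 500
    edge = c(2, 900, 3, 4, 5, 2, 2, 2, 2, 2),     # 900/2 = 450 <= 500
    zmin = c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1),       # min 0, max > 0 in a group
    ok   = rep(2, 10))
  colnames(m) <- d5$sample_id
  got <- filter_rows(m, d5, max_min_ratio = 500)
  rep_of <- function(id) got$report$reason[got$report$id == id]
  expect_equal(rep_of("zero"), "all_zero")
  expect_equal(rep_of("bad"), "replicate_inconsistent")
  expect_equal(rep_of("zmin"), "replicate_inconsistent")
  expect_true(all(c("edge", "ok") %in% rownames(got$kept)))
  expect_setequal(got$report$id, rownames(m))
  # idempotence: filtering the kept rows drops nothing
  again <- filter_rows(got$kept, d5, max_min_ratio = 500)
  expect_true(all(again$report$kept))
})
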