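test_that("run detection matches brute-force window enumeration", {
  set.seed(501)
  params_pool <- list(
    roh_params(min_markers = 10, min_length_bp = 2e5, max_het_per_run = 1,
               max_missing_per_run = 2, max_gap_bp = 2e5),
    roh_params(min_markers = 5, min_length_bp = 5e4, max_het_per_run = 0,
               max_missing_per_run = 0, max_gap_bp = 1e5),
    roh_params(min_markers = 8, min_length_bp = 1e5, max_het_per_run = 2,
               max_missing_per_run = 3, max_gap_bp = 5e4))
  for (rep in 1:12) {
    n <- sample(50:500, 1L)
    tracts <- if (runif(1) < 0.7) {
      from <- sample(seq_len(n - 20L), 1L)
      data.frame(from_idx = from, to_idx = min(n, from + sample(10:60, 1L)))
    } else NULL
    gm <- random_genotype_matrix(n, spacing = sample(c(5000, 20000), 1L),
                                 het_prob = runif(1, 0.1, 0.5),
                                 tracts = tracts)
    par <- params_pool[[sample(3L, 1L)]]
    got <- detect_roh(gm, "case", par)
    want <- brute_roh(gm, "case", par)
    expect_equal(got[, c("chrom", "start", "end", "n_markers")],
                 want[, c("chrom", "start", "end", "n_markers")],
                 ignore_attr = TRUE)
  }
})

test_that("planted tracts are recovered exactly at the stated thresholds", {
  par <- roh_params(min_markers = 50, min_length_bp = 1e6,
                    max_het_per_run = 1, max_missing_per_run = 2,
                    max_gap_bp = 1e6)
  set.seed(502)
  # 60 hom markers over 1.5 Mb with one het call inside -> one segment
  pos <- seq(1e6, by = 25423, length.out = 200)
  calls <- sample(c(0L, 1L), 200, replace = TRUE)  # het-rich background
  calls[70:129] <- 2L
  calls[100] <- 1L                                  # tolerated het
  gm <- genotype_matrix(
    data.frame(chrom = "1", pos = pos, ref = "A", alt = "C"),
    matrix(calls, 1, dimnames = list("x", NULL)))
  seg <- detect_roh(gm, "x", par)
  expect_equal(nrow(seg), 1L)
  expect_lte(seg$start, pos[70])   # the run covers the planted tract
  expect_gte(seg$end, pos[129])
  expect_lte(seg$n_het, par$max_het_per_run)
  expect_equal(seg[, c("start", "end", "n_markers")],
               brute_roh(gm, "x", par)[, c("start", "end", "n_markers")],
               ignore_attr = TRUE)

  # below min_markers: 40-marker tract is discarded
  calls2 <- sample(c(0L, 1L), 200, replace = TRUE)
  calls2[81:120] <- 2L
  calls2[c(80, 121)] <- 1L
  gm2 <- genotype_matrix(gm$map,
                         matrix(calls2, 1, dimnames = list("x", NULL)))
  expect_equal(nrow(detect_roh(gm2, "x", par)), 0L)

  # an all-heterozygous individual yields nothing
  gm3 <- genotype_matrix(gm$map,
                         matrix(rep(1L, 200), 1, dimnames = list("x", NULL)))
  expect_equal(nrow(detect_roh(gm3, "x", par)), 0L)
  expect_error(detect_roh(gm, "nobody", par), "unknown")
})

test_that("parental exclusion subtracts intervals and honours the length floor", {
  seg <- function(id, start, end) {
    data.frame(individual = id, chrom = "1", start = start, end = end,
               stringsAsFactors = FALSE)
  }
  # fully inside a parental segment -> removed
  out <- exclude_parental(seg("c", 2e6, 4e6), seg("p", 1e6, 5e6))
  expect_equal(nrow(out), 0L)
  # no overlap -> unchanged
  out <- exclude_parental(seg("c", 2e6, 4e6), seg("p", 6e6, 9e6))
  expect_equal(out$start, 2e6); expect_equal(out$end, 4e6)
  # 3 Mb case segment, 1 Mb parental overlap at the left end -> one 2 Mb piece
  out <- exclude_parental(seg("c", 1e6, 3999999), seg("p", 5e5, 1999999),
                          min_novel_length_bp = 1e6)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 2e6)
  expect_equal(out$end, 3999999)
  # pieces below the floor vanish; union of both parents is subtracted
  out <- exclude_parental(seg("c", 1e6, 4e6),
                          rbind(seg("p1", 1.5e6, 2.5e6),
                                seg("p2", 2.4e6, 3.8e6)),
                          min_novel_length_bp = 1e6)
  expect_equal(nrow(out), 0L)
  # drop mode rejects on any overlap
  out <- exclude_parental(seg("c", 1e6, 3999999), seg("p", 5e5, 1099999),
                          mode = "drop")
  expect_equal(nrow(out), 0L)
})

test_that("novel segments never overlap parental segments (property)", {
  set.seed(503)
  for (rep in 1:10) {
    cs <- data.frame(individual = "c", chrom = "1",
                     start = sort(sample(seq(1e6, 5e7, by = 1e6), 3)))
    cs$end <- cs$start + sample(seq(1e6, 8e6, by = 1e6), 3)
    ps <- data.frame(individual = "p", chrom = "1",
                     start = sort(sample(seq(1e6, 5e7, by = 5e5), 5)))
    ps$end <- ps$start + sample(seq(5e5, 6e6, by = 5e5), 5)
    out <- exclude_parental(cs, ps, min_novel_length_bp = 1)
    if (nrow(out) == 0L) next
    ov <- IRanges::findOverlaps(IRanges::IRanges(out$start, out$end),
                                IRanges::IRanges(ps$start, ps$end))
    expect_length(ov, 0L)
  }
})

test_that("shared homozygosity keeps only same-allele intersections", {
  pos <- seq(1e6, by = 2e4, length.out = 300)
  map <- data.frame(chrom = "1", pos = pos, ref = "A", alt = "C")
  mk <- function(...) {
    m <- rbind(...)
    rownames(m) <- paste0("case", seq_len(nrow(m)))
    genotype_matrix(map, m)
  }
  par <- roh_params(min_markers = 20, min_length_bp = 3e5,
                    max_het_per_run = 0, max_missing_per_run = 1,
                    max_gap_bp = 1e6)
  base <- rep(1L, 300)
  a <- base; a[50:149] <- 2L            # shared tract, same allele
  b <- base; b[50:149] <- 2L; b[200:260] <- 0L   # plus a private tract
  gm <- mk(a, b)
  segs <- list(case1 = detect_roh(gm, "case1", par),
               case2 = detect_roh(gm, "case2", par))
  sh <- shared_homozygosity(segs, gm)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$start, pos[50]); expect_equal(sh$end, pos[149])
  # opposite alleles over the same interval -> excluded
  b2 <- base; b2[50:149] <- 0L
  gm2 <- mk(a, b2)
  segs2 <- list(case1 = detect_roh(gm2, "case1", par),
                case2 = detect_roh(gm2, "case2", par))
  expect_equal(nrow(shared_homozygosity(segs2, gm2)), 0L)
  # single case: identity
  one <- shared_homozygosity(segs["case1"], gm)
  expect_equal(one$start, segs$case1$start)
})

test_that("genome fraction sums non-overlapping segment lengths", {
  expect_equal(genome_fraction_homozygous(empty_seg <- data.frame(
    individual = character(), chrom = character(), start = numeric(),
    end = numeric()), 1e8), 0)
  one <- data.frame(individual = "x", chrom = "1",
                    start = 1, end = 25e6)
  expect_equal(genome_fraction_homozygous(one, 1e8), 0.25)
  two <- rbind(one, data.frame(individual = "x", chrom = "1",
                               start = 2e7, end = 3e7))
  expect_error(genome_fraction_homozygous(two, 1e8), "overlap")
  expect_error(genome_fraction_homozygous(one, 0), "positive")
})

test_that("candidate-gene intersection is 1 bp-exact at the boundaries", {
  genes <- data.frame(gene = c("g1", "g2", "g3"), chrom = "1",
                      start = c(100, 300, 500), end = c(199, 399, 599))
  expect_equal(nrow(intersect_candidates(
    data.frame(chrom = character(), start = numeric(), end = numeric()),
    genes)), 0L)
  # region abutting g1 without overlap; touching g2 by exactly one base
  regions <- data.frame(chrom = "1", start = c(200, 399), end = c(250, 450))
  hit <- intersect_candidates(regions, genes)
  expect_setequal(hit$gene, "g2")
  # 8-of-18 fixture: genes inside planted regions are exactly recovered
  set.seed(504)
  g18 <- data.frame(gene = sprintf("g%02d", 1:18), chrom = "2",
                    start = seq(1e6, by = 2e6, length.out = 18))
  g18$end <- g18$start + 5e4
  inside <- sort(sample(18, 8))
  reg <- data.frame(chrom = "2", start = g18$start[inside] - 1e4,
                    end = g18$end[inside] + 1e4)
  expect_setequal(intersect_candidates(reg, g18)$gene, g18$gene[inside])
})

test_that("BED round-trip converts between 0-based half-open and 1-based", {
  df <- data.frame(chrom = "1", start = c(101, 5001), end = c(200, 6000),
                   gene = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(df, path)
  raw <- read.table(path, sep = "\t")
  expect_equal(raw$V2, c(100, 5000))   # BED start is 0-based
  back <- read_bed(path)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
})
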