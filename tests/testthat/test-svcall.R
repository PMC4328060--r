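lib_config <- function(depth = 20, seed = NULL) {
  sim_config(seed = 1L, n_chrom = 1L, chrom_length = 2e5,
             deletion = list(chrom = 1L, start = 100000, end = 102432,
                             carrier = "IV/A"),
             shared_deletion = NULL, insert_mean = 300, insert_sd = 30,
             read_length = 100L, depth = depth, read_flank = 10000)
}

locus_region <- function() list(chrom = "1", start = 90000, end = 112432)
causal_del <- function() data.frame(start = 100000, end = 102432)

hom_library <- function(seed, depth = 20) {
  cfg <- lib_config(depth)
  simulate_read_pairs(cfg, locus_region(), causal_del(), causal_del(),
                      sample = "case", seed = seed)
}

wt_library <- function(seed, depth = 20) {
  cfg <- lib_config(depth)
  simulate_read_pairs(cfg, locus_region(), NULL, NULL, sample = "wt",
                      seed = seed)
}

test_that("insert-size model is accurate and robust to discordant contamination", {
  set.seed(701)
  n <- 10000L
  span <- round(rnorm(n, 300, 30))
  pairs <- data.frame(fragment = paste0("f", 1:n), chrom = "1",
                      m1_start = 1000, m1_end = 1099,
                      m2_start = 1000 + span - 100, m2_end = 1000 + span - 1,
                      orientation = "FR", mapq = 60L)
  m <- fit_insert_model(pairs)
  expect_lt(abs(m$location - 300), 3)
  expect_lt(abs(m$scale - 30), 3)
  # 5% of pairs inflated by a 2,433 bp deletion barely moves the location
  pairs2 <- pairs
  inflate <- sample(n, n * 0.05)
  pairs2$m2_start[inflate] <- pairs2$m2_start[inflate] + 2433
  pairs2$m2_end[inflate] <- pairs2$m2_end[inflate] + 2433
  m2 <- fit_insert_model(pairs2)
  expect_lt(abs(m2$location - 300), 3)
  # degenerate scale and too-few-pairs guards
  const <- pairs[1:100, ]
  const$m2_end <- const$m1_start + 299
  const$m2_start <- const$m2_end - 99
  expect_error(fit_insert_model(const), "degenerate")
  expect_error(fit_insert_model(pairs[1:10, ]), "at least 50")
})

test_that("discordance is a strict span threshold on FR pairs with good mapq", {
  model <- structure(list(location = 300, scale = 30, k = 3, n = 100),
                     class = "insert_size_model")
  mk_pair <- function(span, ori = "FR", mapq = 60L) {
    data.frame(fragment = "f", chrom = "1", m1_start = 1000, m1_end = 1099,
               m2_start = 1000 + span - 100, m2_end = 1000 + span - 1,
               orientation = ori, mapq = mapq)
  }
  expect_equal(nrow(find_discordant(mk_pair(300), model)), 0L)
  expect_equal(nrow(find_discordant(mk_pair(390), model)), 0L)  # boundary
  expect_equal(nrow(find_discordant(mk_pair(391), model)), 1L)
  expect_equal(nrow(find_discordant(mk_pair(2733, ori = "RF"), model)), 0L)
  expect_equal(nrow(find_discordant(mk_pair(2733, mapq = 5L), model)), 0L)
})

test_that("a single discordant pair becomes a call with its inner gap", {
  model <- structure(list(location = 300, scale = 30, k = 3, n = 100),
                     class = "insert_size_model")
  pair <- data.frame(fragment = "f1", chrom = "1", m1_start = 1000,
                     m1_end = 1099, m2_start = 3500, m2_end = 3599,
                     orientation = "FR", mapq = 60L)
  calls <- cluster_discordant(pair, model, min_support = 1L, min_size = 300)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 1100)
  expect_equal(calls$end, 3499)
  expect_equal(calls$support, 1L)
  expect_equal(calls$size_est, 2600 - 300)
  expect_equal(supporting_pairs(calls[1, ], pair)$fragment, "f1")
})

test_that("a planted homozygous deletion yields one accurate hom_del call", {
  pairs <- hom_library(seed = 702)
  calls <- call_deletions(pairs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$genotype, "hom_del")
  model <- fit_insert_model(pairs)
  expect_lt(abs(calls$size_est - 2433),
            3 * model$scale / sqrt(calls$support))
  # breakpoint interval contains the true breakpoints
  expect_lte(calls$start, 100000)
  expect_gte(calls$end, 102432)
  expect_lte(100000 - calls$start, model$location)
  expect_lte(calls$end - 102432, model$location)
})

test_that("heterozygous and wildtype loci genotype correctly", {
  cfg <- lib_config()
  het <- simulate_read_pairs(cfg, locus_region(), NULL, causal_del(),
                             sample = "het", seed = 703)
  calls <- call_deletions(het)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$genotype, "het_del")
  expect_true(calls$support_ratio >= 0.3 && calls$support_ratio < 0.8)
  # wildtype: no cluster survives
  wt <- wt_library(seed = 704)
  expect_equal(nrow(call_deletions(wt)), 0L)
})

test_that("two deletions 50 kb apart produce two separate calls", {
  cfg <- sim_config(seed = 1L, n_chrom = 1L, chrom_length = 3e5,
                    deletion = list(chrom = 1L, start = 100000, end = 102432,
                                    carrier = "IV/A"),
                    shared_deletion = NULL, depth = 20, read_flank = 10000)
  dels <- data.frame(start = c(100000, 152433), end = c(102432, 154932))
  pairs <- simulate_read_pairs(cfg, list(chrom = "1", start = 80000,
                                         end = 180000),
                               dels, dels, sample = "x", seed = 705)
  calls <- call_deletions(pairs)
  expect_equal(nrow(calls), 2L)
  expect_true(all(calls$genotype == "hom_del"))
  expect_lt(abs(calls$size_est[1] - 2433), 60)
  expect_lt(abs(calls$size_est[2] - 2500), 60)
})

test_that("private-deletion filtering uses 50% reciprocal overlap", {
  case <- data.frame(chrom = "1", start = c(1000, 5000, 9000),
                     end = c(2000, 6000, 9500), support = 5L,
                     size_est = 1000, genotype = "hom_del")
  ctrl_match <- data.frame(chrom = "1", start = 1100, end = 2100)
  ctrl_engulf <- data.frame(chrom = "1", start = 1901, end = 6500)
  ctrl_match2 <- data.frame(chrom = "1", start = 5400, end = 6400)
  out <- private_deletions(case, list(ctrl_match))
  expect_equal(out$start, c(5000, 9000))     # matched call dropped
  # full overlap by a much larger control call fails the reciprocal rule
  out2 <- private_deletions(case, list(ctrl_engulf))
  expect_equal(out2$start, c(1000, 5000, 9000))
  expect_equal(private_deletions(case, list(ctrl_match2))$start,
               c(1000, 9000))
  expect_equal(nrow(private_deletions(case, list())), 3L)
  expect_equal(nrow(private_deletions(case, list(ctrl_match, ctrl_match2))),
               1L)
})

test_that("deletion calls export as symbolic DEL VCF records", {
  calls <- data.frame(chrom = "16", start = 65704617, end = 65707049,
                      support = 12L, size_est = 2433.4,
                      genotype = "hom_del")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_deletion_vcf(calls, path, sample = "case1")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix   # always a matrix, even for one record
  expect_equal(as.integer(fix[, "POS"]), 65704616L)  # anchor base
  expect_equal(unname(fix[, "ALT"]), "<DEL>")
  expect_match(unname(v@fix[, "INFO"]), "SVTYPE=DEL;END=65707049;SVLEN=-2433")
  expect_equal(unname(vcfR::extract.gt(v)[1, 1]), "1/1")
})

test_that("SAM input reduces to the flat read-pair table", {
  skip_if_not_installed("Rsamtools")
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:100000",
           paste("frag1", 99, "chr1", 1001, 60, "100M", "=", 1201, 300,
                 strrep("A", 100), strrep("I", 100), sep = "\t"),
           paste("frag1", 147, "chr1", 1201, 60, "100M", "=", 1001, -300,
                 strrep("A", 100), strrep("I", 100), sep = "\t"))
  path <- withr::local_tempfile(lines = sam, fileext = ".sam")
  pairs <- read_pairs_from_sam(path, sample = "s1")
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$m1_start, 1001)
  expect_equal(pairs$m2_end, 1300)
  expect_equal(pairs$orientation, "FR")
  expect_equal(pairs$mapq, 60L)
})
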