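# gene model mirroring the case-study geometry: exon 1 carries the start
# codon plus 79 coding bases and is wholly contained in the deletion
lamc2_like <- function() {
  del <- list(chrom = "16", start = 65704617, end = 65707049)
  ex1 <- c(del$start + 933, del$start + 1332)
  model <- gene_model(
    "LAMC2like", "TX1", chrom = "16", strand = "+",
    exons = data.frame(start = c(ex1[1], del$end + 1051, del$end + 2951),
                       end = c(ex1[2], del$end + 2571, del$end + 5150)),
    cds_start = ex1[2] - 78, cds_end = del$end + 2951 + 1999)
  list(del = del, model = model)
}

test_that("deletion length is inclusive-interval arithmetic", {
  expect_equal(deletion_length(65704617, 65707049), 2433L)
  expect_equal(deletion_length(5, 5), 1L)
  expect_error(deletion_length(10, 9), "end must be")
  set.seed(801)
  for (i in 1:100) {
    s <- sample(1e6, 1)
    e <- s + sample(0:5000, 1)
    expect_equal(deletion_length(s, e), length(seq(s, e)))
  }
})

test_that("full exon-1 deletion is start_lost with 79 coding bases removed", {
  fx <- lamc2_like()
  cc <- classify_consequence(fx$del, fx$model)
  expect_equal(cc$class, "start_lost")
  expect_equal(cc$coding_bases_deleted, 79L)
  expect_equal(cc$exons_lost, 1L)
  expect_true(cc$start_codon_lost)
})

test_that("consequence classes cover intronic, truncation, exon loss and flanks", {
  m <- gene_model("G", "T", chrom = "1", strand = "+",
                  exons = data.frame(start = c(11000, 13000, 15000),
                                     end = c(11199, 13399, 15499)),
                  cds_start = 11100, cds_end = 15200)
  cls <- function(s, e, chrom = "1")
    classify_consequence(list(chrom = chrom, start = s, end = e), m)
  expect_equal(cls(11500, 12500)$class, "intronic")
  expect_equal(cls(11500, 12500)$coding_bases_deleted, 0L)
  expect_equal(cls(13200, 13250)$class, "cds_truncation")
  expect_equal(cls(13200, 13250)$coding_bases_deleted, 51L)
  expect_equal(cls(12900, 13500)$class, "exon_loss")
  expect_equal(cls(11099, 11101)$class, "start_lost")  # clips the codon
  expect_equal(cls(11103, 11110)$class, "cds_truncation")  # codon intact
  expect_equal(cls(9500, 10900)$class, "upstream")
  expect_equal(cls(100, 200)$class, "intergenic")
  expect_warning(bad <- cls(11000, 11200, chrom = "2"),
                 "different chromosome")
  expect_equal(bad$class, "intergenic")
  # deleted coding bases never exceed the deletion or the CDS length
  set.seed(802)
  cds_len <- 100 + 400 + 201
  for (i in 1:50) {
    s <- sample(10500:15500, 1); e <- s + sample(0:3000, 1)
    cc <- cls(s, e)
    expect_lte(cc$coding_bases_deleted, min(e - s + 1, cds_len))
  }
})

test_that("classification is strand-symmetric under coordinate reflection", {
  L <- 100000
  reflect <- function(x) L - x + 1
  set.seed(803)
  for (i in 1:20) {
    repeat {
      e1 <- sort(sample(1000:20000, 6))
      if (min(e1[c(2, 4, 6)] - e1[c(1, 3, 5)]) >= 30) break
    }
    exons <- data.frame(start = e1[c(1, 3, 5)], end = e1[c(2, 4, 6)])
    cds_start <- exons$start[1] + 10
    cds_end <- exons$end[3] - 10
    plus <- gene_model("G", "T", "1", "+", exons, cds_start, cds_end)
    minus <- gene_model("G", "T", "1", "-",
                        data.frame(start = reflect(exons$end),
                                   end = reflect(exons$start)),
                        reflect(cds_end), reflect(cds_start))
    s <- sample(500:25000, 1); e <- s + sample(0:8000, 1)
    cp <- classify_consequence(list(chrom = "1", start = s, end = e), plus)
    cm <- classify_consequence(list(chrom = "1", start = reflect(e),
                                    end = reflect(s)), minus)
    expect_equal(cm$class, cp$class)
    expect_equal(cm$coding_bases_deleted, cp$coding_bases_deleted)
  }
})

test_that("minus-strand start codon sits at the high-coordinate CDS end", {
  m <- gene_model("G", "T", chrom = "1", strand = "-",
                  exons = data.frame(start = c(1000, 3000),
                                     end = c(1499, 3399)),
                  cds_start = 1200, cds_end = 3350)
  # deleting the highest-coordinate exon removes the translation start
  cc <- classify_consequence(list(chrom = "1", start = 2900, end = 3500), m)
  expect_equal(cc$class, "start_lost")
  # deleting the low-coordinate CDS end does not
  cc2 <- classify_consequence(list(chrom = "1", start = 1150, end = 1250), m)
  expect_equal(cc2$class, "cds_truncation")
})

test_that("downstream start rescue finds the first in-frame ATG", {
  fx <- lamc2_like()
  set.seed(804)
  cds <- recmapper:::make_cds(3600L, 900L)
  cc <- classify_consequence(fx$del, fx$model)
  r <- downstream_start_rescue(fx$model, cds, cc)
  expect_equal(r$offset, 900L)
  expect_equal(r$fraction_removed, 0.25)
  expect_false(r$total_loss)
  # ATG immediately at the original start, nothing deleted -> offset 0
  r0 <- downstream_start_rescue(fx$model, cds, 0L)
  expect_equal(r0$offset, 0L)
  expect_equal(r0$fraction_removed, 0)
  # no in-frame ATG left -> total loss
  no_atg <- paste0("ATG", strrep("CCC", 19))
  rn <- downstream_start_rescue(fx$model, no_atg, 3L)
  expect_true(rn$total_loss)
  expect_equal(rn$fraction_removed, 1)
  # refuses non-start_lost classifications
  intr <- classify_consequence(list(chrom = "16", start = fx$del$end + 2600,
                                    end = fx$del$end + 2700), fx$model)
  expect_error(downstream_start_rescue(fx$model, cds, intr), "start_lost")
})

test_that("three-primer band patterns depend only on the allele pair", {
  assay <- genotyping_assay(forward = 100, rev1 = 500, rev2 = 1200,
                            deletion = list(start = 300, end = 1000))
  expect_equal(predict_genotyping_bands(assay, "wt/wt"), "F+Rev1")
  expect_equal(predict_genotyping_bands(assay, "del/del"), "F+Rev2")
  expect_equal(predict_genotyping_bands(assay, "wt/del"),
               c("F+Rev1", "F+Rev2"))
  expect_equal(predict_genotyping_bands(assay, "del/wt"),
               c("F+Rev1", "F+Rev2"))
  expect_equal(predict_genotyping_bands(assay, "del/del"),
               predict_genotyping_bands(assay, "del/del"))
  expect_error(predict_genotyping_bands(assay, "wt/xx"), "unknown genotype")
  # assay invariants
  expect_error(genotyping_assay(400, 500, 1200,
                                list(start = 300, end = 1000)), "upstream")
  expect_error(genotyping_assay(100, 1100, 1200,
                                list(start = 300, end = 1000)), "inside")
  expect_error(genotyping_assay(100, 500, 900,
                                list(start = 300, end = 1000)), "downstream")
  expect_error(predict_genotyping_bands(list(), "wt/wt"), "genotyping_assay")
})

test_that("gene models round-trip through JSON and transcripts through FASTA", {
  fx <- lamc2_like()
  path <- withr::local_tempfile(fileext = ".json")
  write_gene_models(list(fx$model), path)
  back <- read_gene_models(path)
  expect_equal(back[["LAMC2like"]]$exons, fx$model$exons)
  expect_equal(back[["LAMC2like"]]$cds_start, fx$model$cds_start)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">TX1", "ATGAAACCC"), fa)
  tx <- read_transcripts(fa)
  expect_equal(unname(tx["TX1"]), "ATGAAACCC")
})
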