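# Small-variant container: list(fix = data.frame(chrom, pos, id, ref, alt,
# qual, filter), gt = character matrix sites x samples of GT strings).

#' Variant table
#'
#' In-memory container for VCF small variants: site table plus a GT matrix
#' (sites x samples, diploid `"a/b"` strings, `"./."` missing).
#'
#' @param fix data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `qual`, `filter` (missing `id`/`qual` are filled with `"."`).
#' @param gt character matrix, one column per sample.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(fix, gt) {
  if (is.null(fix$id)) fix$id <- "."
  if (is.null(fix$qual)) fix$qual <- "."
  if (is.null(fix$filter)) fix$filter <- "PASS"
  gt <- as.matrix(gt)
  stopifnot(nrow(gt) == nrow(fix), !is.null(colnames(gt)))
  fix <- fix[, c("chrom", "pos", "id", "ref", "alt", "qual", "filter")]
  rownames(fix) <- NULL
  structure(list(fix = fix, gt = gt), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d sample(s) [%s]\n",
              nrow(x$fix), ncol(x$gt),
              paste(utils::head(colnames(x$gt), 4), collapse = ", ")))
  invisible(x)
}

subset_variant_table <- function(vt, keep) {
  variant_table(vt$fix[keep, , drop = FALSE], vt$gt[keep, , drop = FALSE])
}

#' Write a variant table as a plain-text VCF v4.2
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=recmapper",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FILTER=<ID=LowQual,Description="Low quality site">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vt$gt)), collapse = "\t")), con)
  if (nrow(vt$fix)) {
    body <- cbind(vt$fix$chrom, vt$fix$pos, vt$fix$id, vt$fix$ref,
                  vt$fix$alt, vt$fix$qual, vt$fix$filter, ".", "GT", vt$gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Uses vcfR for parsing; only CHROM/POS/ID/REF/ALT/QUAL/FILTER and the GT
#' field are retained.
#'
#' @param path VCF path.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  fix <- data.frame(chrom = fixm[, "CHROM"],
                    pos = as.integer(fixm[, "POS"]),
                    id = fixm[, "ID"], ref = fixm[, "REF"],
                    alt = fixm[, "ALT"], qual = fixm[, "QUAL"],
                    filter = fixm[, "FILTER"], stringsAsFactors = FALSE)
  fix$id[is.na(fix$id)] <- "."
  fix$qual[is.na(fix$qual)] <- "."
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "./."
  variant_table(fix, gt)
}

# allele dosage of the GT string; NA when any allele is missing
gt_dosage <- function(g) {
  a <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
  vapply(a, function(x) {
    if (length(x) != 2L || any(x == ".")) return(NA_integer_)
    sum(as.integer(x) > 0L)
  }, integer(1))
}
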