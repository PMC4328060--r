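# Filter cascade for case small variants. Each filter is a pure subset of
# its input (set-intersection semantics, so filters commute); the reason for
# membership is accumulated in the table's `reasons` vector.

add_reason <- function(vt, label) {
  old <- if (is.null(vt$reasons)) rep("", nrow(vt$fix)) else vt$reasons
  vt$reasons <- ifelse(old == "", label, paste(old, label, sep = ";"))
  vt
}

keep_rows <- function(vt, keep) {
  out <- variant_table(vt$fix[keep, , drop = FALSE],
                       vt$gt[keep, , drop = FALSE])
  if (!is.null(vt$reasons)) out$reasons <- vt$reasons[keep]
  out
}

#' Decompose multi-allelic records into biallelic ones
#'
#' Records with comma-separated ALT alleles are split into one record per
#' alternate allele; genotype allele indices equal to the extracted allele
#' become 1, all others 0 (missing stays missing). This makes per-allele
#' privacy well defined.
#'
#' @param vt a [variant_table()].
#' @return A [variant_table()] with biallelic records only.
#' @export
decompose_multiallelic <- function(vt) {
  alts <- strsplit(vt$fix$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  if (all(n_alt == 1L)) return(vt)
  rows <- rep(seq_len(nrow(vt$fix)), n_alt)
  which_alt <- unlist(lapply(n_alt, seq_len))
  fix <- vt$fix[rows, , drop = FALSE]
  fix$alt <- unlist(alts)
  gt <- vt$gt[rows, , drop = FALSE]
  for (i in seq_along(rows)) {
    a <- which_alt[i]
    gt[i, ] <- vapply(gt[i, ], function(g) {
      parts <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1L]]
      paste(ifelse(parts == ".", ".",
                   ifelse(parts == as.character(a), "1", "0")),
            collapse = "/")
    }, character(1))
  }
  out <- variant_table(fix, gt)
  if (!is.null(vt$reasons)) out$reasons <- vt$reasons[rows]
  out
}

#' Retain variants homozygous for the alternate allele in the case
#'
#' Keeps records where the case genotype is hom-alt and the site passes its
#' FILTER flags (`PASS` or `.`). Under a recessive identical-by-descent
#' model the causative allele must be homozygous in affected individuals.
#'
#' @param vt a [variant_table()].
#' @param case_id sample name of the case.
#' @return The filtered [variant_table()].
#' @export
filter_case_homozygous_alt <- function(vt, case_id) {
  if (!case_id %in% colnames(vt$gt)) {
    stop("sample '", case_id, "' not present in the variant table")
  }
  dos <- gt_dosage(vt$gt[, case_id])
  keep <- !is.na(dos) & dos == 2L & vt$fix$filter %in% c("PASS", ".")
  add_reason(keep_rows(vt, keep), "hom_alt_pass")
}

#' Retain variants private to the case versus a control cohort
#'
#' Drops any record whose alternate allele is observed, heterozygous or
#' homozygous, in any control genome at the same site (chrom, pos, ref,
#' alt). Missing control genotypes do not count as observed; sites absent
#' from the control data are private by definition.
#'
#' @param vt the case [variant_table()].
#' @param controls a [variant_table()] of control genotypes (one column per
#'   control genome), or a list of per-control tables.
#' @return The filtered [variant_table()].
#' @export
filter_private <- function(vt, controls) {
  if (!inherits(controls, "variant_table")) {
    controls <- merge_variant_tables(controls)
  }
  key <- function(fix) paste(fix$chrom, fix$pos, fix$ref, fix$alt, sep = ":")
  m <- match(key(vt$fix), key(controls$fix))
  observed <- vapply(seq_len(nrow(vt$fix)), function(i) {
    if (is.na(m[i])) return(FALSE)
    g <- controls$gt[m[i], ]
    any(!is.na(gt_dosage(g)) & gt_dosage(g) > 0L)
  }, logical(1))
  add_reason(keep_rows(vt, !observed), "private_vs_controls")
}

# column-bind per-control variant tables on the union of sites
merge_variant_tables <- function(tables) {
  key <- function(fix) paste(fix$chrom, fix$pos, fix$ref, fix$alt, sep = ":")
  all_fix <- unique(do.call(rbind, lapply(tables, function(t) t$fix)))
  gt <- matrix("./.", nrow(all_fix),
               sum(vapply(tables, function(t) ncol(t$gt), integer(1))))
  cn <- character(0); col <- 0L
  for (t in tables) {
    idx <- match(key(t$fix), key(all_fix))
    for (j in seq_len(ncol(t$gt))) {
      col <- col + 1L
      gt[idx, col] <- t$gt[, j]
      cn <- c(cn, colnames(t$gt)[j])
    }
  }
  colnames(gt) <- cn
  variant_table(all_fix, gt)
}

#' Retain variants inside mapped regions
#'
#' @param vt a [variant_table()].
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return The filtered [variant_table()].
#' @export
filter_in_regions <- function(vt, regions) {
  keep <- vapply(seq_len(nrow(vt$fix)), function(i) {
    any(regions$chrom == vt$fix$chrom[i] &
        regions$start <= vt$fix$pos[i] &
        regions$end >= vt$fix$pos[i])
  }, logical(1))
  add_reason(keep_rows(vt, keep), "in_mapped_region")
}

#' Prioritized variants inside regions, annotated against gene models
#'
#' Restricts records to the mapped regions and annotates each with the
#' overlapped candidate gene (by transcript span) and whether it falls in
#' coding sequence (exon intersected with the CDS bounds).
#'
#' @param vt a [variant_table()] (typically after
#'   [filter_case_homozygous_alt()] and [filter_private()]).
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param gene_models named list of [gene_model()] objects.
#' @return data.frame of prioritized variants: site columns plus `gene`,
#'   `coding` and `reasons`.
#' @export
restrict_to_regions <- function(vt, regions, gene_models) {
  vt <- filter_in_regions(vt, regions)
  n <- nrow(vt$fix)
  gene <- rep(NA_character_, n)
  coding <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (gmod in gene_models) {
      if (!identical(as.character(gmod$chrom),
                     as.character(vt$fix$chrom[i]))) next
      p <- vt$fix$pos[i]
      if (p < min(gmod$exons$start) || p > max(gmod$exons$end)) next
      gene[i] <- gmod$gene_id
      coding[i] <- any(p >= pmax(gmod$exons$start, gmod$cds_start) &
                       p <= pmin(gmod$exons$end, gmod$cds_end))
      break
    }
  }
  reasons <- vt$reasons
  reasons[coding] <- paste(reasons[coding], "coding", sep = ";")
  data.frame(vt$fix, gt = vt$gt[, 1L], gene = gene, coding = coding,
             reasons = reasons, stringsAsFactors = FALSE)
}
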