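#' Gene model
#'
#' A single-transcript gene model: ordered, non-overlapping exons plus CDS
#' bounds, all 1-based inclusive genomic coordinates. `cds_start` and
#' `cds_end` are the lowest and highest coding genomic positions; on the
#' minus strand translation starts at `cds_end`.
#'
#' @param gene_id,tx_id identifiers.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end`.
#' @param cds_start,cds_end genomic CDS bounds.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, tx_id, chrom, strand, exons,
                       cds_start, cds_end) {
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) stop("exon with end < start")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("exons must be non-overlapping")
  }
  if (cds_end < cds_start) stop("cds_end < cds_start")
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    stop("CDS bounds must lie within exons")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(gene_id = gene_id, tx_id = tx_id, chrom = chrom,
                 strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) chr%s:%d-%d [%s], %d exons, CDS %d-%d\n",
              x$gene_id, x$tx_id, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons),
              x$cds_start, x$cds_end))
  invisible(x)
}

#' Read / write gene models as JSON
#'
#' @param models named list of [gene_model()] objects.
#' @param path JSON file path.
#' @return `path` invisibly (writer) or a named list of models (reader).
#' @export
write_gene_models <- function(models, path) {
  jsonlite::write_json(
    lapply(unname(models), function(m) {
      list(gene_id = m$gene_id, tx_id = m$tx_id, chrom = m$chrom,
           strand = m$strand, exons = m$exons,
           cds_start = m$cds_start, cds_end = m$cds_end)
    }),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  models <- lapply(raw, function(m) {
    gene_model(m$gene_id, m$tx_id, m$chrom, m$strand,
               data.frame(start = unlist(m$exons$start),
                          end = unlist(m$exons$end)),
               m$cds_start, m$cds_end)
  })
  names(models) <- vapply(models, function(m) m$gene_id, character(1))
  models
}

#' Length of a genomic deletion in HGVS g. coordinates
#'
#' HGVS `g.start_enddel` intervals are 1-based inclusive, so the deleted
#' length is `end - start + 1`.
#'
#' @param start,end 1-based inclusive genomic coordinates (vectorised).
#' @return Integer length(s) in bp.
#' @examples
#' deletion_length(65704617, 65707049)  # 2433
#' @export
deletion_length <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  as.integer(end - start + 1)
}

# genomic positions of the first `n` coding bases, in translation order
coding_start_positions <- function(model, n = 3L) {
  ex <- model$exons
  pos <- integer(0)
  if (model$strand == "+") {
    for (i in seq_len(nrow(ex))) {
      lo <- max(ex$start[i], model$cds_start)
      hi <- min(ex$end[i], model$cds_end)
      if (lo <= hi) pos <- c(pos, seq(lo, hi))
      if (length(pos) >= n) break
    }
  } else {
    for (i in rev(seq_len(nrow(ex)))) {
      hi <- min(ex$end[i], model$cds_end)
      lo <- max(ex$start[i], model$cds_start)
      if (lo <= hi) pos <- c(pos, seq(hi, lo))
      if (length(pos) >= n) break
    }
  }
  utils::head(pos, n)
}

overlap_len <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1) + 1)
}

#' Classify the functional consequence of a deletion on a gene model
#'
#' Strand-aware classification: `start_lost` when the deletion intersects
#' any of the three bases of the translation start codon (any disruption of
#' the codon is disruptive); otherwise `exon_loss` when at least one whole
#' exon is contained in the deletion; otherwise `cds_truncation` when coding
#' bases are removed; otherwise `intronic` for any other overlap with the
#' transcript span; `upstream` when the deletion lies within
#' `upstream_window` bp 5' of the transcript; `intergenic` otherwise (also
#' returned with a warning on a chromosome mismatch).
#'
#' @param deletion list or one-row data.frame with `chrom`, `start`, `end`.
#' @param model a [gene_model()].
#' @param upstream_window bp window defining `upstream` (default 2 kb).
#' @return A list of class `consequence_call`: `class`, `coding_bases_deleted`,
#'   `exons_lost`, `start_codon_lost`, `gene`, `tx`.
#' @export
classify_consequence <- function(deletion, model, upstream_window = 2000) {
  if (deletion$end < deletion$start) stop("deletion end < start")
  mk <- function(class, coding = 0L, exons_lost = 0L, start_lost = FALSE) {
    structure(list(class = class, coding_bases_deleted = as.integer(coding),
                   exons_lost = as.integer(exons_lost),
                   start_codon_lost = start_lost,
                   gene = model$gene_id, tx = model$tx_id,
                   deletion = deletion),
              class = "consequence_call")
  }
  if (!identical(as.character(deletion$chrom), as.character(model$chrom))) {
    warning("deletion and gene model are on different chromosomes")
    return(mk("intergenic"))
  }
  ex <- model$exons
  tx_start <- min(ex$start); tx_end <- max(ex$end)
  coding <- sum(overlap_len(deletion$start, deletion$end,
                            pmax(ex$start, model$cds_start),
                            pmin(ex$end, model$cds_end)))
  whole <- sum(ex$start >= deletion$start & ex$end <= deletion$end)
  sc <- coding_start_positions(model, 3L)
  start_lost <- any(sc >= deletion$start & sc <= deletion$end)
  if (start_lost) return(mk("start_lost", coding, whole, TRUE))
  if (whole >= 1L) return(mk("exon_loss", coding, whole))
  if (coding > 0L) return(mk("cds_truncation", coding))
  if (deletion$end >= tx_start && deletion$start <= tx_end) {
    return(mk("intronic"))
  }
  upstream <- if (model$strand == "+") {
    deletion$end < tx_start && deletion$end >= tx_start - upstream_window
  } else {
    deletion$start > tx_end && deletion$start <= tx_end + upstream_window
  }
  mk(if (upstream) "upstream" else "intergenic")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("consequence_call: %s in %s (%s); %d coding bases deleted, %d whole exon(s) lost\n",
              x$class, x$gene, x$tx, x$coding_bases_deleted, x$exons_lost))
  invisible(x)
}

#' Downstream start-codon rescue after start loss
#'
#' When a deletion removes the translation start, a downstream in-frame ATG
#' may initiate a truncated protein. Scans the coding sequence 5' to 3' for
#' the first in-frame ATG past the deleted 5' coding bases and reports its
#' offset from the lost start plus the fraction of the wildtype CDS removed
#' up to that point. The deleted coding bases must be a 5' prefix of the
#' CDS (i.e. the call must be `start_lost`).
#'
#' @param model a [gene_model()] (identifiers are echoed in the result).
#' @param cds_seq the wildtype coding sequence, 5' to 3' (character or
#'   `Biostrings::DNAString`).
#' @param consequence a `start_lost` [classify_consequence()] call, or an
#'   integer count of deleted 5' coding bases.
#' @return list: `offset` (bp from the lost start to the rescue ATG),
#'   `fraction_removed` (of the wildtype CDS), `total_loss` (TRUE when no
#'   in-frame ATG remains; then `offset` is `NA` and `fraction_removed` 1).
#' @export
downstream_start_rescue <- function(model, cds_seq, consequence) {
  n_del <- if (inherits(consequence, "consequence_call")) {
    if (consequence$class != "start_lost") {
      stop("rescue analysis applies to start_lost calls only")
    }
    consequence$coding_bases_deleted
  } else {
    as.integer(consequence)
  }
  seq <- as.character(cds_seq)
  len <- nchar(seq)
  starts <- seq.int(1L, len - 2L, by = 3L)        # in-frame codon starts
  starts <- starts[starts > n_del]
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons == "ATG")
  if (length(hit) == 0L) {
    return(list(offset = NA_integer_, fraction_removed = 1,
                total_loss = TRUE, gene = model$gene_id, tx = model$tx_id))
  }
  off <- starts[hit[1L]] - 1L
  list(offset = off, fraction_removed = off / len, total_loss = FALSE,
       gene = model$gene_id, tx = model$tx_id)
}

#' Three-primer PCR genotyping assay
#'
#' A common forward primer upstream of the deletion, a reverse primer inside
#' the deleted region (Rev1) and a reverse primer immediately downstream of
#' the deletion (Rev2). The wildtype allele amplifies F+Rev1 (the F+Rev2
#' product is too long by design); the deleted allele amplifies F+Rev2.
#'
#' @param forward,rev1,rev2 primer positions (bp).
#' @param deletion list with `start`, `end`.
#' @return An object of class `genotyping_assay`.
#' @export
genotyping_assay <- function(forward, rev1, rev2, deletion) {
  if (!(forward < deletion$start)) {
    stop("forward primer must lie upstream of the deletion")
  }
  if (!(rev1 >= deletion$start && rev1 <= deletion$end)) {
    stop("Rev1 must lie inside the deletion")
  }
  if (!(rev2 > deletion$end)) {
    stop("Rev2 must lie downstream of the deletion")
  }
  structure(list(forward = forward, rev1 = rev1, rev2 = rev2,
                 deletion = deletion), class = "genotyping_assay")
}

#' Predict diagnostic PCR band patterns
#'
#' Each wildtype allele yields the F+Rev1 product, each deleted allele the
#' F+Rev2 product; a diploid genotype shows the union over its two alleles:
#' wt/wt one band (F+Rev1), del/del one band (F+Rev2), wt/del both bands.
#'
#' @param assay a [genotyping_assay()].
#' @param genotype `"wt/wt"`, `"wt/del"` (or `"del/wt"`), `"del/del"`.
#' @return Character vector of product labels.
#' @export
predict_genotyping_bands <- function(assay, genotype) {
  if (!inherits(assay, "genotyping_assay")) {
    stop("'assay' must be a genotyping_assay")
  }
  alleles <- strsplit(genotype, "/", fixed = TRUE)[[1L]]
  if (length(alleles) != 2L || !all(alleles %in% c("wt", "del"))) {
    stop("unknown genotype: ", genotype)
  }
  band <- function(a) if (a == "wt") "F+Rev1" else "F+Rev2"
  sort(unique(vapply(alleles, band, character(1))))
}

#' Read transcript sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
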