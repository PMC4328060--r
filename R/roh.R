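#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Parameters for run-of-homozygosity detection
#'
#' Defaults follow common SNP-array homozygosity-mapping practice for dense
#' chips: runs of at least 50 markers and 1 Mb, tolerating one heterozygous
#' and two missing calls per run, with no inter-marker gap above 1 Mb.
#'
#' @param min_markers minimum markers per run.
#' @param min_length_bp minimum run length in bp.
#' @param max_het_per_run maximum heterozygous calls tolerated inside a run.
#' @param max_missing_per_run maximum missing calls tolerated inside a run.
#' @param max_gap_bp maximum distance between consecutive markers in a run.
#' @return A named list of class `roh_params`.
#' @export
roh_params <- function(min_markers = 50L, min_length_bp = 1e6,
                       max_het_per_run = 1L, max_missing_per_run = 2L,
                       max_gap_bp = 1e6) {
  structure(list(min_markers = as.integer(min_markers),
                 min_length_bp = as.numeric(min_length_bp),
                 max_het_per_run = as.integer(max_het_per_run),
                 max_missing_per_run = as.integer(max_missing_per_run),
                 max_gap_bp = as.numeric(max_gap_bp)),
            class = "roh_params")
}

empty_roh <- function() {
  data.frame(individual = character(), chrom = character(),
             start = numeric(), end = numeric(), n_markers = integer(),
             n_het = integer(), n_missing = integer(),
             idx_first = integer(), idx_last = integer(),
             stringsAsFactors = FALSE)
}

#' Detect runs of homozygosity for one individual
#'
#' Exact run-based detection (not a sliding-window heuristic): runs are
#' maximal stretches of consecutive markers that begin and end with a
#' homozygous call, contain at most `max_het_per_run` heterozygous and
#' `max_missing_per_run` missing calls, and have no inter-marker gap above
#' `max_gap_bp`. Runs are selected greedily left to right (leftmost start,
#' longest extension), so reported segments never overlap; segment bounds
#' are the first and last marker positions of the run. Runs below
#' `min_markers` or `min_length_bp` are discarded.
#'
#' @param gm a [genotype_matrix()].
#' @param individual individual id (rowname of the call matrix).
#' @param params a [roh_params()].
#' @return data.frame of segments: `individual`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_markers`, `n_het`, `n_missing`, and global
#'   marker indices `idx_first`, `idx_last`.
#' @export
detect_roh <- function(gm, individual, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!individual %in% rownames(gm$calls)) {
    stop("unknown individual: ", individual)
  }
  out <- list()
  for (ch in unique(gm$map$chrom)) {
    sel <- which(gm$map$chrom == ch)
    v <- gm$calls[individual, sel]
    p <- gm$map$pos[sel]
    m <- length(sel)
    is_hom <- !is.na(v) & (v == 0L | v == 2L)
    is_het <- !is.na(v) & v == 1L
    is_mis <- is.na(v)
    chet <- cumsum(is_het); cmis <- cumsum(is_mis)
    i <- 1L
    while (i <= m) {
      if (!is_hom[i]) { i <- i + 1L; next }
      het <- 0L; mis <- 0L; best_j <- i; j <- i
      while (j < m) {
        j <- j + 1L
        if (p[j] - p[j - 1L] > params$max_gap_bp) break
        if (is_het[j]) {
          het <- het + 1L
          if (het > params$max_het_per_run) break
        } else if (is_mis[j]) {
          mis <- mis + 1L
          if (mis > params$max_missing_per_run) break
        } else {
          best_j <- j
        }
      }
      n_mark <- best_j - i + 1L
      len <- p[best_j] - p[i] + 1
      if (n_mark >= params$min_markers && len >= params$min_length_bp) {
        out[[length(out) + 1L]] <- data.frame(
          individual = individual, chrom = ch, start = p[i], end = p[best_j],
          n_markers = n_mark,
          n_het = chet[best_j] - chet[i],
          n_missing = cmis[best_j] - cmis[i],
          idx_first = sel[i], idx_last = sel[best_j],
          stringsAsFactors = FALSE)
        i <- best_j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out)) do.call(rbind, out) else empty_roh()
}

#' Homozygous-allele signature of a segment
#'
#' Calls of the segment's individual over the run's markers, useful for
#' shared-allele comparison and audit.
#'
#' @param gm a [genotype_matrix()].
#' @param segment one row of a [detect_roh()] result.
#' @return Integer vector of calls (0/1/2/NA) across the run.
#' @export
roh_signature <- function(gm, segment) {
  gm$calls[segment$individual, segment$idx_first:segment$idx_last]
}

seg_ranges <- function(seg) IRanges::IRanges(start = seg$start, end = seg$end)

#' Exclude homozygous regions already present in the parents
#'
#' Subtracts from each case segment every interval where either parent also
#' has a run of homozygosity, retaining the novel pieces of at least
#' `min_novel_length_bp`. With `mode = "drop"` a case segment overlapping
#' any parental segment is instead rejected wholesale.
#'
#' @param case_segments segments of the affected individual ([detect_roh()]).
#' @param parent_segments segments of the parents (one data.frame; rows from
#'   both parents may be concatenated).
#' @param min_novel_length_bp minimum retained piece length.
#' @param mode `"subtract"` (interval subtraction, default) or `"drop"`.
#' @return data.frame of novel segments (`individual`, `chrom`, `start`,
#'   `end`, `source_start`, `source_end`).
#' @export
exclude_parental <- function(case_segments, parent_segments,
                             min_novel_length_bp = 1e6,
                             mode = c("subtract", "drop")) {
  mode <- match.arg(mode)
  if (nrow(case_segments) == 0L) return(empty_roh()[, 1:4])
  out <- list()
  for (ch in unique(case_segments$chrom)) {
    cs <- case_segments[case_segments$chrom == ch, , drop = FALSE]
    ps <- parent_segments[parent_segments$chrom == ch, , drop = FALSE]
    pr <- IRanges::reduce(seg_ranges(ps))
    for (k in seq_len(nrow(cs))) {
      r <- IRanges::IRanges(cs$start[k], cs$end[k])
      if (mode == "drop") {
        keep <- if (length(pr) == 0L ||
                    !any(IRanges::overlapsAny(r, pr))) r else
          IRanges::IRanges()
      } else {
        keep <- IRanges::setdiff(r, pr)
      }
      keep <- keep[IRanges::width(keep) >= min_novel_length_bp]
      if (length(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          individual = cs$individual[k], chrom = ch,
          start = IRanges::start(keep), end = IRanges::end(keep),
          source_start = cs$start[k], source_end = cs$end[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(individual = character(), chrom = character(),
               start = numeric(), end = numeric(),
               source_start = numeric(), source_end = numeric(),
               stringsAsFactors = FALSE)
}

#' Consensus homozygous regions shared across cases
#'
#' Intersects run-of-homozygosity segments across all cases and retains the
#' intersections in which every case is homozygous for the same allele at
#' every genotyped marker inside the intersection (missing calls are
#' skipped; any heterozygous or discordant homozygous call rejects the
#' interval).
#'
#' @param segments_by_case named list (case id -> [detect_roh()] output).
#' @param gm the [genotype_matrix()] the segments were called from.
#' @return data.frame of consensus regions: `chrom`, `start`, `end`,
#'   `n_cases`.
#' @export
shared_homozygosity <- function(segments_by_case, gm) {
  stopifnot(length(segments_by_case) >= 1L)
  cases <- names(segments_by_case)
  if (length(segments_by_case) == 1L) {
    seg <- segments_by_case[[1L]]
    if (nrow(seg) == 0L) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), n_cases = integer(),
                        stringsAsFactors = FALSE))
    }
    return(data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                      n_cases = 1L, stringsAsFactors = FALSE))
  }
  chroms <- unique(unlist(lapply(segments_by_case, function(s) s$chrom)))
  out <- list()
  for (ch in chroms) {
    inter <- NULL
    for (seg in segments_by_case) {
      r <- IRanges::reduce(seg_ranges(seg[seg$chrom == ch, , drop = FALSE]))
      inter <- if (is.null(inter)) r else IRanges::intersect(inter, r)
    }
    if (length(inter) == 0L) next
    sel <- which(gm$map$chrom == ch)
    pos <- gm$map$pos[sel]
    for (k in seq_along(inter)) {
      a <- IRanges::start(inter)[k]; b <- IRanges::end(inter)[k]
      mk <- sel[pos >= a & pos <= b]
      calls <- gm$calls[cases, mk, drop = FALSE]
      ok <- TRUE
      for (j in seq_len(ncol(calls))) {
        cj <- calls[, j]
        cj <- cj[!is.na(cj)]
        if (length(cj) == 0L) next
        if (any(cj == 1L) || length(unique(cj)) > 1L) { ok <- FALSE; break }
      }
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = a, end = b, n_cases = length(cases),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_cases = integer(), stringsAsFactors = FALSE)
}

#' Fraction of the genome covered by homozygous segments
#'
#' @param segments [detect_roh()] output for one individual; overlapping
#'   segments violate the detection contract and raise an error.
#' @param genome_length_bp total genome length.
#' @return Fraction in `[0, 1]`.
#' @export
genome_fraction_homozygous <- function(segments, genome_length_bp) {
  if (genome_length_bp <= 0) stop("genome_length_bp must be positive")
  if (nrow(segments) == 0L) return(0)
  if ("individual" %in% names(segments) &&
      length(unique(segments$individual)) > 1L) {
    stop("segments from multiple individuals; compute the fraction per individual")
  }
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
      stop("overlapping segments on chromosome ", ch)
    }
  }
  sum(segments$end - segments$start + 1) / genome_length_bp
}

#' Intersect mapped regions with candidate genes
#'
#' A gene is reported whenever it overlaps any region by at least 1 bp
#' (both inputs 1-based inclusive; convert BED at I/O with [read_bed()]).
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`.
#' @return data.frame of (gene, region) pairs.
#' @export
intersect_candidates <- function(regions, genes) {
  out <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    r <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0L || nrow(g) == 0L) next
    hits <- IRanges::findOverlaps(seg_ranges(g), seg_ranges(r))
    if (length(hits)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = g$gene[queryHits(hits)], chrom = ch,
        gene_start = g$start[queryHits(hits)],
        gene_end = g$end[queryHits(hits)],
        region_start = r$start[subjectHits(hits)],
        region_end = r$end[subjectHits(hits)],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), chrom = character(),
               gene_start = numeric(), gene_end = numeric(),
               region_start = numeric(), region_end = numeric(),
               stringsAsFactors = FALSE)
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open on disk; in memory all coordinates in this
#' package are 1-based inclusive, so `start` is shifted by one at the
#' boundary.
#'
#' @param path BED file path.
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`
#'   (1-based inclusive).
#' @return data.frame (reader) or `path` invisibly (writer).
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df$start <- df$start + 1L
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  if ("name" %in% names(df)) out$name <- df$name
  if ("gene" %in% names(df)) out$name <- df$gene
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
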