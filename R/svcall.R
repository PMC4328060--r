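# Read-pair mapping records (SAM-subset semantics): fragment, chrom,
# m1_start, m1_end, m2_start, m2_end (1-based inclusive, mate1 leftmost),
# orientation (FR/RF/FF/RR), mapq. The apparent span of a pair is the outer
# distance m2_end - m1_start + 1, which for a concordant forward-reverse
# pair estimates the fragment (insert) length.

#' Write / read read-pair mapping records as TSV
#'
#' @param pairs data.frame of read-pair records.
#' @param path file path.
#' @return `path` invisibly (writer) or the data.frame (reader).
#' @export
write_read_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_pairs
#' @export
read_read_pairs <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read pairs from a name-sorted or coordinate-sorted SAM/BAM file
#'
#' Extracts properly paired primary alignments and reduces them to the
#' flat mapping-record table the caller consumes. Requires Rsamtools.
#'
#' @param path SAM or BAM path.
#' @param sample sample id stamped on the records.
#' @return data.frame of read-pair records.
#' @export
read_pairs_from_sam <- function(path, sample = basename(path)) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM/BAM input")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "mapq", "strand"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  keep <- !is.na(b$pos) & !bitwAnd(b$flag, 256L) & !bitwAnd(b$flag, 2048L)
  d <- data.frame(qname = b$qname, chrom = as.character(b$rname),
                  start = b$pos, end = b$pos + b$qwidth - 1L,
                  strand = as.character(b$strand), mapq = b$mapq,
                  stringsAsFactors = FALSE)[keep, , drop = FALSE]
  sp <- split(d, d$qname)
  rows <- lapply(sp, function(x) {
    if (nrow(x) != 2L || x$chrom[1L] != x$chrom[2L]) return(NULL)
    x <- x[order(x$start), , drop = FALSE]
    ori <- paste0(ifelse(x$strand == "+", "F", "R"), collapse = "")
    data.frame(fragment = x$qname[1L], chrom = x$chrom[1L],
               m1_start = x$start[1L], m1_end = x$end[1L],
               m2_start = x$start[2L], m2_end = x$end[2L],
               orientation = ori, mapq = min(x$mapq),
               sample = sample, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pair_span <- function(pairs) pairs$m2_end - pairs$m1_start + 1

#' Fit a robust insert-size model from forward-reverse pairs
#'
#' Location is the median apparent span of FR pairs and scale the
#' MAD-based robust standard deviation (1.4826 x median absolute
#' deviation), so a contaminating discordant fraction up to ~10% leaves the
#' model essentially unchanged. Pairs whose span exceeds
#' `location + k * scale` are later classed discordant.
#'
#' @param pairs data.frame of read-pair records (>= 50 FR pairs required).
#' @param k discordance multiplier (robust SDs above location).
#' @return An object of class `insert_size_model`: `location`, `scale`, `k`,
#'   `n`.
#' @export
fit_insert_model <- function(pairs, k = 3) {
  if (k <= 0) stop("k must be positive")
  fr <- pairs[pairs$orientation == "FR", , drop = FALSE]
  if (nrow(fr) < 50L) {
    stop("need at least 50 FR pairs to fit the insert-size model, got ",
         nrow(fr))
  }
  span <- pair_span(fr)
  loc <- median(span)
  sc <- mad(span)
  if (sc <= 0) stop("degenerate insert-size scale (MAD = 0)")
  structure(list(location = loc, scale = sc, k = k, n = nrow(fr)),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf("insert_size_model: location %.1f bp, scale %.1f bp (k = %g, n = %d)\n",
              x$location, x$scale, x$k, x$n))
  invisible(x)
}

#' Select deletion-discordant pairs
#'
#' FR pairs whose apparent span strictly exceeds `location + k * scale` and
#' whose mapping quality passes the threshold; other orientations carry no
#' deletion signal and are excluded.
#'
#' @param pairs data.frame of read-pair records.
#' @param model an [fit_insert_model()] fit.
#' @param min_mapq minimum mapping quality.
#' @return Subset of `pairs`.
#' @export
find_discordant <- function(pairs, model, min_mapq = 20L) {
  keep <- pairs$orientation == "FR" &
    pair_span(pairs) > model$location + model$k * model$scale &
    pairs$mapq >= min_mapq
  pairs[keep, , drop = FALSE]
}

# implied deleted interval of a discordant pair: the unread inner gap
implied_interval <- function(pairs) {
  data.frame(start = pairs$m1_end + 1, end = pairs$m2_start - 1)
}

#' Cluster discordant pairs into deletion calls
#'
#' Each discordant pair implies a candidate deleted interval (the inner gap
#' between its mates). Single-linkage clustering joins pairs with
#' overlapping implied intervals; a cluster whose implied intervals have an
#' empty common intersection is split greedily along the start-sorted pairs
#' into runs with a non-empty running intersection. Per cluster the
#' breakpoint interval is the intersection of implied intervals (it contains
#' the true breakpoints when all member pairs stem from the same event) and
#' the estimated size is the mean apparent span minus the model location.
#' Clusters below `min_support` pairs or `min_size` bp estimated size are
#' discarded.
#'
#' @param discordant discordant pairs from one chromosome
#'   ([find_discordant()]).
#' @param model an [fit_insert_model()] fit.
#' @param min_support minimum supporting pair count.
#' @param min_size minimum estimated deletion size in bp (a Delly-like
#'   minimum SV length guarding against chance spans in the insert tail).
#' @return data.frame of ungenotyped calls: `chrom`, `start`, `end`,
#'   `support`, `size_est`, `span_mean`, plus a `fragments` list-column of
#'   supporting fragment ids.
#' @export
cluster_discordant <- function(discordant, model, min_support = 3L,
                               min_size = 300) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), support = integer(),
                      size_est = numeric(), span_mean = numeric(),
                      stringsAsFactors = FALSE)
  empty$fragments <- list()
  if (nrow(discordant) == 0L) return(empty)
  if (length(unique(discordant$chrom)) > 1L) {
    stop("cluster_discordant expects pairs from a single chromosome")
  }
  ii <- implied_interval(discordant)
  ok <- ii$end >= ii$start
  discordant <- discordant[ok, , drop = FALSE]
  ii <- ii[ok, , drop = FALSE]
  if (nrow(ii) == 0L) return(empty)
  r <- IRanges::IRanges(ii$start, ii$end)
  comp <- IRanges::reduce(r, min.gapwidth = 0L)    # overlap components
  grp <- S4Vectors::subjectHits(IRanges::findOverlaps(r, comp))
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(ii$start[idx], ii$end[idx])]
    # greedy split on empty running intersection
    runs <- list(); cur <- idx[1L]
    lo <- ii$start[cur]; hi <- ii$end[cur]
    for (i in idx[-1L]) {
      nlo <- max(lo, ii$start[i]); nhi <- min(hi, ii$end[i])
      if (nlo > nhi) {
        runs[[length(runs) + 1L]] <- cur
        cur <- i; lo <- ii$start[i]; hi <- ii$end[i]
      } else {
        cur <- c(cur, i); lo <- nlo; hi <- nhi
      }
    }
    runs[[length(runs) + 1L]] <- cur
    for (members in runs) {
      # span-consistency trim: pairs from one deletion share span = L + size
      # with L ~ insert distribution, so members deviating more than
      # k robust SDs from the cluster median span are tail contaminants
      spans <- pair_span(discordant[members, , drop = FALSE])
      members <- members[abs(spans - median(spans)) <=
                           model$k * model$scale]
      if (length(members) < min_support) next
      bstart <- max(ii$start[members])
      bend <- min(ii$end[members])
      if (bstart > bend) next
      spans <- pair_span(discordant[members, , drop = FALSE])
      size <- mean(spans) - model$location
      if (size < min_size) next
      row <- data.frame(chrom = discordant$chrom[members[1L]],
                        start = bstart,
                        end = bend,
                        support = length(members),
                        size_est = size, span_mean = mean(spans),
                        stringsAsFactors = FALSE)
      row$fragments <- list(discordant$fragment[members])
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Genotyping thresholds for deletion calls
#'
#' @param r_hom minimum discordant-support ratio for hom_del.
#' @param r_het minimum ratio for het_del.
#' @param d_hom maximum inside/flank depth ratio for hom_del.
#' @param d_het_lo,d_het_hi depth-ratio band for het_del.
#' @param flank_bp flank width used for the depth comparison.
#' @param min_mapq mapping-quality threshold for counted pairs.
#' @return Named list of class `sv_genotype_params`.
#' @export
sv_genotype_params <- function(r_hom = 0.8, r_het = 0.3, d_hom = 0.2,
                               d_het_lo = 0.3, d_het_hi = 0.7,
                               flank_bp = 1000, min_mapq = 20L) {
  structure(as.list(environment()), class = "sv_genotype_params")
}

# mean per-bp read coverage of [a, b] from both mates of the given pairs
interval_coverage <- function(pairs, a, b) {
  if (b < a) return(0)
  covered <- overlap_len(pairs$m1_start, pairs$m1_end, a, b) +
             overlap_len(pairs$m2_start, pairs$m2_end, a, b)
  sum(covered) / (b - a + 1)
}

#' Genotype a deletion call
#'
#' Combines the discordant-pair support ratio with a read-depth
#' corroboration. Support ratio r = D / (D + C) where D is the number of
#' discordant pairs whose implied interval contains the call interval and C
#' the mean, over the two breakpoints, of concordant pairs whose unread
#' inner gap crosses that breakpoint (the inner gap matches the detection
#' window of a discordant junction, and a discordant pair spans the single
#' junction while each concordant pair crosses one breakpoint). Depth ratio
#' d compares coverage inside the call with the mean of the two flanks.
#' hom_del: r >= r_hom and d <= d_hom; het_del: r in [r_het, r_hom) and d in
#' [d_het_lo, d_het_hi]; anything else is `ambiguous` with reasons; zero
#' informative pairs flag the call `ambiguous` as well.
#'
#' @param call one row of [cluster_discordant()] output.
#' @param pairs all read pairs of the same genome and chromosome.
#' @param model an [fit_insert_model()] fit.
#' @param params an [sv_genotype_params()].
#' @return The call row with `genotype`, `support_ratio`, `depth_ratio` and
#'   `gt_reason` columns added.
#' @export
genotype_deletion <- function(call, pairs, model,
                              params = sv_genotype_params()) {
  pairs <- pairs[pairs$orientation == "FR" &
                 pairs$mapq >= params$min_mapq, , drop = FALSE]
  disc <- find_discordant(pairs, model, min_mapq = params$min_mapq)
  conc <- pairs[!pairs$fragment %in% disc$fragment, , drop = FALSE]
  di <- implied_interval(disc)
  D <- sum(di$start <= call$start & di$end >= call$end)
  ci <- implied_interval(conc)
  crosses <- function(b) sum(ci$start <= b & ci$end >= b)
  C <- (crosses(call$start) + crosses(call$end)) / 2
  cov_in <- interval_coverage(pairs, call$start, call$end)
  fl <- params$flank_bp
  cov_fl <- (interval_coverage(pairs, call$start - fl, call$start - 1) +
             interval_coverage(pairs, call$end + 1, call$end + fl)) / 2
  r <- if (D + C > 0) D / (D + C) else NA_real_
  d <- if (cov_fl > 0) cov_in / cov_fl else NA_real_
  gt <- "ambiguous"; reason <- character(0)
  if (is.na(r)) {
    reason <- "no pairs crossing the breakpoints"
  } else if (is.na(d)) {
    reason <- "no flanking coverage for the depth ratio"
  } else if (r >= params$r_hom && d <= params$d_hom) {
    gt <- "hom_del"
    reason <- sprintf("r=%.2f>=%.2f, d=%.2f<=%.2f", r, params$r_hom,
                      d, params$d_hom)
  } else if (r >= params$r_het && r < params$r_hom &&
             d >= params$d_het_lo && d <= params$d_het_hi) {
    gt <- "het_del"
    reason <- sprintf("r=%.2f in [%.2f,%.2f), d=%.2f in [%.2f,%.2f]",
                      r, params$r_het, params$r_hom, d,
                      params$d_het_lo, params$d_het_hi)
  } else {
    reason <- sprintf("r=%.2f, d=%.2f outside genotype bands", r, d)
  }
  call$genotype <- gt
  call$support_ratio <- r
  call$depth_ratio <- d
  call$gt_reason <- paste(reason, collapse = "; ")
  call
}

#' Call and genotype deletions from one genome's read pairs
#'
#' Convenience wrapper: fits the insert model, selects discordant pairs,
#' clusters them per chromosome and genotypes every call.
#'
#' @param pairs read-pair records of one genome.
#' @param k discordance multiplier.
#' @param min_support,min_size cluster thresholds (see
#'   [cluster_discordant()]).
#' @param params an [sv_genotype_params()].
#' @return data.frame of genotyped deletion calls (possibly 0 rows).
#' @export
call_deletions <- function(pairs, k = 3, min_support = 3L, min_size = 300,
                           params = sv_genotype_params()) {
  model <- fit_insert_model(pairs, k = k)
  disc <- find_discordant(pairs, model, min_mapq = params$min_mapq)
  out <- list()
  for (ch in unique(disc$chrom)) {
    calls <- cluster_discordant(disc[disc$chrom == ch, , drop = FALSE],
                                model, min_support, min_size)
    for (i in seq_len(nrow(calls))) {
      out[[length(out) + 1L]] <- genotype_deletion(
        calls[i, , drop = FALSE],
        pairs[pairs$chrom == ch, , drop = FALSE], model, params)
    }
  }
  if (length(out) == 0L) {
    res <- cluster_discordant(pairs[0, , drop = FALSE],
                              structure(list(location = 0, scale = 1, k = k),
                                        class = "insert_size_model"))
    res$genotype <- character(0); res$support_ratio <- numeric(0)
    res$depth_ratio <- numeric(0); res$gt_reason <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- overlap_len(a_start, a_end, b_start, b_end)
  pmin(ov / (a_end - a_start + 1), ov / (b_end - b_start + 1))
}

#' Retain deletions private to the case genome
#'
#' Drops any case call matched by a control call with reciprocal overlap of
#' at least `min_reciprocal` in any control genome.
#'
#' @param case_calls genotyped calls of the case genome.
#' @param control_call_sets list of call data.frames, one per control.
#' @param min_reciprocal reciprocal-overlap threshold.
#' @return Subset of `case_calls`.
#' @export
private_deletions <- function(case_calls, control_call_sets,
                              min_reciprocal = 0.5) {
  if (nrow(case_calls) == 0L || length(control_call_sets) == 0L) {
    return(case_calls)
  }
  matched <- rep(FALSE, nrow(case_calls))
  for (ctrl in control_call_sets) {
    if (is.null(ctrl) || nrow(ctrl) == 0L) next
    for (i in seq_len(nrow(case_calls))) {
      same <- ctrl$chrom == case_calls$chrom[i]
      if (!any(same)) next
      ro <- reciprocal_overlap(case_calls$start[i], case_calls$end[i],
                               ctrl$start[same], ctrl$end[same])
      if (any(ro >= min_reciprocal)) matched[i] <- TRUE
    }
  }
  case_calls[!matched, , drop = FALSE]
}

#' Supporting pairs of a call, for manual audit
#'
#' Returns the mapping records of the pairs that support a deletion call,
#' the analogue of inspecting the alignment around a candidate SV in a
#' genome browser.
#'
#' @param call one call row (from [cluster_discordant()] /
#'   [call_deletions()]).
#' @param pairs the read pairs the call was made from.
#' @return data.frame of supporting read-pair records.
#' @export
supporting_pairs <- function(call, pairs) {
  pairs[pairs$fragment %in% call$fragments[[1L]], , drop = FALSE]
}

#' Write deletion calls as VCF symbolic-allele records
#'
#' Emits SVTYPE=DEL records with symbolic `<DEL>` alternate alleles, END and
#' CIPOS/CIEND reflecting the breakpoint interval, and the diploid genotype.
#' POS is the base before the reported deletion start (anchor-base
#' convention).
#'
#' @param calls genotyped deletion calls.
#' @param path output VCF path.
#' @param sample sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_deletion_vcf <- function(calls, path, sample = "case") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=recmapper",
    '##ALT=<ID=DEL,Description="Deletion">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End of the interval">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Estimated length">',
    '##INFO=<ID=PE,Number=1,Type=Integer,Description="Supporting pairs">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t")), con)
  gt_code <- c(hom_del = "1/1", het_del = "0/1", ref = "0/0",
               ambiguous = "./.")
  for (i in seq_len(nrow(calls))) {
    info <- sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d;PE=%d",
                    as.integer(calls$end[i]),
                    as.integer(round(calls$size_est[i])),
                    calls$support[i])
    writeLines(paste(calls$chrom[i], as.integer(calls$start[i]) - 1L,
                     sprintf("DEL%04d", i), "N", "<DEL>", ".", "PASS",
                     info, "GT", gt_code[[calls$genotype[i]]],
                     sep = "\t"), con)
  }
  invisible(path)
}
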