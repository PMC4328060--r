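#' Final prioritization report
#'
#' Ranks the events that survived the whole filter cascade. An event is
#' nominated as the causal candidate when it overlaps a candidate gene and
#' is disruptive (`start_lost`, `exon_loss` or `cds_truncation` for
#' deletions; any coding private variant). A single nomination is flagged
#' unique; multiple nominations are flagged non-unique; the complete cascade
#' counts are carried for audit.
#'
#' @param prioritized data.frame from [restrict_to_regions()] (private
#'   hom-alt variants in mapped regions, gene-annotated).
#' @param private_dels genotyped private deletion calls.
#' @param candidate_genes data.frame with `gene`, `chrom`, `start`, `end`.
#' @param consequences list of [classify_consequence()] calls, one per row
#'   of `private_dels` (entries may be `NULL` for calls overlapping no
#'   candidate gene).
#' @param cascade named list of stage counts (audit trail).
#' @return An object of class `prioritization_report`: `nominations`
#'   (data.frame), `unique` (logical), `cascade`.
#' @export
final_report <- function(prioritized, private_dels, candidate_genes,
                         consequences = list(), cascade = list()) {
  disruptive <- c("start_lost", "exon_loss", "cds_truncation")
  events <- list()
  if (nrow(prioritized) > 0L) {
    cod <- prioritized[prioritized$coding %in% TRUE, , drop = FALSE]
    for (i in seq_len(nrow(cod))) {
      events[[length(events) + 1L]] <- data.frame(
        type = "small_variant", chrom = as.character(cod$chrom[i]),
        start = cod$pos[i], end = cod$pos[i], gene = cod$gene[i],
        class = "coding_variant", genotype = cod$gt[i],
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(private_dels))) {
    cq <- if (i <= length(consequences)) consequences[[i]] else NULL
    if (is.null(cq) || !cq$class %in% disruptive) next
    events[[length(events) + 1L]] <- data.frame(
      type = "deletion", chrom = as.character(private_dels$chrom[i]),
      start = private_dels$start[i], end = private_dels$end[i],
      gene = cq$gene, class = cq$class,
      genotype = private_dels$genotype[i], stringsAsFactors = FALSE)
  }
  nominations <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), chrom = character(), start = numeric(),
               end = numeric(), gene = character(), class = character(),
               genotype = character(), stringsAsFactors = FALSE)
  structure(list(nominations = nominations,
                 unique = nrow(nominations) == 1L,
                 cascade = cascade),
            class = "prioritization_report")
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat("Prioritization report\n")
  cat("=====================\n")
  if (length(x$cascade)) {
    cat("Filter cascade:\n")
    for (nm in names(x$cascade)) {
      cat(sprintf("  %-38s %s\n", nm, format(x$cascade[[nm]])))
    }
  }
  if (nrow(x$nominations) == 0L) {
    cat("No causal candidate nominated.\n")
  } else {
    cat(sprintf("Nominated event(s)%s:\n",
                if (x$unique) "" else " [non-unique]"))
    print(x$nominations, row.names = FALSE)
  }
  invisible(x)
}

#' Write a prioritization report as JSON and text
#'
#' @param report a [final_report()] object.
#' @param json_path,txt_path output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(nominations = report$nominations, unique = report$unique,
           cascade = report$cascade),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(report)
}

#' Run the full mapping pipeline on a synthetic cohort
#'
#' Executes the complete positional-cloning cascade: per-individual ROH
#' detection on the case trio, exclusion of regions homozygous in the
#' parents, candidate-gene intersection, hom-alt/private/in-region filtering
#' of case small variants, deletion calling from the case read library,
#' private-deletion filtering against the control libraries, consequence
#' classification of surviving deletions, and the final nomination report.
#'
#' @param cohort a [simulate_cohort()] result (or an equivalently shaped
#'   list built from files).
#' @param case_id id of the sequenced affected individual.
#' @param roh roh detection parameters ([roh_params()]).
#' @param k,min_support,min_size deletion-caller thresholds.
#' @param sv_params an [sv_genotype_params()].
#' @param min_reciprocal reciprocal-overlap threshold for private deletions.
#' @return A list of class `pipeline_result` with elements `case_segments`,
#'   `novel_regions`, `genome_fraction`, `genes_in_regions`, `variants`
#'   (stage tables), `sv` (stage tables), `consequences`, `rescue` and
#'   `report`.
#' @export
run_pipeline <- function(cohort, case_id = "case1", roh = roh_params(),
                         k = 3, min_support = 3L, min_size = 300,
                         sv_params = sv_genotype_params(),
                         min_reciprocal = 0.5) {
  gm <- cohort$genotypes
  ped <- cohort$ped
  i <- ped_index(ped, case_id)
  parents <- stats::na.omit(c(ped$ind$sire[i], ped$ind$dam[i]))
  parents <- intersect(parents, rownames(gm$calls))

  case_segments <- detect_roh(gm, case_id, roh)
  parent_segments <- do.call(rbind, lapply(parents, function(p)
    detect_roh(gm, p, roh)))
  if (is.null(parent_segments)) parent_segments <- empty_roh()
  novel <- exclude_parental(case_segments, parent_segments,
                            min_novel_length_bp = roh$min_length_bp)
  genome_len <- cohort$config$n_chrom * cohort$config$chrom_length
  frac <- genome_fraction_homozygous(case_segments, genome_len)
  regions <- novel[, c("chrom", "start", "end")]
  genes_in_regions <- intersect_candidates(regions, cohort$candidate_genes)

  v_all <- decompose_multiallelic(cohort$case_variants)
  v_hom <- filter_case_homozygous_alt(v_all, case_id)
  v_priv <- filter_private(v_hom, cohort$control_variants)
  prioritized <- restrict_to_regions(v_priv, regions, cohort$gene_models)
  coding_private <- prioritized[prioritized$coding %in% TRUE, , drop = FALSE]

  pairs <- cohort$read_pairs
  case_pairs <- pairs[pairs$sample == case_id, , drop = FALSE]
  case_calls <- call_deletions(case_pairs, k = k, min_support = min_support,
                               min_size = min_size, params = sv_params)
  ctrl_ids <- grep("^control", unique(pairs$sample), value = TRUE)
  control_calls <- lapply(ctrl_ids, function(cid) {
    call_deletions(pairs[pairs$sample == cid, , drop = FALSE], k = k,
                   min_support = min_support, min_size = min_size,
                   params = sv_params)
  })
  priv_dels <- private_deletions(case_calls, control_calls, min_reciprocal)

  consequences <- vector("list", nrow(priv_dels))
  rescue <- list()
  for (j in seq_len(nrow(priv_dels))) {
    dl <- list(chrom = priv_dels$chrom[j], start = priv_dels$start[j],
               end = priv_dels$end[j])
    hit <- cohort$candidate_genes$chrom == dl$chrom &
      cohort$candidate_genes$start <= dl$end &
      cohort$candidate_genes$end >= dl$start
    if (!any(hit)) next
    gmod <- cohort$gene_models[[cohort$candidate_genes$gene[which(hit)[1L]]]]
    cq <- classify_consequence(dl, gmod)
    consequences[[j]] <- cq
    if (cq$class == "start_lost" && gmod$tx_id %in% names(cohort$transcripts)) {
      rescue[[gmod$gene_id]] <- downstream_start_rescue(
        gmod, cohort$transcripts[[gmod$tx_id]], cq)
    }
  }

  cascade <- list(
    roh_segments_case = nrow(case_segments),
    roh_genome_fraction = frac,
    novel_regions_after_parental_exclusion = nrow(novel),
    candidate_genes_in_regions = length(unique(genes_in_regions$gene)),
    case_variants_total = nrow(v_all$fix),
    hom_alt_pass = nrow(v_hom$fix),
    private_vs_controls = nrow(v_priv$fix),
    private_in_regions = nrow(prioritized),
    private_coding_in_candidates = nrow(coding_private),
    deletion_calls_case = nrow(case_calls),
    private_deletions = nrow(priv_dels),
    private_deletions_in_candidates =
      sum(!vapply(consequences, is.null, logical(1))))

  report <- final_report(prioritized, priv_dels, cohort$candidate_genes,
                         consequences, cascade)
  structure(list(case_segments = case_segments,
                 parent_segments = parent_segments,
                 novel_regions = novel, genome_fraction = frac,
                 genes_in_regions = genes_in_regions,
                 variants = list(all = v_all, hom_alt = v_hom,
                                 private = v_priv,
                                 prioritized = prioritized,
                                 coding_private = coding_private),
                 sv = list(case_calls = case_calls,
                           control_calls = control_calls,
                           private = priv_dels),
                 consequences = consequences, rescue = rescue,
                 report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
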