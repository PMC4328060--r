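#' Configuration of the synthetic cohort
#'
#' Study conditions for the simulated data set: a dense SNP array over a
#' bovine-like autosomal genome (29 autosomes), a recessive deletion planted
#' in a candidate gene and carried into the pedigree by one founder, a cohort
#' of unrelated control genomes, and a paired-end fragment library over the
#' deletion locus. Defaults mirror the case study this package models: a
#' 2,433 bp deletion at position 65,704,617-65,707,049 of chromosome 16,
#' forty controls, a 300 bp-insert 2 x 100 bp library at 20-fold coverage.
#' Marker density (2,000 per chromosome) is a desk-scale stand-in for a
#' 777k-SNP chip.
#'
#' @param seed integer seed driving every random draw.
#' @param n_chrom number of autosomes.
#' @param chrom_length autosome length in bp (all chromosomes equal).
#' @param n_markers_per_chrom array markers per chromosome, evenly spaced
#'   with jitter.
#' @param allele_freq_beta shape parameters of the symmetric Beta that
#'   founder/control allele frequencies are drawn from.
#' @param recomb_rate per-bp recombination rate for gene dropping.
#' @param deletion list `(chrom, start, end, carrier)`: the planted
#'   recessive deletion (1-based inclusive) and the founder carrying it.
#' @param shared_deletion list `(offset, length, n_control_carriers)`: a
#'   second, non-causal deletion placed `offset` bp downstream of the causal
#'   one, present in the case and in controls (so that private-deletion
#'   filtering has work to do). `NULL` disables it.
#' @param n_candidate_genes number of candidate genes, one of which hosts
#'   the deletion over its first exon.
#' @param n_controls number of unrelated control genomes.
#' @param insert_mean,insert_sd fragment-length distribution (bp);
#'   `insert_sd` must be positive.
#' @param read_length read length (bp) of each mate.
#' @param depth fold sequence coverage over the deletion locus (>= 0; 0
#'   produces an empty read set).
#' @param read_flank half-width of the sequenced window around the deletion.
#' @param mapq mapping quality written for simulated pairs.
#' @param n_shared_variants,n_private_variants,n_nonpass_variants small
#'   variants: polymorphisms shared with controls, case-private calls, and
#'   case-private calls flagged non-PASS (to exercise FILTER handling).
#' @param control_missing_rate per-genotype missing rate in control calls.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 29L,
                       chrom_length = 9e7,
                       n_markers_per_chrom = 2000L,
                       allele_freq_beta = c(1.5, 1.5),
                       recomb_rate = 1e-8,
                       deletion = list(chrom = 16L, start = 65704617,
                                       end = 65707049, carrier = "IV/A"),
                       shared_deletion = list(offset = 8000, length = 1500,
                                              n_control_carriers = 10L),
                       n_candidate_genes = 18L,
                       n_controls = 40L,
                       insert_mean = 300,
                       insert_sd = 30,
                       read_length = 100L,
                       depth = 20,
                       read_flank = 15000,
                       mapq = 60L,
                       n_shared_variants = 400L,
                       n_private_variants = 12L,
                       n_nonpass_variants = 5L,
                       control_missing_rate = 0.02) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chrom >= 1, chrom_length > 0, n_markers_per_chrom >= 1,
              length(allele_freq_beta) == 2, all(allele_freq_beta > 0),
              recomb_rate > 0)
    if (insert_sd <= 0) stop("insert_sd must be positive")
    if (depth < 0) stop("depth must be >= 0")
    if (deletion$end < deletion$start) stop("deletion end < start")
    if (deletion$start < 1 || deletion$end > chrom_length ||
        deletion$chrom < 1 || deletion$chrom > n_chrom) {
      stop("deletion interval must lie within its chromosome")
    }
  })
  structure(cfg, class = "sim_config")
}

# positions avoiding exclusion intervals; exclude = data.frame(chrom,start,end)
draw_sites <- function(n, n_chrom, chrom_length, exclude) {
  out <- data.frame(chrom = integer(0), pos = numeric(0))
  while (nrow(out) < n) {
    k <- n - nrow(out)
    cand <- data.frame(chrom = sample.int(n_chrom, k, replace = TRUE),
                       pos = ceiling(runif(k, 0, chrom_length)))
    bad <- rep(FALSE, k)
    for (j in seq_len(nrow(exclude))) {
      bad <- bad | (cand$chrom == exclude$chrom[j] &
                    cand$pos >= exclude$start[j] &
                    cand$pos <= exclude$end[j])
    }
    cand <- cand[!bad, , drop = FALSE]
    out <- unique(rbind(out, cand))
  }
  out[seq_len(n), , drop = FALSE]
}

random_codons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ok <- setdiff(all_codons, c("ATG", "TAA", "TAG", "TGA"))
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

# CDS with the translation start at base 1 and the next in-frame ATG at a
# prescribed offset; used for the downstream start-codon rescue analysis
make_cds <- function(total_len = 3600L, second_atg_offset = 900L) {
  stopifnot(total_len %% 3 == 0, second_atg_offset %% 3 == 0,
            second_atg_offset + 3 < total_len)
  n_mid <- second_atg_offset / 3 - 1L
  n_tail <- (total_len - second_atg_offset) / 3 - 2L
  paste0("ATG", random_codons(n_mid), "ATG", random_codons(n_tail), "TAA")
}

# gene models for the candidate set; gene `del_gene_idx` hosts the causal
# deletion over its first exon (933 bp upstream flank, 400 bp exon of which
# the last 79 bases are coding, 1,100 bp downstream flank)
make_candidate_genes <- function(config) {
  del <- config$deletion
  genes <- vector("list", config$n_candidate_genes)
  del_gene_idx <- min(config$n_candidate_genes, del$chrom)
  for (g in seq_len(config$n_candidate_genes)) {
    gid <- sprintf("CAND%02d", g)
    tid <- sprintf("TX%02d", g)
    if (g == del_gene_idx) {
      s <- del$start
      exon1 <- c(s + 933, s + 1332)
      cds_start <- exon1[2] - 78
      exon2 <- c(del$end + 1051, del$end + 2571)
      exon3 <- c(del$end + 2951, del$end + 5150)
      cds_end <- exon3[1] + 1999
      genes[[g]] <- gene_model(
        gene_id = gid, tx_id = tid, chrom = del$chrom, strand = "+",
        exons = data.frame(start = c(exon1[1], exon2[1], exon3[1]),
                           end = c(exon1[2], exon2[2], exon3[2])),
        cds_start = cds_start, cds_end = cds_end)
    } else {
      margin <- config$read_flank + 6000   # keep clear of the locus window
      repeat {
        ch <- sample.int(config$n_chrom, 1L)
        st <- round(runif(1, 0.05, 0.9) * config$chrom_length)
        if (!(ch == del$chrom && st + 4000 >= del$start - margin &&
              st <= del$end + margin)) break
      }
      genes[[g]] <- gene_model(
        gene_id = gid, tx_id = tid, chrom = ch,
        strand = if (runif(1) < 0.5) "+" else "-",
        exons = data.frame(start = c(st, st + 1000, st + 3000),
                           end = c(st + 199, st + 2499, st + 3999)),
        cds_start = st + 100, cds_end = st + 3499)
    }
  }
  names(genes) <- vapply(genes, function(x) x$gene_id, character(1))
  attr(genes, "del_gene") <- names(genes)[del_gene_idx]
  genes
}

#' Simulate a paired-end fragment library over a locus
#'
#' Fragments are drawn with length ~ Normal(`insert_mean`, `insert_sd`)
#' (rounded, floored at two read lengths plus two) and placed uniformly on
#' each haplotype of the region; reads are the outermost `read_length` bases
#' of the fragment in forward-reverse orientation. Deletions carried on a
#' haplotype contract its coordinate space, so a fragment spanning a
#' deletion maps with an apparent span exceeding its true length by the
#' deletion length, a fragment lying inside deleted sequence cannot exist,
#' and a read crossing a breakpoint junction is dropped as unmappable.
#'
#' @param config a [sim_config()] (only the library fields are used).
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param deletions_hap1,deletions_hap2 data.frames with `start`, `end`
#'   (1-based inclusive, within the region) of deletions on each haplotype;
#'   `NULL` for none.
#' @param sample sample id stamped on fragment ids.
#' @param seed optional integer; when given, seeds the draw (otherwise the
#'   caller's RNG stream is used).
#' @return data.frame of read-pair mapping records: `fragment`, `chrom`,
#'   `m1_start`, `m1_end`, `m2_start`, `m2_end`, `orientation`, `mapq`,
#'   `sample`.
#' @export
simulate_read_pairs <- function(config, region, deletions_hap1 = NULL,
                                deletions_hap2 = NULL, sample = "S1",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$depth < 0) stop("depth must be >= 0")
  check_dels <- function(d) {
    if (is.null(d) || nrow(d) == 0L) {
      return(data.frame(start = numeric(0), end = numeric(0)))
    }
    if (any(d$end < d$start)) stop("deletion interval with end < start")
    d[order(d$start), c("start", "end"), drop = FALSE]
  }
  dels <- list(check_dels(deletions_hap1), check_dels(deletions_hap2))
  empty <- data.frame(fragment = character(), chrom = character(),
                      m1_start = numeric(), m1_end = numeric(),
                      m2_start = numeric(), m2_end = numeric(),
                      orientation = character(), mapq = integer(),
                      sample = character(), stringsAsFactors = FALSE)
  if (config$depth == 0) return(empty)
  span <- region$end - region$start + 1
  rl <- config$read_length
  out <- list()
  for (hap in 1:2) {
    d <- dels[[hap]]
    # kept reference blocks between deletions, and their coordinates on the
    # contracted (alternate) haplotype
    blk_ref_start <- c(region$start, d$end + 1)
    blk_ref_end <- c(d$start - 1, region$end)
    keep <- blk_ref_end >= blk_ref_start
    blk_ref_start <- blk_ref_start[keep]; blk_ref_end <- blk_ref_end[keep]
    blk_w <- blk_ref_end - blk_ref_start + 1
    blk_alt_start <- cumsum(c(1, blk_w[-length(blk_w)]))
    alt_len <- sum(blk_w)
    n <- as.integer(round(config$depth * alt_len / (4 * rl)))
    if (n == 0L) next
    L <- pmax(round(rnorm(n, config$insert_mean, config$insert_sd)),
              2 * rl + 2)
    s <- floor(runif(n, 1, alt_len - L + 2))
    map_read <- function(a1, a2) {   # alt interval -> ref interval or NA
      b1 <- findInterval(a1, blk_alt_start)
      b2 <- findInterval(a2, blk_alt_start)
      ref1 <- a1 + blk_ref_start[b1] - blk_alt_start[b1]
      ref2 <- a2 + blk_ref_start[b2] - blk_alt_start[b2]
      ref1[b1 != b2] <- NA  # read straddles a breakpoint junction
      cbind(ref1, ref2)
    }
    r1 <- map_read(s, s + rl - 1)
    r2 <- map_read(s + L - rl, s + L - 1)
    ok <- !is.na(r1[, 1]) & !is.na(r2[, 1])
    if (!any(ok)) next
    out[[hap]] <- data.frame(
      fragment = sprintf("%s_h%d_f%06d", sample, hap, which(ok)),
      chrom = region$chrom,
      m1_start = r1[ok, 1], m1_end = r1[ok, 2],
      m2_start = r2[ok, 1], m2_end = r2[ok, 2],
      orientation = "FR", mapq = as.integer(config$mapq),
      sample = sample, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty
}

# haplotype deletion lists for a diploid genotype at a single locus
haplotype_deletions <- function(genotype, deletion) {
  d <- data.frame(start = deletion$start, end = deletion$end)
  none <- data.frame(start = numeric(0), end = numeric(0))
  switch(genotype,
         "wt/wt" = list(none, none),
         "wt/del" = list(none, d),
         "del/del" = list(d, d),
         stop("unknown genotype: ", genotype))
}

#' Simulate the full synthetic cohort
#'
#' Generates, under a single seed, every input the mapping pipeline
#' consumes: dense array genotypes over the pedigree (by gene-dropping
#' founder haplotypes with recombination), a case VCF and a multi-sample
#' control VCF of small variants, the candidate-gene BED and gene models, a
#' transcript FASTA, a paired-end read library over the deletion locus for
#' the sequenced individuals and all controls, and a truth record of every
#' planted feature. Transmissions on the founder-to-affected paths are
#' phase-forced at the deletion locus so that all affected individuals are
#' del/del (exact conditional sampling: crossover positions are independent
#' of phase). Array markers inside a homozygous deletion are emitted as
#' missing calls; in carriers they are emitted hemizygous-as-homozygous.
#'
#' @param config a [sim_config()].
#' @param ped a [pedigree_graph()]; defaults to [hereford_pedigree()]. The
#'   deletion carrier must be a founder and the pedigree must contain at
#'   least one affected individual.
#' @param out_dir optional directory; when given, all cohort files are
#'   written there (PED, genotype TSV, VCFs, BED, gene-model JSON, FASTA,
#'   read-pair TSV, truth JSON).
#' @return An object of class `synthetic_cohort`: list with `ped`, `config`,
#'   `genotypes` ([genotype_matrix()]), `case_variants` and
#'   `control_variants` ([variant_table()]), `candidate_genes` (data.frame),
#'   `gene_models`, `transcripts` (named character), `read_pairs`
#'   (data.frame), `truth` (list), and `files` (paths, when written).
#' @export
simulate_cohort <- function(config = sim_config(), ped = hereford_pedigree(),
                            out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  df <- ped$ind
  affected <- df$id[df$status == "affected"]
  if (length(affected) == 0L) {
    stop("pedigree must contain at least one affected individual")
  }
  del <- config$deletion
  forced <- carrier_transmissions(ped, del$carrier, affected)
  mid <- (del$start + del$end) / 2
  chrom_lengths <- rep(config$chrom_length, config$n_chrom)
  dh <- drop_haplotypes(ped, chrom_lengths, config$recomb_rate,
                        forced = list(chrom = del$chrom, pos = mid,
                                      edges = forced$edges))
  fl <- dh$founder_labels
  del_label <- fl$label[fl$id == del$carrier & fl$slot == 1L]

  # ---- marker map and founder haplotype alleles --------------------------
  m <- config$n_markers_per_chrom
  n_lab <- max(fl$label)
  map_list <- vector("list", config$n_chrom)
  hap_alleles <- vector("list", config$n_chrom)   # label x marker, 0/1
  bases <- c("A", "C", "G", "T")
  for (ch in seq_len(config$n_chrom)) {
    sp <- config$chrom_length / (m + 1)
    pos <- round(sp * seq_len(m) + runif(m, -0.3, 0.3) * sp)
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    map_list[[ch]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                                 stringsAsFactors = FALSE)
    p <- rbeta(m, config$allele_freq_beta[1], config$allele_freq_beta[2])
    hap_alleles[[ch]] <- matrix(rbinom(n_lab * m, 1L, rep(p, each = n_lab)),
                                nrow = n_lab)
  }
  map <- do.call(rbind, map_list)

  # ---- array genotypes for genotyped individuals -------------------------
  genotyped <- df$id[df$genotyped]
  calls <- matrix(NA_integer_, length(genotyped), nrow(map),
                  dimnames = list(genotyped, NULL))
  offset <- 0L
  for (ch in seq_len(config$n_chrom)) {
    pos <- map_list[[ch]]$pos
    idx <- offset + seq_len(m)
    for (id in genotyped) {
      pair <- dh$haps[[id]][[ch]]
      l1 <- pair[[1]]$lab[findInterval(pos - 0.5, pair[[1]]$brk)]
      l2 <- pair[[2]]$lab[findInterval(pos - 0.5, pair[[2]]$brk)]
      a1 <- hap_alleles[[ch]][cbind(l1, seq_len(m))]
      a2 <- hap_alleles[[ch]][cbind(l2, seq_len(m))]
      g <- a1 + a2
      if (ch == del$chrom) {
        inside <- pos >= del$start & pos <= del$end
        if (any(inside)) {
          d1 <- hap_label_at(pair[[1]], mid - 0.5) == del_label
          d2 <- hap_label_at(pair[[2]], mid - 0.5) == del_label
          if (d1 && d2) {
            g[inside] <- NA_integer_           # no DNA: array call fails
          } else if (d1) {
            g[inside] <- 2L * a2[inside]       # hemizygous read as homozygous
          } else if (d2) {
            g[inside] <- 2L * a1[inside]
          }
        }
      }
      calls[id, idx] <- as.integer(g)
    }
    offset <- offset + m
  }
  gm <- genotype_matrix(map, calls)

  # deletion genotypes of all pedigree members (truth)
  del_geno <- vapply(df$id, function(id) {
    pair <- dh$haps[[id]][[del$chrom]]
    nd <- (hap_label_at(pair[[1]], mid - 0.5) == del_label) +
          (hap_label_at(pair[[2]], mid - 0.5) == del_label)
    c("wt/wt", "wt/del", "del/del")[nd + 1L]
  }, character(1))

  # ---- candidate genes, models, transcripts ------------------------------
  gene_models <- make_candidate_genes(config)
  del_gene <- attr(gene_models, "del_gene")
  candidate_genes <- do.call(rbind, lapply(gene_models, function(gmod) {
    data.frame(gene = gmod$gene_id, chrom = gmod$chrom,
               start = min(gmod$exons$start), end = max(gmod$exons$end),
               stringsAsFactors = FALSE)
  }))
  rownames(candidate_genes) <- NULL
  transcripts <- vapply(gene_models, function(gmod) {
    if (gmod$gene_id == del_gene) make_cds(3600L, 900L) else
      paste0("ATG", random_codons(598L), "TAA")
  }, character(1))
  names(transcripts) <- vapply(gene_models, function(x) x$tx_id, character(1))

  # ---- small variants ----------------------------------------------------
  win <- list(chrom = del$chrom,
              start = max(1, del$start - config$read_flank),
              end = min(config$chrom_length, del$end + config$read_flank))
  excl_win <- data.frame(chrom = del$chrom, start = win$start, end = win$end)
  excl_genes <- data.frame(chrom = candidate_genes$chrom,
                           start = candidate_genes$start - 100,
                           end = candidate_genes$end + 100)
  shared_sites <- draw_sites(config$n_shared_variants, config$n_chrom,
                             config$chrom_length, excl_win)
  priv_sites <- draw_sites(config$n_private_variants + config$n_nonpass_variants,
                           config$n_chrom, config$chrom_length,
                           rbind(excl_win, excl_genes))
  mk_alleles <- function(n) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    list(ref = ref, alt = alt)
  }
  ns <- nrow(shared_sites)
  sa <- mk_alleles(ns)
  case_gt_shared <- sample(c("0/1", "1/1"), ns, replace = TRUE)
  q <- pmin(pmax(rbeta(ns, config$allele_freq_beta[1],
                       config$allele_freq_beta[2]), 0.02), 0.98)
  ctrl_ids <- sprintf("control%02d", seq_len(config$n_controls))
  ctrl_gt <- matrix("0/0", ns, config$n_controls,
                    dimnames = list(NULL, ctrl_ids))
  for (i in seq_len(ns)) {
    dos <- rbinom(config$n_controls, 2L, q[i])
    g <- c("0/0", "0/1", "1/1")[dos + 1L]
    g[runif(config$n_controls) < config$control_missing_rate] <- "./."
    if (!any(g %in% c("0/1", "1/1"))) g[1L] <- "0/1"  # keep site polymorphic
    ctrl_gt[i, ] <- g
  }
  np <- config$n_private_variants
  nn <- config$n_nonpass_variants
  pa <- mk_alleles(np + nn)
  case_fix <- data.frame(
    chrom = c(shared_sites$chrom, priv_sites$chrom),
    pos = c(shared_sites$pos, priv_sites$pos),
    ref = c(sa$ref, pa$ref), alt = c(sa$alt, pa$alt),
    filter = c(rep("PASS", ns + np), rep("LowQual", nn)),
    stringsAsFactors = FALSE)
  case_gt <- matrix(c(case_gt_shared, rep("1/1", np + nn)),
                    ncol = 1L, dimnames = list(NULL, "case1"))
  ord <- order(case_fix$chrom, case_fix$pos)
  case_variants <- variant_table(case_fix[ord, , drop = FALSE],
                                 case_gt[ord, , drop = FALSE])
  ords <- order(shared_sites$chrom, shared_sites$pos)
  control_variants <- variant_table(
    data.frame(chrom = shared_sites$chrom[ords], pos = shared_sites$pos[ords],
               ref = sa$ref[ords], alt = sa$alt[ords], filter = "PASS",
               stringsAsFactors = FALSE),
    ctrl_gt[ords, , drop = FALSE])

  # ---- paired-end library over the deletion locus ------------------------
  causal <- data.frame(start = del$start, end = del$end)
  shared_del <- NULL
  if (!is.null(config$shared_deletion)) {
    sd_ <- config$shared_deletion
    shared_del <- data.frame(start = del$end + sd_$offset,
                             end = del$end + sd_$offset + sd_$length - 1)
    stopifnot(shared_del$end <= win$end)
  }
  none <- data.frame(start = numeric(0), end = numeric(0))
  lib <- list()
  seq_ids <- intersect(c("case1", "III/A", "IV/A", "II/C"), df$id)
  for (id in seq_ids) {
    g <- del_geno[[id]]
    hd <- haplotype_deletions(g, del)
    if (!is.null(shared_del)) hd[[2]] <- rbind(hd[[2]], shared_del)
    lib[[id]] <- simulate_read_pairs(config, win, hd[[1]], hd[[2]],
                                     sample = id)
  }
  shared_carriers <- character(0)
  if (!is.null(shared_del)) {
    shared_carriers <- ctrl_ids[seq_len(min(config$shared_deletion$n_control_carriers,
                                            config$n_controls))]
  }
  for (cid in ctrl_ids) {
    cd <- if (cid %in% shared_carriers) shared_del else none
    lib[[cid]] <- simulate_read_pairs(config, win, cd, cd, sample = cid)
  }
  read_pairs <- do.call(rbind, lib)
  rownames(read_pairs) <- NULL

  truth <- list(
    deletion = list(chrom = del$chrom, start = del$start, end = del$end,
                    length = del$end - del$start + 1, carrier = del$carrier,
                    gene = del_gene,
                    tx = gene_models[[del_gene]]$tx_id),
    carrier_path = forced$edges,
    deletion_genotypes = as.list(del_geno),
    shared_deletion = if (is.null(shared_del)) NULL else
      list(chrom = del$chrom, start = shared_del$start, end = shared_del$end,
           case_genotype = "wt/del", control_carriers = shared_carriers),
    n_private_variants = np,
    n_shared_variants = ns,
    n_nonpass_variants = nn,
    private_variant_sites = priv_sites[seq_len(np), , drop = FALSE],
    n_private_deletions = 1L,
    n_candidate_genes = config$n_candidate_genes,
    read_window = win,
    sequenced = c(seq_ids, ctrl_ids))

  cohort <- structure(
    list(ped = ped, config = config, genotypes = gm,
         case_variants = case_variants, control_variants = control_variants,
         candidate_genes = candidate_genes, gene_models = gene_models,
         transcripts = transcripts, read_pairs = read_pairs, truth = truth,
         files = NULL),
    class = "synthetic_cohort")
  if (!is.null(out_dir)) cohort <- write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_cohort: %d markers x %d genotyped, %d case variants, ",
    "%d controls, %d read pairs\n  planted deletion: chr%s:%d-%d (%d bp) ",
    "in %s, carried by %s\n"),
    ncol(x$genotypes$calls), nrow(x$genotypes$calls),
    nrow(x$case_variants$fix), x$config$n_controls, nrow(x$read_pairs),
    x$truth$deletion$chrom, x$truth$deletion$start, x$truth$deletion$end,
    x$truth$deletion$length, x$truth$deletion$gene,
    x$truth$deletion$carrier))
  invisible(x)
}

#' Write cohort files to a directory
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created if needed).
#' @return The cohort with `files` filled in, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  files <- list(ped = fp("pedigree.ped"),
                genotypes = fp("genotypes.tsv"),
                case_vcf = fp("case.vcf"),
                controls_vcf = fp("controls.vcf"),
                genes_bed = fp("candidate_genes.bed"),
                gene_models = fp("gene_models.json"),
                transcripts = fp("transcripts.fa"),
                read_pairs = fp("read_pairs.tsv"),
                truth = fp("truth.json"))
  write_pedigree(cohort$ped, files$ped)
  write_genotype_tsv(cohort$genotypes, files$genotypes)
  write_vcf(cohort$case_variants, files$case_vcf)
  write_vcf(cohort$control_variants, files$controls_vcf)
  write_bed(cohort$candidate_genes, files$genes_bed)
  write_gene_models(cohort$gene_models, files$gene_models)
  writeLines(paste0(">", names(cohort$transcripts), "\n",
                    unname(cohort$transcripts)), files$transcripts)
  write_read_pairs(cohort$read_pairs, files$read_pairs)
  jsonlite::write_json(cohort$truth, files$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  cohort$files <- files
  invisible(cohort)
}
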