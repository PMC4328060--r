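# Haplotypes are piecewise-constant founder-label mosaics over [0, L):
# list(brk = segment start coords (first element 0), lab = integer labels).

hap_atom <- function(label) list(brk = 0, lab = as.integer(label))

# slice of haplotype `h` covering [a, b); keeps absolute coordinates
hap_slice <- function(h, a, b) {
  i1 <- findInterval(a, h$brk)
  i2 <- findInterval(b, h$brk, left.open = TRUE)
  brk <- c(a, h$brk[seq_len(i2 - i1) + i1])
  list(brk = brk, lab = h$lab[i1:i2])
}

hap_label_at <- function(h, pos) h$lab[findInterval(pos, h$brk)]

# drop adjacent segments with equal labels
hap_simplify <- function(h) {
  if (length(h$lab) < 2L) return(h)
  keep <- c(TRUE, h$lab[-1L] != h$lab[-length(h$lab)])
  list(brk = h$brk[keep], lab = h$lab[keep])
}

# One meiosis under the Haldane model: crossovers are a Poisson process of
# the given per-bp rate along [0, L), the starting parental haplotype is a
# fair coin, and the transmitted gamete alternates at each crossover.
# `force = list(pos, slot)` conditions the draw so that the segment covering
# `pos` descends from parental haplotype `slot`; since crossover positions
# are independent of the starting phase this is exact conditional sampling.
meiosis <- function(h1, h2, L, rate, force = NULL) {
  nx <- rpois(1L, rate * L)
  cuts <- if (nx > 0L) sort(runif(nx, 0, L)) else numeric(0)
  if (is.null(force)) {
    first <- sample.int(2L, 1L)
  } else {
    k <- findInterval(force$pos, cuts)
    first <- ((force$slot - 1L - k) %% 2L) + 1L
  }
  bounds <- c(0, cuts, L)
  pieces_brk <- vector("list", length(bounds) - 1L)
  pieces_lab <- vector("list", length(bounds) - 1L)
  for (j in seq_along(pieces_brk)) {
    hp <- if ((j + first) %% 2L == 0L) h1 else h2
    sl <- hap_slice(hp, bounds[j], bounds[j + 1L])
    pieces_brk[[j]] <- sl$brk
    pieces_lab[[j]] <- sl$lab
  }
  hap_simplify(list(brk = unlist(pieces_brk), lab = unlist(pieces_lab)))
}

# genome length (bp-equivalent) over which the two haplotypes carry the same
# founder label, i.e. the autozygous length
hap_shared_length <- function(h1, h2, L) {
  brk <- sort(unique(c(h1$brk, h2$brk)))
  ends <- c(brk[-1L], L)
  same <- h1$lab[findInterval(brk, h1$brk)] == h2$lab[findInterval(brk, h2$brk)]
  sum((ends - brk)[same])
}

# Forced del-allele transmissions down the pedigree so that every affected
# individual is homozygous by descent for the carrier founder's haplotype 1
# at the deletion locus. Returns list(edges = data.frame(child, parent,
# parent_slot), del_slot = named int vector: 1 paternal, 2 maternal,
# 3 both).  Slot convention: haplotype 1 = from sire, 2 = from dam.
carrier_transmissions <- function(ped, carrier, affected) {
  df <- ped$ind
  if (!carrier %in% df$id) stop("unknown carrier id: ", carrier)
  if (!(is.na(df$sire[df$id == carrier]) && is.na(df$dam[df$id == carrier]))) {
    stop("deletion carrier '", carrier, "' must be a pedigree founder")
  }
  anc <- function(id) {          # id plus all known ancestors
    out <- character(0); stack <- id
    while (length(stack)) {
      x <- stack[1L]; stack <- stack[-1L]
      if (x %in% out) next
      out <- c(out, x)
      i <- match(x, df$id)
      stack <- c(stack, stats::na.omit(c(df$sire[i], df$dam[i])))
    }
    out
  }
  del_slot <- stats::setNames(integer(0), character(0))
  edges <- list()
  need_carry <- function(x) {
    if (x %in% names(del_slot)) return(invisible())
    if (x == carrier) { del_slot[x] <<- 1L; return(invisible()) }
    i <- match(x, df$id)
    parents <- c(sire = df$sire[i], dam = df$dam[i])
    reach <- vapply(parents, function(p) !is.na(p) && carrier %in% anc(p),
                    logical(1))
    if (!any(reach)) {
      stop("individual '", x, "' cannot inherit the deletion from founder '",
           carrier, "'")
    }
    p <- parents[reach][1L]
    need_carry(p)
    edges[[length(edges) + 1L]] <<- data.frame(
      child = x, parent = unname(p),
      parent_slot = if (del_slot[p] == 3L) 1L else unname(del_slot[p]),
      stringsAsFactors = FALSE)
    del_slot[x] <<- if (names(p) == "sire") 1L else 2L
    invisible()
  }
  for (a in affected) {
    i <- ped_index(ped, a)
    s <- df$sire[i]; d <- df$dam[i]
    if (is.na(s) || is.na(d)) {
      stop("affected individual '", a, "' has an unknown parent; ",
           "cannot force del/del")
    }
    for (p in c(s, d)) {
      need_carry(p)
      edges[[length(edges) + 1L]] <- data.frame(
        child = a, parent = p,
        parent_slot = if (del_slot[p] == 3L) 1L else unname(del_slot[p]),
        stringsAsFactors = FALSE)
    }
    del_slot[a] <- 3L
  }
  list(edges = unique(do.call(rbind, edges)), del_slot = del_slot)
}

# One replicate of gene dropping: founder haplotypes get unique labels,
# non-founders inherit recombinant gametes. `forced` (optional):
# list(chrom = index, pos = bp, edges = data.frame(child, parent,
# parent_slot)) phase-forces the named meioses at `pos` on that chromosome.
# Returns list(haps = [[ind]][[chrom]] = list(h1, h2),
#              founder_labels = data.frame(id, slot, label)).
drop_haplotypes <- function(ped, chrom_lengths, rate, forced = NULL) {
  df <- ped$ind
  n <- nrow(df)
  # stable founder-haplotype labels: one per parentless slot, in topo order
  lab_id <- matrix(NA_integer_, n, 2L)
  counter <- 0L
  for (i in seq_len(n)) {
    for (slot in 1:2) {
      parent <- if (slot == 1L) df$sire[i] else df$dam[i]
      if (is.na(parent)) { counter <- counter + 1L; lab_id[i, slot] <- counter }
    }
  }
  founder_labels <- data.frame(
    id = rep(df$id, 2L)[!is.na(c(lab_id[, 1], lab_id[, 2]))],
    slot = rep(1:2, each = n)[!is.na(c(lab_id[, 1], lab_id[, 2]))],
    label = stats::na.omit(c(lab_id[, 1], lab_id[, 2])))
  haps <- rep(list(vector("list", length(chrom_lengths))), n)
  names(haps) <- df$id
  for (ci in seq_along(chrom_lengths)) {
    L <- chrom_lengths[ci]
    for (i in seq_len(n)) {
      pair <- vector("list", 2L)
      for (slot in 1:2) {
        parent <- if (slot == 1L) df$sire[i] else df$dam[i]
        if (is.na(parent)) {
          pair[[slot]] <- hap_atom(lab_id[i, slot])
        } else {
          ph <- haps[[parent]][[ci]]
          force <- NULL
          if (!is.null(forced) && ci == forced$chrom) {
            hit <- forced$edges$child == df$id[i] &
                   forced$edges$parent == parent
            if (any(hit)) {
              force <- list(pos = forced$pos,
                            slot = forced$edges$parent_slot[hit][1L])
            }
          }
          pair[[slot]] <- meiosis(ph[[1L]], ph[[2L]], L, rate, force)
        }
      }
      haps[[i]][[ci]] <- pair
    }
  }
  list(haps = haps, founder_labels = founder_labels)
}

#' Gene-dropping simulation of autozygosity
#'
#' Drops uniquely labelled founder haplotypes down the pedigree with
#' recombination (Haldane model: Poisson crossovers at `recomb_rate` per bp,
#' no interference) and measures, per individual and replicate, the fraction
#' of the genome where both haplotypes descend from the same founder
#' haplotype. The replicate mean converges to the pedigree inbreeding
#' coefficient; sex chromosomes are not modelled (lengths are interpreted as
#' autosomes).
#'
#' @param ped a [pedigree_graph()].
#' @param chrom_lengths numeric vector of chromosome lengths in bp.
#' @param recomb_rate per-bp recombination rate (1e-8 corresponds to
#'   1 cM/Mb).
#' @param n_rep number of replicates (>= 1).
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @param individuals ids to report (default: all).
#' @return An object of class `gene_drop`: list with `fractions` (n_rep x
#'   individuals matrix), `mean`, `se` (Monte-Carlo standard error of the
#'   mean) and `expected` (pedigree F) per individual.
#' @export
gene_drop <- function(ped, chrom_lengths, recomb_rate, n_rep, seed = 1L,
                      individuals = NULL) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (recomb_rate <= 0) stop("recombination rate must be positive")
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (is.null(individuals)) individuals <- ped$ind$id
  ped_index(ped, individuals)
  set.seed(seed)
  total <- sum(chrom_lengths)
  frac <- matrix(NA_real_, n_rep, length(individuals),
                 dimnames = list(NULL, individuals))
  for (r in seq_len(n_rep)) {
    dh <- drop_haplotypes(ped, chrom_lengths, recomb_rate)
    for (id in individuals) {
      shared <- 0
      for (ci in seq_along(chrom_lengths)) {
        pair <- dh$haps[[id]][[ci]]
        shared <- shared +
          hap_shared_length(pair[[1L]], pair[[2L]], chrom_lengths[ci])
      }
      frac[r, id] <- shared / total
    }
  }
  mu <- colMeans(frac)
  se <- apply(frac, 2L, stats::sd) / sqrt(n_rep)
  expected <- vapply(individuals, function(id)
    inbreeding_coefficient(ped, id), numeric(1))
  structure(list(fractions = frac, mean = mu, se = se, expected = expected,
                 n_rep = n_rep, genome_length = total),
            class = "gene_drop")
}

#' @export
print.gene_drop <- function(x, ...) {
  cat(sprintf("gene_drop: %d replicates over %.0f bp\n",
              x$n_rep, x$genome_length))
  print(data.frame(mean = round(x$mean, 4), se = round(x$se, 4),
                   expected_F = x$expected))
  invisible(x)
}
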