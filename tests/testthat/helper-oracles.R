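# Independent oracles used to check the package implementations.

# ---- Wright path-counting kinship ---------------------------------------
# f(a, b) = sum over common ancestors A and over pairs of ancestor paths
# (node-disjoint except at A) of (1/2)^(n1 + n2 + 1) * (1 + F_A).

oracle_parents <- function(ped) {
  df <- ped$ind
  setNames(lapply(seq_len(nrow(df)), function(i)
    stats::na.omit(c(df$sire[i], df$dam[i]))), df$id)
}

# all ancestor paths from x up to a (inclusive node sequences)
oracle_paths <- function(parents, x, a) {
  if (x == a) return(list(x))
  out <- list()
  for (p in parents[[x]]) {
    for (sub in oracle_paths(parents, p, a)) {
      out[[length(out) + 1L]] <- c(x, sub)
    }
  }
  out
}

oracle_ancestors <- function(parents, x) {
  out <- x
  stack <- parents[[x]]
  while (length(stack)) {
    p <- stack[1L]; stack <- stack[-1L]
    if (!p %in% out) {
      out <- c(out, p)
      stack <- c(stack, parents[[p]])
    }
  }
  out
}

wright_kinship <- function(ped, a, b) {
  parents <- oracle_parents(ped)
  F_of <- function(x) {
    ps <- parents[[x]]
    if (length(ps) < 2L) return(0)
    wright_kinship(ped, ps[1L], ps[2L])
  }
  if (a == b) return(0.5 * (1 + F_of(a)))
  common <- intersect(oracle_ancestors(parents, a),
                      oracle_ancestors(parents, b))
  total <- 0
  for (A in common) {
    pa <- oracle_paths(parents, a, A)
    pb <- oracle_paths(parents, b, A)
    for (p1 in pa) {
      for (p2 in pb) {
        if (length(intersect(p1, p2)) == 1L) {  # share only A
          n1 <- length(p1) - 1L
          n2 <- length(p2) - 1L
          total <- total + 0.5^(n1 + n2 + 1) * (1 + F_of(A))
        }
      }
    }
  }
  total
}

# random valid pedigree (parents always precede offspring)
random_pedigree <- function(n, founder_prob = 0.35) {
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2L && runif(1) > founder_prob) {
      ps <- sample(i - 1L, 2L)
      sire[i] <- id[ps[1L]]
      dam[i] <- id[ps[2L]]
    }
  }
  pedigree_graph(id, sire, dam)
}

# ---- brute-force ROH enumeration ----------------------------------------
# Quadratic scan over all marker windows, then the same leftmost-longest
# greedy selection the contract specifies; independent of the package's
# single-pass scanner.

brute_roh <- function(gm, individual, params) {
  res <- list()
  for (ch in unique(gm$map$chrom)) {
    sel <- which(gm$map$chrom == ch)
    v <- gm$calls[individual, sel]
    p <- gm$map$pos[sel]
    m <- length(sel)
    hom <- !is.na(v) & v != 1L
    het <- !is.na(v) & v == 1L
    valid <- function(i, j) {
      if (!hom[i] || !hom[j]) return(FALSE)
      w <- i:j
      if (sum(het[w]) > params$max_het_per_run) return(FALSE)
      if (sum(is.na(v[w])) > params$max_missing_per_run) return(FALSE)
      if (j > i && any(diff(p[w]) > params$max_gap_bp)) return(FALSE)
      TRUE
    }
    i <- 1L
    while (i <= m) {
      best <- NA_integer_
      for (j in i:m) if (valid(i, j)) best <- j
      if (!is.na(best) &&
          best - i + 1L >= params$min_markers &&
          p[best] - p[i] + 1 >= params$min_length_bp) {
        res[[length(res) + 1L]] <- data.frame(
          individual = individual, chrom = ch, start = p[i], end = p[best],
          n_markers = best - i + 1L, stringsAsFactors = FALSE)
        i <- best + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(individual = character(), chrom = character(),
               start = numeric(), end = numeric(), n_markers = integer(),
               stringsAsFactors = FALSE)
}

# genotype matrix with planted homozygous tracts
# tracts: data.frame(chrom, from_idx, to_idx) of marker index ranges set
# homozygous (allele 2); background random
random_genotype_matrix <- function(n_markers, spacing = 25000,
                                   het_prob = 0.35, miss_prob = 0.02,
                                   id = "case", chrom = "1",
                                   tracts = NULL) {
  pos <- cumsum(ceiling(runif(n_markers, 0.5, 1.5) * spacing))
  calls <- sample(c(0L, 1L, 2L, NA), n_markers, replace = TRUE,
                  prob = c((1 - het_prob - miss_prob) / 2,
                           het_prob,
                           (1 - het_prob - miss_prob) / 2, miss_prob))
  if (!is.null(tracts)) {
    for (k in seq_len(nrow(tracts))) {
      calls[tracts$from_idx[k]:tracts$to_idx[k]] <- 2L
    }
  }
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
               stringsAsFactors = FALSE),
    matrix(calls, nrow = 1L, dimnames = list(id, NULL)))
}
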