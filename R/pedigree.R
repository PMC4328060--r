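#' @importFrom stats rpois runif setNames median mad rnorm rbeta rbinom
#' @importFrom utils read.table write.table
NULL

#' Pedigree graph
#'
#' A directed acyclic sire/dam graph with affection status, the substrate of
#' kinship, inbreeding and gene-dropping computations. Individuals with
#' unknown parents are founders; unknown parents are treated as unique,
#' unrelated founders (a conservative lower bound on inbreeding when pedigree
#' records are incomplete).
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam character vectors of parent ids; `NA` or `"0"` means
#'   unknown.
#' @param sex one of `"male"`, `"female"`, `"unknown"` per individual.
#' @param status one of `"affected"`, `"unaffected"`, `"unknown"`.
#' @param genotyped logical; whether DNA/array data exist for the individual.
#' @return An object of class `pedigree_graph`: a list with element `ind`
#'   (data.frame of individual records, in topological order: parents before
#'   offspring).
#' @examples
#' ped <- pedigree_graph(id = c("f1", "f2", "kid"),
#'                       sire = c(NA, NA, "f1"), dam = c(NA, NA, "f2"))
#' inbreeding_coefficient(ped, "kid")
#' @export
pedigree_graph <- function(id, sire, dam,
                           sex = rep("unknown", length(id)),
                           status = rep("unknown", length(id)),
                           genotyped = rep(TRUE, length(id))) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[!is.na(sire) & sire == "0"] <- NA
  dam[!is.na(dam) & dam == "0"] <- NA
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  stopifnot(length(sire) == length(id), length(dam) == length(id))
  sex <- match.arg(sex, c("male", "female", "unknown"), several.ok = TRUE)
  status <- match.arg(status, c("affected", "unaffected", "unknown"),
                      several.ok = TRUE)
  sex <- rep_len(sex, length(id))
  status <- rep_len(status, length(id))
  genotyped <- rep_len(as.logical(genotyped), length(id))

  # parents referenced but not listed become implicit founders
  refs <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(refs)) {
    id <- c(id, refs)
    sire <- c(sire, rep(NA_character_, length(refs)))
    dam <- c(dam, rep(NA_character_, length(refs)))
    sex <- c(sex, rep("unknown", length(refs)))
    status <- c(status, rep("unknown", length(refs)))
    genotyped <- c(genotyped, rep(FALSE, length(refs)))
  }
  df <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                   status = status, genotyped = genotyped,
                   stringsAsFactors = FALSE)
  ord <- topo_order(df)      # errors on cycles (own-ancestor individuals)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- df$id
  structure(list(ind = df), class = "pedigree_graph")
}

# Kahn topological sort; stops with a cycle error naming the individuals.
topo_order <- function(df) {
  n <- nrow(df)
  idx <- setNames(seq_len(n), df$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(df$sire[i], df$dam[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        indeg[i] <- indeg[i] + 1L
        children[[j]] <- c(children[[j]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree contains a cycle (an individual is its own ancestor): ",
         paste(df$id[setdiff(seq_len(n), out)], collapse = ", "))
  }
  out
}

#' @export
print.pedigree_graph <- function(x, ...) {
  df <- x$ind
  cat(sprintf("pedigree_graph: %d individuals (%d founders, %d affected)\n",
              nrow(df), sum(is.na(df$sire) & is.na(df$dam)),
              sum(df$status == "affected")))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Parse a PED-format pedigree
#'
#' Reads whitespace-delimited PED rows (family, id, sire, dam, sex,
#' phenotype, ...). `"0"` denotes an unknown parent; sex is coded 1 = male,
#' 2 = female, other = unknown; phenotype column 6 is coded 1 = unaffected,
#' 2 = affected, 0/-9 = unknown. An optional 7th column (0/1) flags whether
#' the individual was genotyped (default 1).
#'
#' @param ped a path to a PED file, or a data.frame/matrix of PED columns.
#' @return A [pedigree_graph()].
#' @export
parse_pedigree <- function(ped) {
  if (is.character(ped) && length(ped) == 1L) {
    ped <- read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", fill = TRUE)
  }
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  if (ncol(ped) < 6L) {
    stop("PED input must have at least 6 columns ",
         "(family, id, sire, dam, sex, phenotype)")
  }
  sex_code <- as.character(ped[[5]])
  status_code <- as.character(ped[[6]])
  sex <- ifelse(sex_code == "1", "male",
                ifelse(sex_code == "2", "female", "unknown"))
  status <- ifelse(status_code == "2", "affected",
                   ifelse(status_code == "1", "unaffected", "unknown"))
  genotyped <- if (ncol(ped) >= 7L) as.character(ped[[7]]) != "0" else TRUE
  pedigree_graph(id = as.character(ped[[2]]),
                 sire = as.character(ped[[3]]),
                 dam = as.character(ped[[4]]),
                 sex = sex, status = status, genotyped = genotyped)
}

#' Write a pedigree as a PED file
#'
#' @param ped a [pedigree_graph()].
#' @param path output file path.
#' @param family family id written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  df <- ped$ind
  out <- data.frame(
    family = family, id = df$id,
    sire = ifelse(is.na(df$sire), "0", df$sire),
    dam = ifelse(is.na(df$dam), "0", df$dam),
    sex = c(male = 1L, female = 2L, unknown = 0L)[df$sex],
    status = c(affected = 2L, unaffected = 1L, unknown = 0L)[df$status],
    genotyped = as.integer(df$genotyped))
  write.table(out, path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' The Hereford epidermolysis bullosa study pedigree
#'
#' The four-generation inbred Hereford pedigree around three calves affected
#' by junctional epidermolysis bullosa. Two inbreeding loops are present:
#' son III/A mated back to his mother IV/A (producing case 1), and son II/C
#' mated back to III/B (producing case 3); case 2 is the offspring of the
#' full sibs III/A and III/B. III/C is a cow of unknown descent and II/2 is
#' an ancillary relative of unknown descent; neither was genotyped.
#'
#' @return A [pedigree_graph()] of 10 individuals with three affected leaves.
#' @export
hereford_pedigree <- function() {
  pedigree_graph(
    id   = c("IV/A", "IV/B", "III/C", "II/2", "III/A", "III/B",
             "II/C", "case1", "case2", "case3"),
    sire = c(NA, NA, NA, NA, "IV/B", "IV/B", "III/A", "III/A", "III/A", "II/C"),
    dam  = c(NA, NA, NA, NA, "IV/A", "IV/A", "III/C", "IV/A", "III/B", "III/B"),
    sex  = c("female", "male", "female", "unknown", "male", "female",
             "male", "female", "unknown", "male"),
    status = c(rep("unaffected", 7), rep("affected", 3)),
    genotyped = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                  TRUE, TRUE, TRUE, TRUE))
}

ped_index <- function(ped, ids) {
  i <- match(ids, ped$ind$id)
  if (anyNA(i)) {
    stop("unknown individual id(s): ", paste(ids[is.na(i)], collapse = ", "))
  }
  i
}

#' Kinship matrix of a pedigree
#'
#' Computes the full kinship (coancestry) matrix by the tabular method in
#' topological order: f(x, x) = (1 + f(sire_x, dam_x)) / 2 and, for y not an
#' ancestor of x, f(x, y) = (f(sire_x, y) + f(dam_x, y)) / 2, with founders
#' mutually unrelated and unknown parents contributing 0.
#'
#' @param ped a [pedigree_graph()].
#' @return A symmetric numeric matrix with individual ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  df <- ped$ind                      # topological order
  n <- nrow(df)
  K <- matrix(0, n, n, dimnames = list(df$id, df$id))
  si <- match(df$sire, df$id)        # NA for unknown
  di <- match(df$dam, df$id)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      fs <- if (is.na(s)) 0 else K[prev, s]
      fd <- if (is.na(d)) 0 else K[prev, d]
      K[prev, j] <- K[j, prev] <- (fs + fd) / 2
    }
    fsd <- if (is.na(s) || is.na(d)) 0 else K[s, d]
    K[j, j] <- (1 + fsd) / 2
  }
  K
}

#' Kinship coefficient of two individuals
#'
#' Probability that one allele drawn at random from `a` and one from `b` at
#' the same autosomal locus are identical by descent.
#'
#' @param ped a [pedigree_graph()].
#' @param a,b individual ids.
#' @return A probability in `[0, 1]`.
#' @export
kinship_coefficient <- function(ped, a, b) {
  i <- ped_index(ped, c(a, b))
  K <- kinship_matrix(ped)
  unname(K[i[1], i[2]])
}

#' Inbreeding coefficient
#'
#' `F(ind)` is the kinship of the individual's parents; it is exactly 0 when
#' either parent is unknown.
#'
#' @param ped a [pedigree_graph()].
#' @param ind individual id.
#' @return A probability in `[0, 1]`.
#' @export
inbreeding_coefficient <- function(ped, ind) {
  i <- ped_index(ped, ind)
  s <- ped$ind$sire[i]; d <- ped$ind$dam[i]
  if (is.na(s) || is.na(d)) return(0)
  kinship_coefficient(ped, s, d)
}

#' Obligate carriers under autosomal recessive inheritance
#'
#' Each parent of an affected individual must carry one copy of the mutant
#' allele; the unaffected ones among them are obligate carriers. Carrier
#' status of more remote relatives (e.g. one of the two parents of a known
#' carrier) is not decidable from the pedigree alone and is not reported.
#'
#' @param ped a [pedigree_graph()].
#' @param affected character vector of affected individual ids; defaults to
#'   the individuals with `status == "affected"`.
#' @return Character vector of obligate-carrier ids.
#' @export
obligate_carriers <- function(ped, affected = NULL) {
  df <- ped$ind
  if (is.null(affected)) affected <- df$id[df$status == "affected"]
  if (length(affected) == 0L) stop("'affected' must be non-empty")
  i <- ped_index(ped, affected)
  parents <- unique(stats::na.omit(c(df$sire[i], df$dam[i])))
  setdiff(parents, affected)
}

#' Check genotypes for Mendelian consistency
#'
#' Flags offspring whose biallelic genotype is incompatible with their
#' genotyped parents under Mendelian transmission. Genotypes are coded
#' `"wt/wt"`, `"wt/del"`, `"del/del"`; missing individuals are skipped.
#'
#' @param ped a [pedigree_graph()].
#' @param genotypes named character vector or list, id -> genotype.
#' @return A data.frame of violations (possibly 0 rows) with columns
#'   `offspring`, `sire`, `dam` and `reason`.
#' @export
mendelian_check <- function(ped, genotypes) {
  genotypes <- unlist(genotypes)
  df <- ped$ind
  alleles <- list("wt/wt" = c(0L, 0L), "wt/del" = c(0L, 1L),
                  "del/del" = c(1L, 1L))
  bad <- vapply(names(genotypes), function(id) {
    !genotypes[[id]] %in% names(alleles)
  }, logical(1))
  if (any(bad)) {
    stop("unrecognised genotype(s): ",
         paste(unique(genotypes[bad]), collapse = ", "))
  }
  typed <- function(x) !is.na(x) && x %in% names(genotypes)
  viol <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$id[i]
    if (!typed(id)) next
    po <- alleles[[genotypes[[id]]]]
    can_give <- function(parent, allele) {
      if (!typed(parent)) return(TRUE)   # ungenotyped: anything possible
      allele %in% alleles[[genotypes[[parent]]]]
    }
    s <- df$sire[i]; d <- df$dam[i]
    # offspring alleles (a1, a2): one from each parent, either assignment
    ok <- (can_give(s, po[1]) && can_give(d, po[2])) ||
          (can_give(s, po[2]) && can_give(d, po[1]))
    if (!ok) {
      viol[[length(viol) + 1L]] <- data.frame(
        offspring = id, sire = s, dam = d,
        reason = sprintf("offspring %s incompatible with parents (%s x %s)",
                         genotypes[[id]],
                         if (typed(s)) genotypes[[s]] else "untyped",
                         if (typed(d)) genotypes[[d]] else "untyped"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(offspring = character(), sire = character(),
               dam = character(), reason = character(),
               stringsAsFactors = FALSE)
}

#' Export kinship and inbreeding tables as JSON
#'
#' @param ped a [pedigree_graph()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_kinship_json <- function(ped, path) {
  K <- kinship_matrix(ped)
  f <- vapply(ped$ind$id, function(id) inbreeding_coefficient(ped, id),
              numeric(1))
  jsonlite::write_json(
    list(individuals = ped$ind$id,
         kinship = as.data.frame(K),
         inbreeding = as.list(f)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
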