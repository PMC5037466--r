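## Microsatellite population genetics and the population tree:
## allele frequencies, Nei's DA allele-sharing distance, neighbor-joining
## with locus bootstrap, Weir-Cockerham FST between clusters, and midpoint
## rooting for the downstream contrasts.

#' Diploid microsatellite genotype table
#'
#' @param individual character vector of individual ids (unique).
#' @param population character vector assigning each individual to one
#'   population.
#' @param a1,a2 integer matrices (individuals x loci) of allele labels
#'   (positive integers); `NA` in both marks a missing genotype.
#' @param loci locus names.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(individual, population, a1, a2, loci) {
  individual <- as.character(individual); population <- as.character(population)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (anyDuplicated(individual)) stop_invalid("individual ids must be unique")
  if (length(individual) != nrow(a1) || length(population) != nrow(a1) ||
      !identical(dim(a1), dim(a2)) || ncol(a1) != length(loci))
    stop_invalid("dimension mismatch between ids, populations and allele matrices")
  if (any(a1[!is.na(a1)] < 1) || any(a2[!is.na(a2)] < 1))
    stop_invalid("allele labels must be positive integers")
  if (any(is.na(a1) != is.na(a2)))
    stop_invalid("half-missing genotypes are not supported")
  dimnames(a1) <- dimnames(a2) <- list(individual, loci)
  structure(list(individual = individual, population = population,
                 a1 = a1, a2 = a2, loci = as.character(loci)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d populations, %d loci (%.1f%% missing)\n",
              length(x$individual), length(unique(x$population)),
              length(x$loci), 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Write genotypes in GenePop format
#'
#' Three-digit allele codes per allele (six digits per genotype), missing
#' genotypes coded `000000`, one `Pop` block per population.
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  if (any(c(table$a1, table$a2) > 999, na.rm = TRUE))
    stop_invalid("allele labels must fit 3-digit GenePop codes (<= 999)")
  lines <- c("chorusem genotype export", table$loci)
  for (pop in unique(table$population)) {
    lines <- c(lines, "Pop")
    idx <- which(table$population == pop)
    for (i in idx) {
      codes <- vapply(seq_along(table$loci), function(l) {
        if (is.na(table$a1[i, l])) "000000"
        else sprintf("%03d%03d", table$a1[i, l], table$a2[i, l])
      }, "")
      lines <- c(lines, paste0(table$individual[i], " ,  ",
                               paste(codes, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes
#'
#' Parses GenePop (`format = "genepop"`; 2- or 3-digit allele codes,
#' all-zero = missing) or a long CSV (`format = "csv"` with columns
#' `individual`, `population`, `locus`, `allele1`, `allele2`; empty/NA
#' alleles = missing).
#'
#' @param path file path.
#' @param format `"genepop"` or `"csv"`.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("genepop", "csv")) {
  format <- match.arg(format)
  if (format == "csv") return(read_genotypes_csv(path))
  lines <- readLines(path)
  if (length(lines) < 4) stop_invalid("truncated GenePop file: ", path)
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop_invalid("no 'Pop' line found in ", path)
  header <- lines[2:(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(paste(header, collapse = ","), ",")))
  loci <- loci[nzchar(loci)]
  ind <- character(0); pop <- character(0)
  rows1 <- list(); rows2 <- list()
  pop_counter <- 0
  for (k in seq(pop_idx[1], length(lines))) {
    line <- trimws(lines[k])
    if (!nzchar(line)) next
    if (grepl("^pop$", line, ignore.case = TRUE)) {
      pop_counter <- pop_counter + 1; next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2)
      stop_invalid("malformed GenePop row at line ", k, ": ", lines[k])
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop_invalid("line ", k, ": expected ", length(loci), " genotypes, got ",
                   length(codes))
    w <- nchar(codes[1]) / 2
    if (!w %in% c(2, 3))
      stop_invalid("line ", k, ": allele codes must be 2 or 3 digits")
    g1 <- as.integer(substr(codes, 1, w))
    g2 <- as.integer(substr(codes, w + 1, 2 * w))
    miss <- g1 == 0 | g2 == 0
    g1[miss] <- NA_integer_; g2[miss] <- NA_integer_
    ind <- c(ind, id)
    pop <- c(pop, sprintf("pop%02d", pop_counter))
    rows1[[length(rows1) + 1]] <- g1; rows2[[length(rows2) + 1]] <- g2
  }
  # GenePop convention: a population is often named after its individuals'
  # shared prefix; recover "Pxx" style prefixes when present.
  prefix <- sub("_.*$", "", ind)
  for (pc in unique(pop)) {
    pr <- unique(prefix[pop == pc])
    if (length(pr) == 1 && nzchar(pr)) pop[pop == pc] <- pr
  }
  genotype_table(ind, pop, do.call(rbind, rows1), do.call(rbind, rows2), loci)
}

read_genotypes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop_invalid("genotype CSV needs columns: ", paste(need, collapse = ", "))
  loci <- sort(unique(df$locus))
  inds <- unique(df$individual)
  popmap <- df$population[match(inds, df$individual)]
  a1 <- matrix(NA_integer_, length(inds), length(loci))
  a2 <- a1
  a1[cbind(match(df$individual, inds), match(df$locus, loci))] <-
    suppressWarnings(as.integer(df$allele1))
  a2[cbind(match(df$individual, inds), match(df$locus, loci))] <-
    suppressWarnings(as.integer(df$allele2))
  both_na <- is.na(a1) | is.na(a2)
  a1[both_na] <- NA_integer_; a2[both_na] <- NA_integer_
  genotype_table(inds, popmap, a1, a2, loci)
}

#' Remove individuals with too much missing data
#'
#' Drops individuals whose fraction of missing loci exceeds
#' `max_missing_fraction` (default 0.20, i.e. keep only individuals with
#' at most 20% missing).
#'
#' @param table a [genotype_table()].
#' @param max_missing_fraction threshold in \[0, 1\].
#' @return the filtered [genotype_table()]; warns if a population is
#'   emptied entirely.
#' @export
filter_missing <- function(table, max_missing_fraction = 0.20) {
  stopifnot(inherits(table, "genotype_table"))
  if (!is_number(max_missing_fraction) || max_missing_fraction < 0 ||
      max_missing_fraction > 1)
    stop_invalid("threshold must be in [0, 1]")
  frac <- rowMeans(is.na(table$a1))
  keep <- frac <= max_missing_fraction
  lost_pops <- setdiff(unique(table$population),
                       unique(table$population[keep]))
  if (length(lost_pops))
    warning("filter_missing emptied population(s): ",
            paste(lost_pops, collapse = ", "))
  genotype_table(table$individual[keep], table$population[keep],
                 table$a1[keep, , drop = FALSE],
                 table$a2[keep, , drop = FALSE], table$loci)
}

#' Per-population allele frequencies
#'
#' Counts alleles over non-missing genotypes per (population, locus) and
#' normalises. A (population, locus) cell with no data is absent
#' (`NULL`); downstream DA computation skips such loci pairwise.
#'
#' @param table a [genotype_table()].
#' @return object of class `allele_frequencies`: `freqs[[pop]][[locus]]`
#'   is a named numeric vector summing to 1, and `n[[pop]][[locus]]` the
#'   number of genotyped individuals.
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- unique(table$population)
  freqs <- list(); ns <- list()
  for (pop in pops) {
    idx <- table$population == pop
    freqs[[pop]] <- list(); ns[[pop]] <- list()
    for (l in seq_along(table$loci)) {
      al <- c(table$a1[idx, l], table$a2[idx, l])
      al <- al[!is.na(al)]
      if (!length(al)) next
      tab <- table(al)
      freqs[[pop]][[table$loci[l]]] <- setNames(as.numeric(tab) / sum(tab),
                                                names(tab))
      ns[[pop]][[table$loci[l]]] <- length(al) / 2
    }
  }
  structure(list(freqs = freqs, n = ns, loci = table$loci,
                 populations = pops),
            class = "allele_frequencies")
}

#' Nei's DA distance between two populations
#'
#' `DA = 1 - (1/L) * sum over shared loci of sum over alleles of
#' sqrt(p_a q_a)`, where L is the number of loci with data in both
#' populations. Lies in \[0, 1\]; 0 iff frequencies are identical at every
#' shared locus, 1 iff allele sets are disjoint at every shared locus.
#'
#' @param p,q per-locus allele-frequency lists for the two populations
#'   (elements of `allele_frequencies()$freqs`).
#' @return the DA distance.
#' @export
da_distance <- function(p, q) {
  shared <- intersect(names(p), names(q))
  if (!length(shared))
    stop_insufficient("no locus with data in both populations; DA undefined")
  s <- vapply(shared, function(l) {
    alleles <- union(names(p[[l]]), names(q[[l]]))
    pa <- setNames(rep(0, length(alleles)), alleles)
    qa <- pa
    pa[names(p[[l]])] <- p[[l]]; qa[names(q[[l]])] <- q[[l]]
    sum(sqrt(pa * qa))
  }, 0)
  1 - mean(s)
}

#' Pairwise DA distance matrix
#'
#' @param freqs an [allele_frequencies()] object.
#' @return symmetric matrix of DA distances with zero diagonal, labelled
#'   by population.
#' @export
build_distance_matrix <- function(freqs) {
  stopifnot(inherits(freqs, "allele_frequencies"))
  pops <- freqs$populations
  n <- length(pops)
  D <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- da_distance(freqs$freqs[[pops[i]]],
                                      freqs$freqs[[pops[j]]])
  }
  D
}

# Kuhner-Felsenstein handling of negative NJ branch lengths: clamp to zero
# and transfer the deficit to an adjacent branch at the same node so path
# lengths are approximately preserved; residual negatives are clamped.
clamp_negative_branches <- function(tree) {
  for (e in seq_along(tree$edge.length)) {
    if (tree$edge.length[e] < 0) {
      node <- tree$edge[e, 1]
      sib <- which(tree$edge[, 1] == node & seq_len(nrow(tree$edge)) != e)
      if (length(sib)) {
        sib <- sib[1]
        tree$edge.length[sib] <- tree$edge.length[sib] + tree$edge.length[e]
      }
      tree$edge.length[e] <- 0
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining population tree
#'
#' Saitou-Nei agglomeration on a distance matrix. Negative branch lengths
#' (an occasional artefact of NJ on noisy distances) are clamped to zero
#' with the deficit transferred to the adjacent branch, so downstream
#' contrast standardisation never sees a negative variance.
#'
#' @param D symmetric distance matrix with >= 3 labelled rows.
#' @return an unrooted `phylo`.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop_invalid("neighbor joining needs >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop_invalid("distance matrix must be symmetric")
  tr <- ape::nj(D)
  clamp_negative_branches(tr)
}

#' Locus-bootstrap support for the NJ population tree
#'
#' Loci are resampled with replacement `n_reps` times; each replicate's
#' allele frequencies, DA matrix and NJ tree are recomputed, and support
#' for each internal bipartition of the full-data tree is the percentage
#' of replicate trees containing it. Supports are stored in
#' `tree$node.label` (root label empty).
#'
#' @param table a [genotype_table()] with >= 2 loci.
#' @param n_reps bootstrap replicates (>= 1); the study design uses
#'   10,000, smaller values are fine for exploration.
#' @param seed RNG seed.
#' @return the full-data NJ `phylo` with `node.label` support percentages.
#' @export
bootstrap_support <- function(table, n_reps = 1000, seed = 1L) {
  stopifnot(inherits(table, "genotype_table"))
  if (length(table$loci) < 2) stop_invalid("bootstrap needs >= 2 loci")
  if (!is_count(n_reps, min = 1)) stop_invalid("n_reps must be >= 1")
  full <- neighbor_joining(build_distance_matrix(allele_frequencies(table)))
  L <- length(table$loci)
  boots <- with_rng(seed, {
    lapply(seq_len(n_reps), function(r) {
      pick <- sample.int(L, L, replace = TRUE)
      tb <- genotype_table(table$individual, table$population,
                           table$a1[, pick, drop = FALSE],
                           table$a2[, pick, drop = FALSE],
                           sprintf("bs%03d", seq_len(L)))
      neighbor_joining(build_distance_matrix(allele_frequencies(tb)))
    })
  })
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(full, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  supp <- round(100 * cnt / n_reps, 1)
  full$node.label <- as.character(supp)
  full$node.label[1] <- ""   # root of the unrooted representation
  full
}

# Weir-Cockerham (1984) variance components for one allele at one locus.
# n_i = diploid sample sizes, p_i = allele frequencies, h_i = observed
# heterozygote proportions involving the allele.
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

fst_theta <- function(table, groups) {
  ug <- unique(groups)
  A <- 0; ABC <- 0
  for (l in seq_along(table$loci)) {
    g1 <- table$a1[, l]; g2 <- table$a2[, l]
    ok <- !is.na(g1)
    alleles <- sort(unique(c(g1[ok], g2[ok])))
    if (length(alleles) < 2) next
    n_i <- vapply(ug, function(g) sum(ok & groups == g), 0)
    if (any(n_i < 1)) next
    for (al in alleles) {
      p_i <- vapply(ug, function(g) {
        idx <- ok & groups == g
        (sum(g1[idx] == al) + sum(g2[idx] == al)) / (2 * sum(idx))
      }, 0)
      h_i <- vapply(ug, function(g) {
        idx <- ok & groups == g
        sum((g1[idx] == al) != (g2[idx] == al)) / sum(idx)
      }, 0)
      comp <- wc_components(n_i, p_i, h_i)
      A <- A + comp["a"]; ABC <- ABC + sum(comp)
    }
  }
  if (ABC == 0) return(NA_real_)
  unname(A / ABC)
}

#' Mean FST between clusters (Weir-Cockerham theta)
#'
#' Multi-allelic Weir-Cockerham theta per locus, combined over alleles and
#' loci as a ratio of sums of variance components, over all clusters
#' jointly. The p-value is obtained by permuting cluster labels across
#' individuals.
#'
#' @param table a [genotype_table()].
#' @param cluster_map named character/integer vector mapping individual id
#'   to cluster (or a vector aligned with `table$individual`).
#' @param n_perm permutations for the p-value (0 to skip).
#' @param seed RNG seed for the permutations.
#' @return list with `theta`, `p_value`, `n_clusters`; clusters with < 2
#'   individuals are dropped with a warning.
#' @export
mean_fst <- function(table, cluster_map, n_perm = 199, seed = 1L) {
  stopifnot(inherits(table, "genotype_table"))
  groups <- if (!is.null(names(cluster_map)))
    as.character(cluster_map[table$individual]) else as.character(cluster_map)
  if (length(groups) != length(table$individual) || any(is.na(groups)))
    stop_invalid("every individual needs a cluster assignment")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding cluster(s) with < 2 individuals: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    table <- genotype_table(table$individual[keep], table$population[keep],
                            table$a1[keep, , drop = FALSE],
                            table$a2[keep, , drop = FALSE], table$loci)
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop_invalid("need >= 2 clusters")
  obs <- fst_theta(table, groups)
  p <- NA_real_
  if (n_perm > 0) {
    perm <- with_rng(seed, vapply(seq_len(n_perm), function(i)
      fst_theta(table, sample(groups)), 0))
    p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
  }
  list(theta = obs, p_value = p, n_clusters = length(unique(groups)))
}

#' Midpoint-root an unrooted tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path, giving
#' the rooted tree required by independent contrasts.
#'
#' @param tree an unrooted `phylo` with positive total path lengths.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    stop_invalid("cannot midpoint-root a tree with no positive branch lengths")
  phangorn::midpoint(tree)
}
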