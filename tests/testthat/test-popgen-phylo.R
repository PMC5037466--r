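# Population genetics: GenePop I/O, missing-data filter, allele
# frequencies, DA distances, neighbor joining, bootstrap support, FST,
# midpoint rooting.

test_that("GenePop files round-trip and malformed input is rejected", {
  g <- toy_genotypes(n_per_pop = 3, n_loci = 3)
  f <- tempfile(fileext = ".gen")
  write_genepop(g, f)
  back <- read_genotypes(f, format = "genepop")
  expect_equal(length(unique(back$population)), 2)
  expect_equal(back$a1, g$a1, ignore_attr = TRUE)
  expect_equal(back$a2, g$a2, ignore_attr = TRUE)
  expect_equal(back$loci, g$loci)

  writeLines(c("title", "L1"), f)
  expect_error(read_genotypes(f, "genepop"), "truncated")
  writeLines(c("title", "L1", "L2", "Pop", "ind1 , 001001"), f)
  expect_error(read_genotypes(f, "genepop"), "expected 2")
})

test_that("missing genotypes survive the GenePop round-trip as zeros", {
  g <- toy_genotypes(n_per_pop = 3, n_loci = 4)
  g$a1[1, 2] <- NA; g$a2[1, 2] <- NA
  g <- genotype_table(g$individual, g$population, g$a1, g$a2, g$loci)
  f <- tempfile(fileext = ".gen")
  write_genepop(g, f)
  back <- read_genotypes(f)
  expect_true(is.na(back$a1[1, 2]) && is.na(back$a2[1, 2]))
  expect_equal(sum(is.na(back$a1)), 1)
})

test_that("CSV genotype format parses to the same table", {
  g <- toy_genotypes(n_per_pop = 2, n_loci = 2)
  df <- expand.grid(individual = g$individual, locus = g$loci,
                    stringsAsFactors = FALSE)
  df$population <- g$population[match(df$individual, g$individual)]
  df$allele1 <- g$a1[cbind(match(df$individual, g$individual),
                           match(df$locus, g$loci))]
  df$allele2 <- df$allele1
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  back <- read_genotypes(f, format = "csv")
  expect_equal(back$a1[g$individual, g$loci], g$a1, ignore_attr = TRUE)
})

test_that("the >20% missing-data filter drops the right individuals", {
  n_loci <- 18
  a <- matrix(1L, nrow = 3, ncol = n_loci)
  a[1, 1:5] <- NA      # 27.8% missing -> dropped
  a[2, 1:3] <- NA      # 16.7% missing -> kept
  g <- genotype_table(c("x", "y", "z"), c("A", "A", "B"), a, a,
                      sprintf("L%02d", 1:n_loci))
  out <- filter_missing(g, 0.20)
  expect_equal(out$individual, c("y", "z"))
  expect_equal(filter_missing(g, 1.0)$individual, g$individual)
  a2 <- a; a2[3, ] <- NA
  g2 <- genotype_table(c("x", "y", "z"), c("A", "A", "B"), a2, a2,
                       sprintf("L%02d", 1:n_loci))
  expect_warning(filter_missing(g2, 0.20), "emptied population")
})

test_that("allele frequencies count non-missing genotypes and normalise", {
  a1 <- matrix(c(1L, 1L), ncol = 1); a2 <- matrix(c(1L, 2L), ncol = 1)
  g <- genotype_table(c("i1", "i2"), c("A", "A"), a1, a2, "L1")
  fr <- allele_frequencies(g)
  expect_equal(fr$freqs$A$L1, c("1" = 0.75, "2" = 0.25))
  expect_equal(fr$n$A$L1, 2)
  # monomorphic population
  g2 <- toy_genotypes(2, 1)
  fr2 <- allele_frequencies(g2)
  expect_equal(unname(fr2$freqs$A$L1), 1)
  # sums to one for random tables
  tr <- simulate_tree(3, seed = 1)
  g3 <- simulate_genotypes(tr, synthetic_config(n_populations = 3,
                                                n_individuals_per_pop = 6),
                           seed = 2)
  fr3 <- allele_frequencies(g3)
  sums <- unlist(lapply(fr3$freqs, function(p) vapply(p, sum, 0)))
  expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("DA distance matches its closed form and is a premetric", {
  p <- list(L1 = c("1" = 1))
  q <- list(L1 = c("1" = 0.5, "2" = 0.5))
  expect_equal(da_distance(p, q), 1 - sqrt(0.5), tolerance = 1e-12)
  expect_equal(da_distance(p, p), 0)
  expect_equal(da_distance(p, list(L1 = c("2" = 0.6, "3" = 0.4))), 1)
  set.seed(3)
  for (i in 1:20) {
    ra <- abs(rnorm(4)); ra <- ra / sum(ra)
    rb <- abs(rnorm(4)); rb <- rb / sum(rb)
    a <- list(L1 = setNames(ra, 1:4), L2 = setNames(rb, 1:4))
    b <- list(L1 = setNames(rb, 1:4), L2 = setNames(ra, 1:4))
    expect_equal(da_distance(a, b), da_distance(b, a))
    expect_gte(da_distance(a, b), 0)
    expect_lte(da_distance(a, b), 1)
    expect_equal(da_distance(a, a), 0, tolerance = 1e-12)
  }
  expect_error(da_distance(list(L1 = c("1" = 1)), list(L2 = c("1" = 1))),
               "no locus")
})

test_that("the DA matrix is symmetric, zero-diagonal and per-pair consistent", {
  tr <- simulate_tree(5, seed = 4)
  g <- simulate_genotypes(tr, synthetic_config(n_populations = 5,
                                               n_individuals_per_pop = 8),
                          seed = 5)
  fr <- allele_frequencies(g)
  D <- build_distance_matrix(fr)
  expect_equal(dim(D), c(5, 5))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_equal(D["P01", "P03"],
               da_distance(fr$freqs$P01, fr$freqs$P03))
})

test_that("neighbor joining recovers an additive 4-taxon matrix exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) gives AB=3 AC=5 AD=6 BC=6 BD=7 CD=7
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 4)
  # additive: path lengths reproduce the input distances
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
  # the split AB|CD is present
  parts <- ape::prop.part(ape::unroot(tr))
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  expect_true(any(vapply(splits, identical, TRUE, c("A", "B"))) ||
                any(vapply(splits, identical, TRUE, c("C", "D"))))
  # tip branch lengths
  tip_edge <- setNames(tr$edge.length[match(seq_len(4), tr$edge[, 2])],
                       tr$tip.label)
  expect_equal(tip_edge[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3")
})

test_that("neighbor joining is invariant to label order and never returns negative branches", {
  set.seed(6)
  tr0 <- ape::rtree(7)
  D <- ape::cophenetic.phylo(tr0)
  perm <- sample(rownames(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  # noisy matrix: clamping keeps branches non-negative
  Dn <- D + matrix(runif(49, 0, 0.05), 7, 7)
  Dn <- (Dn + t(Dn)) / 2; diag(Dn) <- 0
  expect_true(all(neighbor_joining(Dn)$edge.length >= 0))
})

test_that("bootstrap support is 100 for duplicated loci and deterministic", {
  g <- toy_genotypes(n_per_pop = 4, n_loci = 1)
  # add two more divergent populations and duplicate the single locus 6x
  a <- rbind(g$a1, matrix(3L, 4, 1), matrix(4L, 4, 1))
  gt <- genotype_table(c(g$individual, sprintf("c%d", 1:4), sprintf("d%d", 1:4)),
                       c(g$population, rep("C", 4), rep("D", 4)),
                       a[, rep(1, 6)], a[, rep(1, 6)], sprintf("L%d", 1:6))
  bs <- bootstrap_support(gt, n_reps = 50, seed = 7)
  supp <- suppressWarnings(as.numeric(bs$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp == 100))
  bs2 <- bootstrap_support(gt, n_reps = 50, seed = 7)
  expect_identical(ape::write.tree(bs), ape::write.tree(bs2))
  # supports bounded
  tr <- simulate_tree(5, seed = 8)
  g5 <- simulate_genotypes(tr, synthetic_config(n_populations = 5,
                                                n_individuals_per_pop = 8),
                           seed = 9)
  bs3 <- bootstrap_support(g5, n_reps = 30, seed = 10)
  s3 <- suppressWarnings(as.numeric(bs3$node.label))
  expect_true(all(s3[!is.na(s3)] >= 0 & s3[!is.na(s3)] <= 100))
})

test_that("Weir-Cockerham FST hits its fixed points", {
  g <- toy_genotypes(n_per_pop = 6, n_loci = 3)   # clusters fixed for
  cl <- setNames(g$population, g$individual)      # different alleles
  expect_equal(mean_fst(g, cl, n_perm = 0)$theta, 1)
  # identical frequency clusters: theta near 0
  set.seed(11)
  a1 <- matrix(sample(1:4, 40 * 3, TRUE), ncol = 3)
  a2 <- matrix(sample(1:4, 40 * 3, TRUE), ncol = 3)
  g2 <- genotype_table(sprintf("i%02d", 1:40), rep(c("A", "B"), each = 20),
                       a1, a2, c("L1", "L2", "L3"))
  th <- mean_fst(g2, setNames(g2$population, g2$individual), n_perm = 99,
                 seed = 12)
  expect_lt(abs(th$theta), 0.05)
  expect_gt(th$p_value, 0.05)
})

test_that("FST matches a direct variance-component oracle on a 2-allele table", {
  # explicit small table, theta recomputed from the WC84 component formulas
  # coded independently (loop form) in the test
  a1 <- matrix(c(1L, 1L, 1L, 2L, 1L, 2L, 2L, 2L, 2L, 2L), ncol = 1)
  a2 <- matrix(c(1L, 1L, 2L, 2L, 1L, 2L, 2L, 1L, 2L, 2L), ncol = 1)
  g <- genotype_table(sprintf("i%d", 1:10), rep(c("A", "B"), each = 5),
                      a1, a2, "L1")
  oracle <- local({
    r <- 2; n_i <- c(5, 5)
    acc_a <- 0; acc_all <- 0
    for (al in 1:2) {
      p_i <- h_i <- numeric(2)
      for (k in 1:2) {
        rows <- which(g$population == c("A", "B")[k])
        alleles <- c(a1[rows], a2[rows])
        p_i[k] <- mean(alleles == al)
        h_i[k] <- mean((a1[rows] == al) != (a2[rows] == al))
      }
      nbar <- mean(n_i)
      nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a_ <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                   hbar / 4) / (nbar - 1))
      b_ <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                   (2 * nbar - 1) / (4 * nbar) * hbar)
      c_ <- hbar / 2
      acc_a <- acc_a + a_; acc_all <- acc_all + a_ + b_ + c_
    }
    acc_a / acc_all
  })
  got <- mean_fst(g, setNames(g$population, g$individual), n_perm = 0)$theta
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("FST is invariant to allele relabelling and individual order", {
  set.seed(13)
  tr <- simulate_tree(3, seed = 13)
  g <- simulate_genotypes(tr, synthetic_config(n_populations = 3,
                                               n_individuals_per_pop = 8,
                                               missing_fraction = 0),
                          seed = 14)
  cl <- setNames(g$population, g$individual)
  base <- mean_fst(g, cl, n_perm = 0)$theta
  # relabel alleles at every locus by an arbitrary bijection
  relab <- function(m) (17L - m)
  g2 <- genotype_table(g$individual, g$population, relab(g$a1), relab(g$a2),
                       g$loci)
  expect_equal(mean_fst(g2, cl, n_perm = 0)$theta, base, tolerance = 1e-12)
  perm <- sample(length(g$individual))
  g3 <- genotype_table(g$individual[perm], g$population[perm],
                       g$a1[perm, ], g$a2[perm, ], g$loci)
  expect_equal(mean_fst(g3, cl, n_perm = 0)$theta, base, tolerance = 1e-12)
  singleton_map <- setNames(c("X", rep(c("A", "B"),
                                       length.out = length(g$individual) - 1)),
                            g$individual)
  expect_warning(mean_fst(g, singleton_map, n_perm = 0), "< 2 individuals")
})

test_that("midpoint rooting splits the longest tip-to-tip path in half", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  un <- ape::unroot(tr)
  rooted <- midpoint_root(un)
  expect_true(ape::is.rooted(rooted))
  # path lengths preserved
  expect_equal(ape::cophenetic.phylo(rooted)[c("A", "B", "C", "D"),
                                             c("A", "B", "C", "D")],
               ape::cophenetic.phylo(un)[c("A", "B", "C", "D"),
                                         c("A", "B", "C", "D")],
               tolerance = 1e-12)
  # brute-force: deepest tip depth equals half the matrix diameter
  depths <- ape::node.depth.edgelength(rooted)[seq_len(4)]
  expect_equal(max(depths), max(ape::cophenetic.phylo(un)) / 2,
               tolerance = 1e-12)
  # random trees
  set.seed(15)
  for (i in 1:10) {
    t0 <- ape::unroot(ape::rtree(6))
    r0 <- midpoint_root(t0)
    expect_equal(max(ape::node.depth.edgelength(r0)[1:6]),
                 max(ape::cophenetic.phylo(t0)) / 2, tolerance = 1e-9)
  }
})
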