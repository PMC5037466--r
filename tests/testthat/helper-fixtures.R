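# Small fixtures built in code, shared across test files.

# call_series from explicit onset vectors, e.g. toy_series(A = c(0, 1000))
toy_series <- function(..., duration_ms = NULL, call_duration_ms = 100) {
  onsets <- list(...)
  events <- do.call(rbind, lapply(names(onsets), function(id)
    data.frame(caller_id = id, onset_ms = onsets[[id]],
               duration_ms = call_duration_ms, stringsAsFactors = FALSE)))
  events <- events[order(events$onset_ms), , drop = FALSE]
  if (is.null(duration_ms)) duration_ms <- max(events$onset_ms) + 1
  structure(list(events = events, params = list(), duration_ms = duration_ms),
            class = "call_series")
}

# tiny two-population genotype table: pop A fixed-ish for allele 1,
# pop B for allele 2, at each of `n_loci` loci
toy_genotypes <- function(n_per_pop = 4, n_loci = 3, alleles_a = 1L,
                          alleles_b = 2L) {
  n <- 2 * n_per_pop
  a <- matrix(rep(c(rep(alleles_a, n_per_pop), rep(alleles_b, n_per_pop)),
                  n_loci), ncol = n_loci)
  genotype_table(sprintf("i%02d", seq_len(n)),
                 rep(c("A", "B"), each = n_per_pop),
                 a, a, sprintf("L%d", seq_len(n_loci)))
}

# preference curve data frame from separation -> index pairs
toy_curve <- function(indices) {
  data.frame(separation_ms = as.numeric(names(indices)),
             index = as.numeric(indices))
}

# choice_trials for one population from a per-trial probability function
toy_trials <- function(p_fun, separations, n_females = 10, n_trials = 4,
                       seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    grid <- expand.grid(trial = seq_len(n_trials),
                        separation_ms = separations,
                        female_id = sprintf("F%02d", seq_len(n_females)),
                        stringsAsFactors = FALSE)
    grid$chose_leader <- runif(nrow(grid)) < p_fun(grid$separation_ms)
    grid$population <- "P01"
    choice_trials(grid)
  })
}

# all permutations of 1:n (n small), as a list of integer vectors
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}
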