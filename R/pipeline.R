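## End-to-end pipeline: simulate (or ingest) a study, estimate per-population
## m and f, build the NJ population tree from genotypes, run the raw and
## phylogenetically corrected correlation analyses, and assemble a report.

#' Count populations where m is shorter than f
#'
#' @param timing a population timing data frame with `m_ms` and `f_ms`.
#' @return list with `count_less` (strict m < f), `n`, and `n_ties`.
#' @export
count_m_less_than_f <- function(timing) {
  if (!nrow(timing)) stop_invalid("timing table is empty")
  list(count_less = sum(timing$m_ms < timing$f_ms),
       n = nrow(timing),
       n_ties = sum(timing$m_ms == timing$f_ms))
}

#' Cluster-level mean timing parameters
#'
#' Unweighted means of m, f and syllable number per genetic cluster.
#'
#' @param timing population timing data frame (needs `population`, `m_ms`,
#'   `f_ms`, optionally `syl`).
#' @param cluster_map named vector mapping population -> cluster id.
#' @return data frame with one row per cluster.
#' @export
cluster_level_means <- function(timing, cluster_map) {
  if (!all(timing$population %in% names(cluster_map)))
    stop_invalid("unmapped population(s): ",
                 paste(setdiff(timing$population, names(cluster_map)),
                       collapse = ", "))
  cl <- as.character(cluster_map[timing$population])
  out <- do.call(rbind, lapply(unique(cl), function(g) {
    rows <- timing[cl == g, , drop = FALSE]
    data.frame(cluster = g, m_ms = mean(rows$m_ms), f_ms = mean(rows$f_ms),
               syl = if ("syl" %in% names(rows)) mean(rows$syl) else NA_real_,
               n_populations = nrow(rows), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Derive a k-cluster partition of the tips from the tree itself (average
# linkage on path distances). Stands in for externally supplied cluster
# assignments in synthetic mode.
tree_clusters <- function(tree, k) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  setNames(paste0("C", cl), names(cl))
}

#' Estimate population timing table from playback records and trials
#'
#' Per population: m as the mean over males of each male's mean 3 shortest
#' delays, and f as the largest separation whose preference index stays at
#' or above half the curve's maximum.
#'
#' @param playback list of [male_playback_record()].
#' @param trials a [choice_trials()] data frame (all populations).
#' @param traits optional trait table supplying `syl` per population.
#' @param contiguous passed to [estimate_f()].
#' @return a `population_timing` data frame, one row per population.
#' @export
estimate_timing_table <- function(playback, trials, traits = NULL,
                                  contiguous = FALSE) {
  pops <- unique(vapply(playback, `[[`, "", "population"))
  rows <- lapply(pops, function(pop) {
    recs <- Filter(function(r) r$population == pop, playback)
    m <- estimate_population_m(recs)
    tr <- trials[trials$population == pop, , drop = FALSE]
    curve <- preference_curve(tr)
    f <- estimate_f(curve, contiguous = contiguous)
    syl <- if (!is.null(traits)) traits$syl[match(pop, traits$population)]
           else NA_real_
    assemble_population_timing(pop, m, f, syl, n_males = length(recs),
                               n_females = length(unique(tr$female_id)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("population_timing", "data.frame")
  out
}

#' Default pipeline configuration
#'
#' The synthetic-study defaults of [synthetic_config()] plus pipeline
#' switches: `n_bootstrap` locus-bootstrap replicates for node support,
#' `n_clusters` genetic clusters for the cluster-level analysis,
#' `short_call_max_syl` the upper syllable bound of the short-call subset
#' (populations with mean syllable number in \[1.0, 2.1\]),
#' `tree_source` (`"nj"`: estimate from genotypes; `"true"`: use the
#' generating tree), and `fst_permutations`.
#'
#' @return a named list.
#' @export
default_pipeline_config <- function() {
  c(unclass(synthetic_config()),
    list(n_bootstrap = 200, n_clusters = 7,
         short_call_min_syl = 1.0, short_call_max_syl = 2.1,
         tree_source = "nj", fst_permutations = 99,
         contiguous_f = FALSE, one_sided = FALSE))
}

#' Read a pipeline configuration file
#'
#' YAML key/value file; keys are the fields of
#' [default_pipeline_config()], unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return the merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop_invalid("unknown config key(s): ",
                                paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

pic_mf <- function(tree, timing, one_sided = FALSE) {
  m <- setNames(timing$m_ms, timing$population)
  f <- setNames(timing$f_ms, timing$population)
  cs_f <- independent_contrasts(tree, f)
  cs_m <- independent_contrasts(tree, m)
  pairs <- positivize(cs_f, cs_m)     # x = f contrasts, y = m contrasts
  list(pairs = pairs,
       correlation = pic_correlation(pairs, one_sided = one_sided),
       rma = rma_regression(pairs$x, pairs$y, through_origin = TRUE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a synthetic study, estimates per-population m and f from the
#' simulated playback and choice-trial records, builds the NJ population
#' tree from the simulated genotypes (with midpoint rooting for the
#' contrasts), and computes: raw OLS/Spearman m-f association, the
#' short-call subset reanalysis with stepwise selection of f vs syllable
#' number, population-level and cluster-level independent-contrast
#' correlations, and the mean between-cluster FST.
#'
#' @param config a configuration list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param seed top-level seed; fans out to stages via [derive_seed()].
#' @param out_dir optional directory to write report files
#'   (`report.json`, `summary.txt`, `timing.csv`, `tree.nwk`,
#'   `contrasts.csv`, `genotypes.gen`).
#' @return an `analysis_report` list.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  full <- default_pipeline_config()
  full[names(config)] <- config
  config <- full
  syn_cfg <- do.call(synthetic_config,
                     c(full[intersect(names(full),
                                      names(formals(synthetic_config)))]))
  study <- simulate_study(syn_cfg, seed = seed)

  timing <- estimate_timing_table(study$playback, study$trials, study$traits,
                                  contiguous = isTRUE(config$contiguous_f))

  # population tree
  genos <- filter_missing(study$genotypes, 0.20)
  freqs <- allele_frequencies(genos)
  D <- build_distance_matrix(freqs)
  nj_tree <- if (config$n_bootstrap > 0)
    bootstrap_support(genos, config$n_bootstrap,
                      seed = derive_seed(seed, 20))
  else neighbor_joining(D)
  analysis_tree <- if (identical(config$tree_source, "true")) study$tree
                   else midpoint_root(nj_tree)

  # raw-trait association (all populations)
  ols_all <- ols_regression(timing$f_ms, timing$m_ms)
  rho_all <- rank_correlation(timing$m_ms, timing$f_ms)
  rho_m_syl <- rank_correlation(timing$m_ms, timing$syl)
  mf <- count_m_less_than_f(timing)

  # short-call subset: populations with mean syllable number in the band
  short <- timing[timing$syl >= config$short_call_min_syl &
                    timing$syl <= config$short_call_max_syl, , drop = FALSE]
  # f is grid-valued, so a small subset can be degenerate (zero variance)
  short_res <- NULL
  if (nrow(short) >= 4 && var(short$f_ms) > 0 && var(short$syl) > 0) {
    short_res <- list(
      ols = ols_regression(short$f_ms, short$m_ms),
      rho = rank_correlation(short$m_ms, short$f_ms),
      stepwise = stepwise_regression(short$m_ms,
                                     data.frame(f_ms = short$f_ms,
                                                syl = short$syl)))
  }

  # phylogenetically corrected association
  pic_pop <- pic_mf(analysis_tree, timing,
                    one_sided = isTRUE(config$one_sided))

  # cluster-level analysis
  cluster_map <- tree_clusters(study$tree, config$n_clusters)
  cl_timing <- cluster_level_means(timing, cluster_map)
  ind_clusters <- setNames(cluster_map[genos$population], genos$individual)
  fst <- mean_fst(genos, ind_clusters, n_perm = config$fst_permutations,
                  seed = derive_seed(seed, 21))
  cl_tree_d <- stats::as.dist(ape::cophenetic.phylo(study$tree))
  cl_D <- matrix(0, nrow(cl_timing), nrow(cl_timing),
                 dimnames = list(cl_timing$cluster, cl_timing$cluster))
  cm <- as.matrix(cl_tree_d)
  for (i in seq_len(nrow(cl_timing) - 1)) for (j in (i + 1):nrow(cl_timing)) {
    gi <- names(cluster_map)[cluster_map == cl_timing$cluster[i]]
    gj <- names(cluster_map)[cluster_map == cl_timing$cluster[j]]
    cl_D[i, j] <- cl_D[j, i] <- mean(cm[gi, gj])
  }
  pic_cl <- if (nrow(cl_timing) >= 4) {
    cl_tree <- midpoint_root(neighbor_joining(cl_D))
    pic_mf(cl_tree, data.frame(population = cl_timing$cluster,
                               m_ms = cl_timing$m_ms, f_ms = cl_timing$f_ms),
           one_sided = isTRUE(config$one_sided))
  } else NULL

  report <- structure(list(
    timing = timing,
    m_less_than_f = mf,
    raw = list(ols_m_on_f = ols_all, rho_m_f = rho_all,
               rho_m_syl = rho_m_syl),
    short_call = short_res,
    tree = analysis_tree,
    nj_tree = nj_tree,
    pic_population = pic_pop,
    clusters = list(map = cluster_map, timing = cl_timing, fst = fst,
                    pic = pic_cl),
    provenance = list(seed = seed, config = config,
                      package_version = as.character(
                        utils::packageVersion("chorusem")))),
    class = "analysis_report")

  if (!is.null(out_dir)) write_report(report, study, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (", nrow(x$timing), " populations, seed ",
      x$provenance$seed, ")\n", sep = "")
  cat(sprintf("  m < f in %d of %d populations\n",
              x$m_less_than_f$count_less, x$m_less_than_f$n))
  cat(sprintf("  raw OLS: m = %.3g + %.3g f (t = %.2f, p = %.3g); Spearman rho = %.3f\n",
              x$raw$ols_m_on_f$intercept, x$raw$ols_m_on_f$slope,
              x$raw$ols_m_on_f$t, x$raw$ols_m_on_f$p_value,
              x$raw$rho_m_f$rho))
  pc <- x$pic_population$correlation
  cat(sprintf("  PIC (populations): r = %.3f, t = %.2f, df = %g, p = %.3g\n",
              pc$correlation, pc$t, pc$df, pc$p_value))
  if (!is.null(x$clusters$pic)) {
    cc <- x$clusters$pic$correlation
    cat(sprintf("  PIC (%d clusters): r = %.3f, p = %.3g; mean FST = %.3f (p = %.3g)\n",
                nrow(x$clusters$timing), cc$correlation, cc$p_value,
                x$clusters$fst$theta, x$clusters$fst$p_value))
  }
  invisible(x)
}

write_report <- function(report, study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$timing, file.path(out_dir, "timing.csv"),
            row.names = FALSE)
  ape::write.tree(report$nj_tree, file.path(out_dir, "tree.nwk"))
  write_genepop(study$genotypes, file.path(out_dir, "genotypes.gen"))
  pp <- report$pic_population$pairs
  write.csv(data.frame(node_id = pp$node_ids, contrast_f = pp$x,
                       contrast_m = pp$y),
            file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  flat <- function(rr) if (is.null(rr)) NULL else
    rr[c("method", "slope", "intercept", "correlation", "t", "df",
         "p_value", "n")]
  json <- list(
    seed = report$provenance$seed,
    package_version = report$provenance$package_version,
    m_less_than_f = report$m_less_than_f,
    raw = list(ols_m_on_f = flat(report$raw$ols_m_on_f),
               rho_m_f = report$raw$rho_m_f,
               rho_m_syl = report$raw$rho_m_syl),
    pic_population = flat(report$pic_population$correlation),
    pic_clusters = if (!is.null(report$clusters$pic))
      flat(report$clusters$pic$correlation) else NULL,
    mean_fst = report$clusters$fst,
    config = report$provenance$config)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Write / read trait and record CSVs
#'
#' Plain-CSV serialisation of the generator outputs, matching the schemas
#' the estimators read back.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study_csvs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  pb <- do.call(rbind, lapply(study$playback, function(r)
    data.frame(male_id = r$male_id, population = r$population,
               stimulus_index = seq_along(r$delays_ms),
               delay_ms = r$delays_ms)))
  write.csv(pb, file.path(dir, "playback.csv"), row.names = FALSE)
  write.csv(as.data.frame(study$trials), file.path(dir, "trials.csv"),
            row.names = FALSE)
  ape::write.tree(study$tree, file.path(dir, "true_tree.nwk"))
  write_genepop(study$genotypes, file.path(dir, "genotypes.gen"))
  invisible(dir)
}

#' @rdname write_study_csvs
#' @param path a playback CSV written by [write_study_csvs()].
#' @return `read_playback_csv`: a list of [male_playback_record()].
#' @export
read_playback_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$male_id), function(d)
    male_playback_record(d$male_id[1], d$population[1],
                         d$delay_ms[order(d$stimulus_index)]))
}

#' @rdname write_study_csvs
#' @return `read_trials_csv`: a [choice_trials()] data frame.
#' @export
read_trials_csv <- function(path) {
  choice_trials(read.csv(path, stringsAsFactors = FALSE))
}
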