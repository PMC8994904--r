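# Scenario runner: one self-contained simulated experiment = genome +
# trait + founder + epistatic network + a trajectory of generations with
# the per-generation variance decomposition.

#' Define a simulation scenario
#'
#' Defaults reproduce the reference study conditions: 400 genes on 10
#' chromosomes of 200 cM (one gene/5 cM), homozygote genotypic extremes
#' 160/30 g per plant with phenotypic bounds 180/10, positive dominance
#' averaging 0.6, broad-sense heritability 0.2, admixture epistasis on 30%
#' of the genes with V(I)/(V(A)+V(D)) = 1, and 10 generations of selfing
#' or random mating at N = 5000.
#'
#' @param n_chrom,chrom_len,genes_per_chrom genome layout.
#' @param avg_freq average founder allele frequency (0.5, 0.3 or 0.7 in
#'   the named populations).
#' @param ld_level `"high"`, `"intermediate"` or `"low"`.
#' @param epistasis_type a concrete type, `"admixture"` or `"none"`.
#' @param pct_interacting fraction of interacting genes.
#' @param ratio V(I)/(V(A)+V(D)) per pair.
#' @param scheme `"selfing"` or `"random"`.
#' @param generations number of generations to advance.
#' @param N individuals per generation.
#' @param H2 broad-sense heritability.
#' @param g_min,g_max,p_min,p_max trait extremes.
#' @param avg_dominance average degree of dominance.
#' @param seed default RNG seed for [run_scenario()].
#' @param name optional label.
#' @return object of class `scenario`.
#' @export
scenario <- function(n_chrom = 10, chrom_len = 200, genes_per_chrom = 40,
                     avg_freq = 0.5, ld_level = "high",
                     epistasis_type = "admixture", pct_interacting = 0.3,
                     ratio = 1, scheme = c("selfing", "random"),
                     generations = 10, N = 5000, H2 = 0.2,
                     g_min = 30, g_max = 160, p_min = 10, p_max = 180,
                     avg_dominance = 0.6, seed = 1, name = NULL) {
  scheme <- match.arg(scheme)
  sc <- list(n_chrom = n_chrom, chrom_len = chrom_len,
             genes_per_chrom = genes_per_chrom, avg_freq = avg_freq,
             ld_level = ld_level, epistasis_type = epistasis_type,
             pct_interacting = pct_interacting, ratio = ratio,
             scheme = scheme, generations = generations, N = N, H2 = H2,
             g_min = g_min, g_max = g_max, p_min = p_min, p_max = p_max,
             avg_dominance = avg_dominance, seed = seed,
             name = name %||% sprintf("%s-LD/%.1f %s %s%% %s",
                                      ld_level, avg_freq, epistasis_type,
                                      round(100 * pct_interacting), scheme))
  class(sc) <- "scenario"
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario <- function(x, ...) {
  cat("scenario:", x$name, "\n ",
      x$n_chrom, "x", x$genes_per_chrom, "genes,", x$chrom_len, "cM;",
      "N =", x$N, ";", x$generations, "generations of", x$scheme, "\n")
  invisible(x)
}

#' Run one scenario
#'
#' Builds the genome and trait, samples the founder population and the
#' epistatic network, then advances the requested generations, recomputing
#' the parametric effects and the sample variance components at every
#' evaluated generation.  Fully deterministic given the seed.
#'
#' @param sc a `scenario`.
#' @param seed RNG seed (defaults to the scenario's).
#' @param eval_generations generations at which to decompose the variance
#'   (default all, 0..generations).  Restricting this (e.g. `c(0, 10)`)
#'   skips the decomposition — not the simulation — at the other
#'   generations.
#' @return object of class `trajectory_result`: list with `components`
#'   (data frame, one row per evaluated generation), `scenario`, `seed`
#'   and `setup` (the `pair_setup` used).
#' @export
run_scenario <- function(sc, seed = sc$seed, eval_generations = NULL) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(seed)
  if (is.null(eval_generations)) eval_generations <- 0:sc$generations
  map <- build_gene_map(sc$n_chrom, sc$chrom_len, sc$genes_per_chrom)
  tspec <- trait_spec(sc$g_min, sc$g_max, sc$p_min, sc$p_max,
                      sc$avg_dominance, sc$H2, sc$epistasis_type,
                      sc$pct_interacting, sc$ratio)
  eff <- assign_gene_effects(map, tspec)
  fs <- founder_spec(map, sc$N, sc$avg_freq, sc$ld_level)
  net <- if (sc$epistasis_type == "none" || sc$pct_interacting == 0)
    assign_epistatic_network(map$n_genes, 0)
  else assign_epistatic_network(map$n_genes, sc$pct_interacting,
                                sc$epistasis_type)
  setup <- pair_setup(map, eff, fs$p1, fs$p2, net, sc$ratio)
  pop <- found_ld_population(fs)
  rows <- vector("list", length(eval_generations))
  ri <- 0
  for (g in 0:sc$generations) {
    if (g %in% eval_generations) {
      pe <- parametric_effects(setup, sc$scheme, g)
      vals <- genetic_values(pop, pe)
      vc <- variance_components_from_sample(vals)
      ri <- ri + 1
      rows[[ri]] <- cbind(data.frame(generation = g, F = pe$F,
                                     M_F = pe$M_F), vc)
    }
    if (g < sc$generations)
      pop <- if (sc$scheme == "selfing") advance_selfing(pop, 1)
             else advance_random_mating(pop, 1)
  }
  structure(list(components = do.call(rbind, rows[seq_len(ri)]),
                 scenario = sc, seed = seed, setup = setup),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("trajectory_result:", x$scenario$name, "(seed", x$seed, ")\n")
  print(x$components[, c("generation", "F", "sigma2_A", "sigma2_D",
                         "sigma2_AA", "sigma2_G", "epistatic_fraction")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a variance-component trajectory
#'
#' @param x a `trajectory_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trajectory_result <- function(x, ...) {
  cmp <- x$components
  vars <- paste0("sigma2_", COMPONENT_NAMES)
  graphics::matplot(cmp$generation, as.matrix(cmp[, vars]), type = "b",
                    pch = 1:6, lty = 1, xlab = "generation",
                    ylab = "variance", main = x$scenario$name, ...)
  graphics::legend("topleft", legend = vars, col = 1:6, pch = 1:6, cex = 0.8)
  invisible(x)
}

#' Run replicates of a scenario and average the components
#'
#' @param sc a `scenario`.
#' @param reps number of replicate seeds.
#' @param base_seed replicate k uses seed `base_seed + k`.
#' @param eval_generations passed to [run_scenario()].
#' @return list with `mean` (replicate-mean components data frame,
#'   epistatic fraction recomputed from the mean variances), `sd`
#'   (replicate SD of each column) and `runs`.
#' @export
run_replicates <- function(sc, reps = 10, base_seed = sc$seed,
                           eval_generations = NULL) {
  runs <- lapply(seq_len(reps), function(k)
    run_scenario(sc, seed = base_seed + k,
                 eval_generations = eval_generations)$components)
  num <- vapply(runs, function(df) as.matrix(df), as.matrix(runs[[1]]))
  mean_df <- as.data.frame(apply(num, c(1, 2), mean))
  sd_df <- as.data.frame(apply(num, c(1, 2), stats::sd))
  mean_df$epistatic_fraction <-
    (mean_df$sigma2_AA + mean_df$sigma2_AD + mean_df$sigma2_DA +
       mean_df$sigma2_DD) / mean_df$sigma2_G
  list(mean = mean_df, sd = sd_df, runs = runs)
}

#' Percent changes of the variance components along a trajectory
#'
#' 100 (X_n - X_0) / X_0 for every variance component and the genotypic
#' variance between the first and last evaluated generations, plus the
#' per-generation epistatic fraction
#' (sigma2_AA + sigma2_AD + sigma2_DA + sigma2_DD) / sigma2_G.
#'
#' @param tr a `trajectory_result`, or its `components` data frame.
#' @return list with `pct_change` (named vector; NA where the generation-0
#'   component is 0) and `epistatic_fraction` (per generation).
#' @export
summarize_percent_changes <- function(tr) {
  cmp <- if (inherits(tr, "trajectory_result")) tr$components else tr
  if (nrow(cmp) < 2) stop("need at least two evaluated generations")
  first <- cmp[1, ]; last <- cmp[nrow(cmp), ]
  vars <- c(paste0("sigma2_", COMPONENT_NAMES), "sigma2_G")
  pct <- vapply(vars, function(v) {
    x0 <- first[[v]]
    if (is.na(x0) || x0 == 0) NA_real_ else 100 * (last[[v]] - x0) / x0
  }, numeric(1))
  list(pct_change = pct,
       epistatic_fraction = stats::setNames(cmp$epistatic_fraction,
                                            cmp$generation))
}

#' The named scenarios of the simulated experiments
#'
#' Enumerates the experimental grid: four founder populations at one
#' gene/5 cM (high-LD/0.5, low-LD/0.5, intermediate-LD/0.3 "not improved",
#' intermediate-LD/0.7 "improved"), each crossed with every epistasis
#' configuration (the seven types plus admixture, at 30% and 100%
#' interacting genes, ratio 1) and both generation schemes (10 generations
#' of selfing or random crosses, N = 5000), plus a high-LD/0.5 population
#' at one gene/cM for LD characterization.
#'
#' @return named list of `scenario` objects.
#' @export
paper_scenarios <- function() {
  founders <- list(
    high_0.5 = list(ld_level = "high", avg_freq = 0.5),
    low_0.5 = list(ld_level = "low", avg_freq = 0.5),
    intermediate_0.3 = list(ld_level = "intermediate", avg_freq = 0.3),
    intermediate_0.7 = list(ld_level = "intermediate", avg_freq = 0.7))
  out <- list()
  for (fn in names(founders)) {
    f <- founders[[fn]]
    for (ty in c(epistasis_types(), "admixture")) {
      for (pct in c(0.3, 1.0)) {
        for (sch in c("random", "selfing")) {
          nm <- paste(fn, ty, paste0(round(100 * pct), "pct"), sch,
                      sep = "_")
          out[[nm]] <- scenario(avg_freq = f$avg_freq,
                                ld_level = f$ld_level, epistasis_type = ty,
                                pct_interacting = pct, scheme = sch,
                                name = nm)
        }
      }
    }
  }
  out$high_0.5_dense_ld <- scenario(chrom_len = 50, ld_level = "high",
                                    avg_freq = 0.5, epistasis_type = "none",
                                    pct_interacting = 0,
                                    name = "high_0.5_dense_ld")
  out
}

#' Write a trajectory to CSV
#'
#' @param tr a `trajectory_result`.
#' @param path output file.
#' @return the components data frame, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  df <- cbind(scenario = tr$scenario$name, seed = tr$seed, tr$components)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(tr$components)
}

#' Build a scenario from a YAML or key-value configuration file
#'
#' Recognized keys match the arguments of [scenario()].  Note that the
#' population-size key must be written quoted (`"N": 5000`) because plain
#' `N` is a YAML boolean literal.
#'
#' @param path configuration file.
#' @return a `scenario`.
#' @export
scenario_from_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scenario))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  do.call(scenario, cfg)
}
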