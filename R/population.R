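# Individual-based forward simulation.  A population stores the two
# haplotype matrices (individuals x genes, alleles 0/1 with 1 = the
# trait-increasing allele), the gene map and the parental-frequency
# provenance needed for the parametric theory.

# per-locus probability that the gamete's source haplotype switches just
# before the locus: 0.5 at chromosome starts (uniform starting haplotype
# and independent assortment across chromosomes), Haldane r of the
# adjacent spacing within a chromosome
map_switch_probs <- function(map) {
  d <- c(Inf, diff(map$pos_cM))
  d[c(TRUE, diff(map$chrom) != 0)] <- Inf
  recombination_fraction(d)
}

new_population <- function(hap1, hap2, map, F = 0, generation = 0,
                           p1 = NULL, p2 = NULL) {
  structure(list(hap1 = hap1, hap2 = hap2, map = map, F = F,
                 generation = generation, p1 = p1, p2 = p2,
                 switch_prob = map_switch_probs(map)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("population:", nrow(x$hap1), "individuals x", ncol(x$hap1),
      "genes; generation", x$generation, "; expected F =",
      round(x$F, 5), "\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `population`.
#' @return integer count.
#' @export
pop_size <- function(pop) nrow(pop$hap1)

#' Observed allele frequencies of a population
#' @param pop a `population`.
#' @return numeric vector, one frequency (of the increasing allele) per gene.
#' @export
allele_freqs <- function(pop) (colMeans(pop$hap1) + colMeans(pop$hap2)) / 2

#' Genotype matrix (allele dosage 0/1/2)
#' @param pop a `population`.
#' @param path optional CSV file to write (individuals x genes).
#' @return integer matrix, invisibly when written to file.
#' @export
genotype_matrix <- function(pop, path = NULL) {
  g <- pop$hap1 + pop$hap2
  if (is.null(path)) return(g)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(g)
}

#' Observed haplotype frequencies for a pair of genes
#'
#' Counts the four haplotypes AB, Ab, aB, ab over the 2N chromosomes of
#' the population — the empirical counterpart of the parametric
#' gametic-pool frequencies.
#'
#' @param pop a `population`.
#' @param i,j gene indices.
#' @return named numeric(4).
#' @export
observed_hap_freqs <- function(pop, i, j) {
  h <- rbind(cbind(pop$hap1[, i], pop$hap1[, j]),
             cbind(pop$hap2[, i], pop$hap2[, j]))
  idx <- factor(2 * (1 - h[, 1]) + (1 - h[, 2]), levels = 0:3)
  stats::setNames(as.vector(table(idx)) / nrow(h), HAP_NAMES)
}

#' Sample a linkage-equilibrium population
#'
#' Every allele of every haplotype is drawn independently (linkage
#' equilibrium and Hardy-Weinberg proportions) with the given per-locus
#' frequencies.
#'
#' @param freqs per-gene frequency of the increasing allele.
#' @param N number of individuals (>= 1).
#' @param map a `gene_map` with `length(freqs)` genes.
#' @return a `population`.
#' @export
sample_le_population <- function(freqs, N, map) {
  if (N < 1) stop("N must be at least 1")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must be in [0, 1]")
  L <- map$n_genes
  if (length(freqs) != L) stop("freqs must have one entry per gene")
  draw <- function() matrix(stats::rbinom(N * L, 1L, rep(freqs, each = N)),
                            N, L)
  new_population(draw(), draw(), map)
}

#' Founder specification for an LD population
#'
#' The founder is made by crossing two linkage-equilibrium populations; its
#' LD comes from the difference in parental allele frequencies
#' (Delta proportional to (p_a1 - p_a2)(p_b1 - p_b2)).  The population is
#' characterized by its average allele frequency: per locus, the average
#' frequency is drawn uniformly on \[target - 0.05, target + 0.05\] and the
#' parental half-difference delta uniformly on \[0, dmax\], giving
#' p1 = avg + delta and p2 = avg - delta (population 1 always the
#' high-frequency parent, so every gene pair is in coupling phase and the
#' founder LD is positive).  The dispersion dmax sets the LD level:
#' 0.45 (high), 0.25 (intermediate), 0.10 (low).  Frequencies are clipped
#' to \[0.02, 0.98\].
#'
#' @param map a `gene_map`.
#' @param N founder population size.
#' @param avg_freq target average allele frequency (e.g. 0.5, 0.3, 0.7).
#' @param ld_level `"high"`, `"intermediate"` or `"low"` (ignored when
#'   `p1`/`p2` are given).
#' @param p1,p2 optional explicit per-locus parental frequency vectors.
#' @return object of class `founder_spec`: list with `p1`, `p2`, `N`, `map`.
#' @export
founder_spec <- function(map, N, avg_freq = 0.5,
                         ld_level = c("high", "intermediate", "low"),
                         p1 = NULL, p2 = NULL) {
  if (N < 2) stop("N must be at least 2")
  if (is.null(p1) != is.null(p2)) stop("give both p1 and p2 or neither")
  if (is.null(p1)) {
    ld_level <- match.arg(ld_level)
    dmax <- c(high = 0.45, intermediate = 0.25, low = 0.10)[[ld_level]]
    clip <- function(x) pmin(pmax(x, 0.02), 0.98)
    avg <- stats::runif(map$n_genes, avg_freq - 0.05, avg_freq + 0.05)
    delta <- stats::runif(map$n_genes, 0, dmax)
    p1 <- clip(avg + delta)
    p2 <- clip(avg - delta)
  } else {
    ld_level <- "custom"
    if (length(p1) != map$n_genes || length(p2) != map$n_genes)
      stop("parental frequency vectors must have one entry per gene")
  }
  structure(list(p1 = p1, p2 = p2, N = N, map = map, avg_freq = avg_freq,
                 ld_level = ld_level), class = "founder_spec")
}

# gametes from a batch of parents given as paired haplotype matrices
gamete_batch <- function(hap1, hap2, switch_prob) {
  cpp_gametes(hap1, hap2, switch_prob)
}

#' Meiosis: one gamete from one individual
#'
#' Builds a gamete chromosome by chromosome: the starting haplotype is
#' chosen at random per chromosome and crossovers occur between adjacent
#' genes with the Haldane recombination fraction of their spacing, so that
#' the pairwise recombination fraction between any two genes equals
#' `recombination_fraction` of their distance (Markovian recombination, no
#' interference).
#'
#' @param h1,h2 the individual's two haplotypes (0/1 vectors).
#' @param map the `gene_map`.
#' @return a 0/1 gamete vector.
#' @export
meiosis <- function(h1, h2, map) {
  as.vector(cpp_gametes(matrix(as.integer(h1), 1), matrix(as.integer(h2), 1),
                        map_switch_probs(map)))
}

#' Found an LD population by crossing two LE populations
#'
#' Samples the two parental linkage-equilibrium populations, crosses them
#' (each F1 individual receives one gamete from a random parent of each
#' population) and applies one generation of random crosses, yielding a
#' Hardy-Weinberg founder of unrelated individuals whose parametric
#' gametic-pool LD is Delta = \[(1-2r)/4\](p_a1 - p_a2)(p_b1 - p_b2).
#'
#' @param spec a `founder_spec`.
#' @return a `population` at generation 0 with `F = 0`.
#' @export
found_ld_population <- function(spec) {
  map <- spec$map; N <- spec$N
  pop1 <- sample_le_population(spec$p1, N, map)
  pop2 <- sample_le_population(spec$p2, N, map)
  sw <- pop1$switch_prob
  i1 <- sample.int(N, N, replace = TRUE)
  i2 <- sample.int(N, N, replace = TRUE)
  f1 <- new_population(
    gamete_batch(pop1$hap1[i1, , drop = FALSE], pop1$hap2[i1, , drop = FALSE], sw),
    gamete_batch(pop2$hap1[i2, , drop = FALSE], pop2$hap2[i2, , drop = FALSE], sw),
    map)
  founder <- advance_random_mating(f1, 1)
  founder$generation <- 0
  founder$p1 <- spec$p1
  founder$p2 <- spec$p2
  founder
}

#' Advance a population by random mating
#'
#' Each generation draws N offspring from random pairs of distinct
#' parents (no selfing, no selection): the expected gametic LD decays as
#' (1 - r)^n, allele frequencies are conserved in expectation and F
#' remains 0.
#'
#' @param pop a `population`.
#' @param n number of generations (>= 0).
#' @return the advanced `population`.
#' @export
advance_random_mating <- function(pop, n = 1) {
  N <- pop_size(pop)
  sw <- pop$switch_prob
  for (g in seq_len(n)) {
    mom <- sample.int(N, N, replace = TRUE)
    dad <- sample.int(N, N, replace = TRUE)
    while (any(clash <- dad == mom))
      dad[clash] <- sample.int(N, sum(clash), replace = TRUE)
    h1 <- gamete_batch(pop$hap1[mom, , drop = FALSE],
                       pop$hap2[mom, , drop = FALSE], sw)
    h2 <- gamete_batch(pop$hap1[dad, , drop = FALSE],
                       pop$hap2[dad, , drop = FALSE], sw)
    pop$hap1 <- h1; pop$hap2 <- h2
    pop$generation <- pop$generation + 1
  }
  pop
}

#' Advance a population by selfing
#'
#' Each individual leaves exactly one selfed offspring (two independent
#' gametes of the same parent), keeping N constant with no selection.  The
#' expected inbreeding coefficient after n generations from F = 0 is
#' 1 - (1/2)^n and the gametic-pool allele frequencies are unchanged.
#'
#' @param pop a `population`.
#' @param n number of selfing generations (>= 0).
#' @return the advanced `population`.
#' @export
advance_selfing <- function(pop, n = 1) {
  sw <- pop$switch_prob
  for (g in seq_len(n)) {
    h1 <- gamete_batch(pop$hap1, pop$hap2, sw)
    h2 <- gamete_batch(pop$hap1, pop$hap2, sw)
    pop$hap1 <- h1; pop$hap2 <- h2
    pop$generation <- pop$generation + 1
    pop$F <- 1 - (1 - pop$F) / 2
  }
  pop
}
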