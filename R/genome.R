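#' Build a gene map with equally spaced genes
#'
#' Lays out `genes_per_chrom` genes on each of `n_chrom` chromosomes of
#' length `chrom_len` centiMorgans.  Genes are equally spaced including the
#' chromosome ends, so the spacing is `chrom_len / (genes_per_chrom - 1)`
#' and the first gene of every chromosome sits at position 0.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_len chromosome length in cM (single value recycled, or one
#'   per chromosome).
#' @param genes_per_chrom genes per chromosome (>= 2).
#' @return An object of class `gene_map`: a list with `chrom` (integer
#'   chromosome index per gene), `pos_cM` (position per gene), `lengths_cM`
#'   and `n_genes`.
#' @examples
#' map <- build_gene_map(10, 200, 40)
#' map$n_genes          # 400
#' diff(map$pos_cM[1:2])  # 200/39 ~ 5.13 cM
#' @export
build_gene_map <- function(n_chrom, chrom_len, genes_per_chrom) {
  if (n_chrom < 1 || genes_per_chrom < 2 || any(chrom_len <= 0))
    stop("invalid genome configuration: need n_chrom >= 1, genes_per_chrom >= 2, chrom_len > 0")
  lengths <- rep_len(chrom_len, n_chrom)
  pos <- unlist(lapply(lengths, function(L) seq(0, L, length.out = genes_per_chrom)))
  map <- list(
    chrom = rep(seq_len(n_chrom), each = genes_per_chrom),
    pos_cM = pos,
    lengths_cM = lengths,
    n_genes = n_chrom * genes_per_chrom
  )
  class(map) <- "gene_map"
  map
}

#' @export
print.gene_map <- function(x, ...) {
  cat("gene_map:", x$n_genes, "genes on", length(x$lengths_cM),
      "chromosome(s) of", paste(unique(x$lengths_cM), collapse = "/"), "cM\n")
  invisible(x)
}

#' Map distance to recombination fraction (Haldane)
#'
#' Haldane's map function (no interference): r = (1 - exp(-2d/100))/2 for a
#' distance d in cM.  Genes on different chromosomes assort independently
#' (r = 0.5); pass `Inf` for that case.
#'
#' @param d map distance in cM (vectorized); `Inf` for different chromosomes.
#' @return recombination fraction in \[0, 0.5\].
#' @examples
#' recombination_fraction(0)    # 0
#' recombination_fraction(50)   # (1 - exp(-1))/2
#' recombination_fraction(Inf)  # 0.5
#' @export
recombination_fraction <- function(d) {
  if (any(d < 0)) stop("map distance must be nonnegative")
  r <- (1 - exp(-2 * d / 100)) / 2
  r[is.infinite(d)] <- 0.5
  r
}

#' Pairwise recombination fraction between two mapped genes
#'
#' @param map a `gene_map`.
#' @param i,j gene indices.
#' @return recombination fraction (0.5 across chromosomes).
#' @export
pair_recombination <- function(map, i, j) {
  same <- map$chrom[i] == map$chrom[j]
  d <- ifelse(same, abs(map$pos_cM[i] - map$pos_cM[j]), Inf)
  recombination_fraction(d)
}

#' Trait architecture specification
#'
#' Bundles the user-facing trait settings: the genotypic values of the two
#' extreme homozygotes (all loci increasing vs all decreasing), the
#' phenotypic bounds used to truncate simulated phenotypes, the average
#' degree of dominance d/a, and the broad-sense heritability.  Epistasis
#' settings (type or admixture, fraction of interacting genes, and the
#' ratio V(I)/(V(A)+V(D))) ride along.
#'
#' @param g_min,g_max genotypic values of the extreme homozygotes (trait units).
#' @param p_min,p_max phenotypic bounds; must enclose the genotypic bounds.
#' @param avg_dominance average degree of dominance d/a (positive direction).
#' @param H2 broad-sense heritability in (0, 1].
#' @param epistasis_type one of the seven type codes, `"admixture"` or `"none"`.
#' @param pct_interacting fraction of genes that interact, in \[0, 1\].
#' @param ratio V(I)/(V(A)+V(D)) for each interacting pair.
#' @return an object of class `trait_spec`.
#' @export
trait_spec <- function(g_min = 30, g_max = 160, p_min = 10, p_max = 180,
                       avg_dominance = 0.6, H2 = 0.2,
                       epistasis_type = "none", pct_interacting = 0,
                       ratio = 1) {
  if (g_max <= g_min) stop("g_max must exceed g_min")
  if (p_min > g_min || p_max < g_max) stop("phenotypic bounds must enclose genotypic bounds")
  if (H2 <= 0 || H2 > 1) stop("H2 must be in (0, 1]")
  if (pct_interacting < 0 || pct_interacting > 1) stop("pct_interacting must be in [0, 1]")
  structure(list(g_min = g_min, g_max = g_max, p_min = p_min, p_max = p_max,
                 avg_dominance = avg_dominance, H2 = H2,
                 epistasis_type = epistasis_type,
                 pct_interacting = pct_interacting, ratio = ratio),
            class = "trait_spec")
}

#' Assign per-gene additive and dominance effects
#'
#' Samples a positive `a` deviation per gene (uniform, then rescaled) so
#' that the genotypic values of the extreme homozygotes hit the configured
#' `g_min`/`g_max` exactly: with per-gene midpoint m, sum(m + a) = g_max and
#' sum(m - a) = g_min.  The degree of dominance d/a is sampled uniformly on
#' \[0, 2 * avg_dominance\] (positive dominance direction) and d = a * (d/a).
#' With `equal_a = TRUE` every gene gets the same a (the degenerate sampler).
#'
#' @param map a `gene_map`.
#' @param spec a `trait_spec`.
#' @param equal_a use identical a for all genes instead of sampling.
#' @return object of class `gene_effects`: data frame with columns `chrom`,
#'   `pos_cM`, `a`, `d`, `deg` (= d/a) and `m`, plus attribute `spec`.
#' @examples
#' set.seed(1)
#' eff <- assign_gene_effects(build_gene_map(10, 200, 40), trait_spec())
#' sum(eff$m + eff$a)  # 160
#' sum(eff$m - eff$a)  # 30
#' @export
assign_gene_effects <- function(map, spec, equal_a = FALSE) {
  n <- map$n_genes
  half_range <- (spec$g_max - spec$g_min) / 2
  a_raw <- if (equal_a) rep(1, n) else stats::runif(n, 0.5, 1.5)
  a <- a_raw * half_range / sum(a_raw)
  m <- rep((spec$g_max + spec$g_min) / 2 / n, n)
  deg <- if (spec$avg_dominance == 0) rep(0, n) else
    stats::runif(n, 0, 2 * spec$avg_dominance)
  eff <- data.frame(chrom = map$chrom, pos_cM = map$pos_cM,
                    a = a, d = a * deg, deg = deg, m = m)
  attr(eff, "spec") <- spec
  class(eff) <- c("gene_effects", "data.frame")
  eff
}

#' Environmental error variance from broad-sense heritability
#'
#' H2 = Var(G) / (Var(G) + Var(E)), hence Var(E) = Var(G) (1 - H2) / H2.
#'
#' @param genotypic_var genotypic variance (trait units squared).
#' @param H2 broad-sense heritability in (0, 1].
#' @return error variance.
#' @export
error_variance <- function(genotypic_var, H2) {
  if (H2 <= 0 || H2 > 1) stop("H2 must be in (0, 1]")
  genotypic_var * (1 - H2) / H2
}

#' Simulate phenotypes from genotypic values
#'
#' P = G + E with E ~ N(0, error_variance(Var(G), H2)).  Values outside the
#' phenotypic bounds are avoided by resampling the error term for the
#' offending individuals.
#'
#' @param G vector of genotypic values.
#' @param spec a `trait_spec` (supplies H2 and the phenotypic bounds).
#' @param max_iter resampling rounds before clipping the stragglers.
#' @return numeric vector of phenotypes.
#' @export
simulate_phenotypes <- function(G, spec, max_iter = 100) {
  s <- sqrt(error_variance(stats::var(G), spec$H2))
  P <- G + stats::rnorm(length(G), 0, s)
  for (it in seq_len(max_iter)) {
    bad <- which(P < spec$p_min | P > spec$p_max)
    if (!length(bad)) break
    P[bad] <- G[bad] + stats::rnorm(length(bad), 0, s)
  }
  pmin(pmax(P, spec$p_min), spec$p_max)
}

#' Export the gene map and effects as a table
#'
#' @param effects a `gene_effects` object.
#' @param path optional file; when supplied a tab-separated table
#'   (chromosome, position_cM, a, d) is written.
#' @return the data frame, invisibly when written to file.
#' @export
export_gene_map <- function(effects, path = NULL) {
  out <- data.frame(chromosome = effects$chrom, position_cM = effects$pos_cM,
                    a = effects$a, d = effects$d)
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
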