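# Per-generation parametric effects and per-individual genetic values.
#
# Genes outside the epistatic network contribute additive and dominance
# values through the single-locus inbred theory; each epistatic pair
# contributes all six components through its own Kempthorne effect set
# (computed once — the constrained solution depends only on the invariant
# allele frequencies).  Per generation the components are centered at the
# expectations taken over that generation's parametric two-locus
# distribution (selfing: the 10-state recursion; random mating:
# Hardy-Weinberg with geometrically decayed Delta), so every centered
# component has parametric expectation 0 and E(G) = M_F.

#' Set up the epistatic pairs of a simulated trait
#'
#' For every pair of the epistatic network: computes the recombination
#' fraction from the map, the founder gametic-pool haplotype frequencies
#' from the parental-population cross formula, builds the epistatic
#' genotypic-value grid (sampling I_22), and solves for the pair's
#' Kempthorne effect set.
#'
#' @param map a `gene_map`.
#' @param eff a `gene_effects` table.
#' @param p1,p2 per-gene parental allele frequencies of the founder cross.
#' @param network data frame from [assign_epistatic_network()].
#' @param ratio V(I)/(V(A)+V(D)) for every pair.
#' @return object of class `pair_setup`: list of per-pair contexts plus
#'   the non-epistatic gene indices and per-gene parametric frequencies.
#' @export
pair_setup <- function(map, eff, p1, p2, network, ratio = 1) {
  p <- (p1 + p2) / 2
  pairs <- lapply(seq_len(nrow(network)), function(k) {
    i <- network$gene_i[k]; j <- network$gene_j[k]
    r <- pair_recombination(map, i, j)
    hap0 <- founder_hap_freqs(p1[i], p2[i], p1[j], p2[j], r)
    dist0 <- two_locus_dist(hap0, r)
    pe <- list(m_a = eff$m[i], a_a = eff$a[i], d_a = eff$d[i],
               m_b = eff$m[j], a_b = eff$a[j], d_b = eff$d[j],
               p_a = p[i], p_b = p[j])
    grid <- build_epistatic_grid(pe, network$type[k], ratio, dist0)
    es <- kempthorne_effects(dist0, grid)
    list(i = i, j = j, r = r, hap0 = hap0, grid = grid, es = es)
  })
  epi_genes <- c(network$gene_i, network$gene_j)
  structure(list(pairs = pairs,
                 ne_idx = setdiff(seq_len(map$n_genes), epi_genes),
                 p = p, eff = eff, map = map),
            class = "pair_setup")
}

#' Table of the epistatic network with sampled grid parameters
#'
#' @param setup a `pair_setup` (e.g. `run_scenario(...)$setup`).
#' @param path optional CSV file to write.
#' @return data frame with columns `gene_i`, `gene_j`, `type`, `r`, `I22`,
#'   `V_I`; invisibly when written to file.
#' @export
epistatic_network_table <- function(setup, path = NULL) {
  out <- do.call(rbind, lapply(setup$pairs, function(pr)
    data.frame(gene_i = pr$i, gene_j = pr$j, type = pr$grid$type,
               r = pr$r, I22 = pr$grid$I22, V_I = pr$grid$V_I)))
  if (is.null(out))
    out <- data.frame(gene_i = integer(0), gene_j = integer(0),
                      type = character(0), r = numeric(0),
                      I22 = numeric(0), V_I = numeric(0))
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

# parametric two-locus cell probabilities of one pair at generation n
pair_cell_probs <- function(pair, scheme, n) {
  if (scheme == "selfing") {
    d0 <- two_locus_dist(pair$hap0, pair$r)
    cell_probabilities(selfing_two_locus_recursion(d0, pair$r, n))
  } else {
    m0 <- ld_metrics(pair$hap0)
    Dn <- delta_random_mating(m0$Delta, pair$r, n)
    pa <- m0$p_a; pb <- m0$p_b
    hap <- c(pa * pb + Dn, pa * (1 - pb) - Dn, (1 - pa) * pb - Dn,
             (1 - pa) * (1 - pb) + Dn)
    cell_probabilities(two_locus_dist(hap, pair$r))
  }
}

#' Parametric effects of a trait at one generation
#'
#' Assembles, for generation `n` of the given scheme, the per-dosage
#' additive and dominance values of the non-epistatic genes (single-locus
#' inbred theory at F = 1 - (1/2)^n under selfing, F = 0 under random
#' mating), the centered per-cell component tables of every epistatic pair
#' under that generation's parametric two-locus distribution, and the
#' inbred population mean M_F.
#'
#' @param setup a `pair_setup`.
#' @param scheme `"selfing"` or `"random"`.
#' @param n generation index (>= 0).
#' @return object of class `parametric_effects`.
#' @export
parametric_effects <- function(setup, scheme = c("selfing", "random"), n = 0) {
  scheme <- match.arg(scheme)
  F <- if (scheme == "selfing") 1 - 0.5^n else 0
  p <- setup$p[setup$ne_idx]
  q <- 1 - p
  a <- setup$eff$a[setup$ne_idx]
  d <- setup$eff$d[setup$ne_idx]
  m <- setup$eff$m[setup$ne_idx]
  alpha <- a + (q - p) * d
  # per-dosage values (columns: 0, 1, 2 copies of the increasing allele)
  A_ne <- cbind(-2 * p * alpha, (q - p) * alpha, 2 * q * alpha)
  D_ne <- cbind(-2 * p^2 * d, 2 * p * q * d, -2 * q^2 * d) + 2 * F * p * q * d
  M_F <- sum(m + (p - q) * a + 2 * p * q * d - 2 * F * p * q * d)
  np <- length(setup$pairs)
  pair_tabs <- NULL
  if (np > 0) {
    comp <- array(0, c(np, 9, 6))
    for (k in seq_len(np)) {
      pair <- setup$pairs[[k]]
      f <- pair_cell_probs(pair, scheme, n)
      cells <- pair$es$cells[, COMPONENT_NAMES, drop = FALSE]
      comp[k, , ] <- sweep(cells, 2, colSums(f * cells))
      M_F <- M_F + sum(f * pair$es$cells[, "G"])
    }
    pair_tabs <- comp
  }
  structure(list(generation = n, scheme = scheme, F = F, M_F = M_F,
                 ne_idx = setup$ne_idx, A_ne = A_ne, D_ne = D_ne,
                 pair_i = vapply(setup$pairs, `[[`, integer(1), "i"),
                 pair_j = vapply(setup$pairs, `[[`, integer(1), "j"),
                 pair_tabs = pair_tabs),
            class = "parametric_effects")
}

# gather per-individual sums of per-locus dosage tables:
# tab is n_loci x 3, dosage is N x n_loci
gather_locus <- function(tab, dosage) {
  if (ncol(dosage) == 0) return(numeric(nrow(dosage)))
  n_loci <- ncol(dosage)
  idx <- cbind(rep(seq_len(n_loci), each = nrow(dosage)),
               as.vector(dosage) + 1L)
  rowSums(matrix(tab[idx], nrow(dosage), n_loci))
}

#' Per-individual parametric genetic values
#'
#' Computes additive (A), dominance (D) and epistatic (AA, AD, DA, DD)
#' genetic values for every individual from the parametric effects of the
#' population's generation, each centered so that its parametric
#' expectation is zero, and the genotypic value
#' G = M_F + A + D + AA + AD + DA + DD.
#'
#' @param pop a `population`.
#' @param pe a `parametric_effects` for the same generation.
#' @return data frame with columns A, D, AA, AD, DA, DD, G and attribute
#'   `M_F`.
#' @export
genetic_values <- function(pop, pe) {
  if (pop$generation != pe$generation)
    stop("effects are for generation ", pe$generation,
         " but the population is at generation ", pop$generation)
  geno <- pop$hap1 + pop$hap2
  N <- nrow(geno)
  out <- data.frame(
    A = gather_locus(pe$A_ne, geno[, pe$ne_idx, drop = FALSE]),
    D = gather_locus(pe$D_ne, geno[, pe$ne_idx, drop = FALSE]),
    AA = numeric(N), AD = numeric(N), DA = numeric(N), DD = numeric(N))
  np <- length(pe$pair_i)
  if (np > 0) {
    cell <- 3L * geno[, pe$pair_i, drop = FALSE] +
      geno[, pe$pair_j, drop = FALSE] + 1L
    idx <- cbind(rep(seq_len(np), each = N), as.vector(cell))
    for (cmp in seq_along(COMPONENT_NAMES)) {
      tab <- pe$pair_tabs[, , cmp, drop = FALSE]
      dim(tab) <- c(np, 9)
      out[[COMPONENT_NAMES[cmp]]] <- out[[COMPONENT_NAMES[cmp]]] +
        rowSums(matrix(tab[idx], N, np))
    }
  }
  out$G <- pe$M_F + rowSums(out[, COMPONENT_NAMES])
  attr(out, "M_F") <- pe$M_F
  out
}
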