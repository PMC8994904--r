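# Digenic epistasis types as genotype-value equality patterns over the 9
# cells g_ij (i = copies of A, j = copies of B).  Cell labels follow the
# F2 dihybrid convention: class membership determines the classic F2
# phenotypic ratios under independent assortment.

EPISTASIS_TYPES <- c("complementary", "duplicate", "dominant", "recessive",
                     "dominant_and_recessive", "duplicate_cumulative",
                     "nonepistatic_interaction")

# equality classes, cells coded "ij" = copies of A, copies of B
EPISTASIS_PATTERNS <- list(
  complementary = list(c("22", "21", "12", "11"),
                       c("20", "10", "02", "01", "00")),
  duplicate = list(c("22", "21", "20", "12", "11", "10", "02", "01"),
                   c("00")),
  dominant = list(c("22", "21", "20", "12", "11", "10"),
                  c("02", "01"), c("00")),
  recessive = list(c("22", "21", "12", "11"),
                   c("02", "01"), c("20", "10", "00")),
  dominant_and_recessive = list(c("22", "21", "12", "11", "20", "10", "00"),
                                c("02", "01")),
  duplicate_cumulative = list(c("22", "21", "12", "11"),
                              c("20", "10", "02", "01"), c("00")),
  nonepistatic_interaction = list(c("22", "21", "12", "11"),
                                  c("20", "10"), c("02", "01"), c("00"))
)

#' The seven digenic epistasis types
#'
#' @return character vector of the concrete type codes.
#' @export
epistasis_types <- function() EPISTASIS_TYPES

#' Equality classes of a digenic epistasis type
#'
#' Each type constrains the 9 two-locus genotypic values G_ij to be equal
#' within classes of cells; e.g. complementary epistasis has
#' G22=G21=G12=G11 and G20=G10=G02=G01=G00 (the 9:7 F2 ratio).
#'
#' @param type one of [epistasis_types()].
#' @return list of character vectors of cell codes `"ij"` (i = copies of A,
#'   j = copies of B) partitioning the 9 cells.
#' @export
epistasis_pattern <- function(type) {
  if (!type %in% EPISTASIS_TYPES)
    stop("not a concrete epistasis type: ", type,
         " (admixture/none must be resolved by the caller)")
  EPISTASIS_PATTERNS[[type]]
}

#' F2 class probabilities of an epistasis type
#'
#' Sums the F2 two-locus genotype distribution (p = q = 0.5, unlinked loci,
#' Hardy-Weinberg, no inbreeding: weights (1,2,1) x (1,2,1)/16) over the
#' equality classes of the type, reproducing the classic ratios (9:7, 15:1,
#' 12:3:1, 9:3:4, 13:3, 9:6:1, 9:3:3:1) exactly in sixteenths.
#'
#' @param type one of [epistasis_types()].
#' @return numeric vector of class probabilities (exact multiples of 1/16),
#'   named by the class's first cell, ordered as in [epistasis_pattern()].
#' @export
f2_class_probabilities <- function(type) {
  pat <- epistasis_pattern(type)
  w <- outer(c(1, 2, 1), c(1, 2, 1))           # index 1..3 = 0..2 copies
  dimnames(w) <- list(0:2, 0:2)
  probs <- vapply(pat, function(cls) {
    sum(vapply(cls, function(cell) {
      i <- as.integer(substr(cell, 1, 1)); j <- as.integer(substr(cell, 2, 2))
      w[i + 1, j + 1]
    }, numeric(1))) / 16
  }, numeric(1))
  names(probs) <- vapply(pat, `[`, character(1), 1)
  probs
}

# nonepistatic 9-cell grid for a pair of genes: cell value =
# (m_a + a/d/-a) + (m_b + ...), in cell order g00..g22 (CELL_NAMES)
nonepistatic_grid <- function(m_a, a_a, d_a, m_b, a_b, d_b) {
  va <- c(m_a - a_a, m_a + d_a, m_a + a_a)   # 0, 1, 2 copies of A
  vb <- c(m_b - a_b, m_b + d_b, m_b + a_b)
  g <- as.vector(t(outer(va, vb, "+")))      # index = 3*iA + iB + 1
  names(g) <- CELL_NAMES
  g
}

# additive + dominance variance of a pair at founder (F = 0) frequencies,
# used to scale V(I)
pair_va_vd <- function(p_a, a_a, d_a, p_b, a_b, d_b, delta) {
  qa <- 1 - p_a; qb <- 1 - p_b
  alpha_a <- a_a + (qa - p_a) * d_a
  alpha_b <- a_b + (qb - p_b) * d_b
  VA <- 2 * p_a * qa * alpha_a^2 + 2 * p_b * qb * alpha_b^2 +
    4 * delta * alpha_a * alpha_b
  VD <- 4 * (p_a * qa * d_a)^2 + 4 * (p_b * qb * d_b)^2 +
    8 * delta^2 * d_a * d_b
  list(VA = VA, VD = VD)
}

#' Build an epistatic genotypic-value grid for a pair of genes
#'
#' Starts from the pair's nonepistatic grid (midpoints + additive +
#' dominance contributions), computes V(I) = ratio x (V(A) + V(D)) at the
#' pair's founder frequencies, and samples the epistatic value of the AABB
#' genotype I_22 ~ N(0, V(I)).  The grid is class-constant on the equality
#' classes of the requested type and is built as
#' `v(t) = classmeans + t * direction`, where `classmeans` are the
#' genotype-probability-weighted class means of the nonepistatic grid (its
#' minimum weighted-norm pattern-satisfying collapse), `direction` is the
#' minimum weighted-norm class contrast that preserves the population mean
#' while raising the epistatic value of genotype AABB (the AA+AD+DA+DD sum
#' of the grid's Kempthorne decomposition at the founder frequencies), and
#' the magnitude `t` is set so that the variance of the pair's epistatic
#' value over the founder genotype distribution equals I_22^2 — hence its
#' expectation over pairs is exactly V(I), and the ratio controls the
#' epistatic-variance magnitude as intended.  Among the two roots the one
#' whose AABB epistatic value is closest to I_22 is taken; if the pattern
#' collapse alone already exceeds the target variance (rare), the
#' magnitude minimizing the variance is used and the grid is flagged with
#' attribute `clamped`.  Since there are infinitely many grids per type,
#' this anchoring rule is this package's choice for tying the
#' epistatic-variance magnitude to the ratio.
#'
#' @param pair_effects list/row with fields `m_a`, `a_a`, `d_a`, `m_b`,
#'   `a_b`, `d_b`, `p_a`, `p_b` (effects and allele frequencies).
#' @param type one of [epistasis_types()].
#' @param ratio V(I)/(V(A)+V(D)) (>= 0).
#' @param dist a `two_locus_dist` supplying the founder genotype
#'   probabilities (class-mean weights, decomposition weights) and the LD
#'   coefficient.
#' @param I22 optionally force the sampled AABB epistatic value.
#' @return object of class `epistatic_grid`: list with `G` (9 cell values),
#'   `I` (total deviations from the nonepistatic grid), `N` (nonepistatic
#'   grid), `type`, `I22`, `V_I`.
#' @export
build_epistatic_grid <- function(pair_effects, type, ratio, dist, I22 = NULL) {
  if (ratio < 0) stop("ratio must be nonnegative")
  e <- pair_effects
  N <- nonepistatic_grid(e$m_a, e$a_a, e$d_a, e$m_b, e$a_b, e$d_b)
  f <- cell_probabilities(dist)
  D <- ld_metrics(hap_frequencies(dist))$Delta
  v <- pair_va_vd(e$p_a, e$a_a, e$d_a, e$p_b, e$a_b, e$d_b, D)
  V_I <- ratio * (v$VA + v$VD)
  if (is.null(I22)) I22 <- stats::rnorm(1, 0, sqrt(V_I))
  pat <- epistasis_pattern(type)
  k <- length(pat)
  cls_cells <- lapply(pat, function(cls) paste0("g", cls))
  w <- numeric(k)            # class probabilities
  B <- numeric(k)            # weighted class means of the nonepistatic grid
  a <- numeric(k)            # AABB epistatic value per unit of class value
  P <- matrix(0, 9, k)       # per-cell epistatic value per unit class value
  for (ci in seq_len(k)) {
    cells <- cls_cells[[ci]]
    w[ci] <- sum(f[cells])
    B[ci] <- if (w[ci] > 0) sum(f[cells] * N[cells]) / w[ci]
             else mean(N[cells])
    e_c <- stats::setNames(numeric(9), CELL_NAMES)
    e_c[cells] <- 1
    epi <- rowSums(kempthorne_effects(dist, e_c)$cells[,
                     c("AA", "AD", "DA", "DD")])
    P[, ci] <- epi
    a[ci] <- epi["g22"]
  }
  # minimum-norm mean-preserving direction with unit AABB epistatic value
  Cc <- rbind(w, a)
  M2 <- Cc %*% (t(Cc) / w)
  if (abs(det(M2)) < 1e-12 * max(abs(M2))^2)
    stop("degenerate pattern contrast for type ", type,
         " at these frequencies")
  dir <- as.vector(t(Cc) %*% solve(M2, c(0, 1))) / w
  # variance of the pair's epistatic value along v(t) = B + t dir:
  # quadratic alpha t^2 + beta t + gamma, target I22^2
  Wc <- diag(f) - outer(f, f)
  Q <- t(P) %*% Wc %*% P
  alpha <- as.numeric(t(dir) %*% Q %*% dir)
  beta <- 2 * as.numeric(t(B) %*% Q %*% dir)
  gamma <- as.numeric(t(B) %*% Q %*% B)
  disc <- beta^2 - 4 * alpha * (gamma - I22^2)
  clamped <- FALSE
  if (alpha <= 1e-14) {
    t_star <- 0; clamped <- TRUE
  } else if (disc < 0) {
    t_star <- -beta / (2 * alpha); clamped <- TRUE
  } else {
    roots <- (-beta + c(-1, 1) * sqrt(disc)) / (2 * alpha)
    epi22_at <- sum(a * B) + roots   # a.dir = 1
    t_star <- roots[which.min(abs(epi22_at - I22))]
  }
  v <- B + t_star * dir
  G <- N
  for (ci in seq_len(k)) G[cls_cells[[ci]]] <- v[ci]
  out <- structure(list(G = G, I = G - N, N = N, type = type,
                        I22 = unname(I22), V_I = unname(V_I)),
                   class = "epistatic_grid")
  attr(out, "clamped") <- clamped
  out
}

#' @export
print.epistatic_grid <- function(x, ...) {
  cat("epistatic_grid:", x$type, " I22 =", signif(x$I22, 4),
      " V(I) =", signif(x$V_I, 4), "\n")
  print(matrix(round(x$G, 4), 3, 3,
               dimnames = list(paste0("A", 0:2), paste0("B", 0:2))))
  invisible(x)
}

#' Assign the epistatic pair network over the genome
#'
#' Selects `pct_interacting * n_genes` genes uniformly at random, pairs
#' them uniformly (pairs may span chromosomes), and assigns each pair an
#' epistasis type: a single fixed type, or one drawn uniformly from the
#' seven concrete types per pair under admixture.  Each interacting gene
#' belongs to exactly one pair.
#'
#' @param n_genes total gene count.
#' @param pct_interacting fraction of interacting genes (`pct * n_genes`
#'   must be even).
#' @param type a concrete type code or `"admixture"`.
#' @return data frame with columns `gene_i`, `gene_j`, `type` (zero rows
#'   when `pct_interacting` is 0).
#' @export
assign_epistatic_network <- function(n_genes, pct_interacting,
                                     type = "admixture") {
  n_sel <- round(pct_interacting * n_genes)
  if (n_sel == 0)
    return(data.frame(gene_i = integer(0), gene_j = integer(0),
                      type = character(0)))
  if (n_sel %% 2 != 0)
    stop("pct_interacting * n_genes must be even, got ", n_sel)
  genes <- sample.int(n_genes, n_sel)
  n_pairs <- n_sel / 2
  types <- if (type == "admixture")
    sample(EPISTASIS_TYPES, n_pairs, replace = TRUE)
  else if (type %in% EPISTASIS_TYPES) rep(type, n_pairs)
  else stop("unknown epistasis type: ", type)
  data.frame(gene_i = genes[seq_len(n_pairs)],
             gene_j = genes[n_pairs + seq_len(n_pairs)],
             type = types)
}
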