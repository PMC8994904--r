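# Kempthorne two-locus decomposition generalized to LD and inbreeding.
#
# The 36 parameters (M; alpha_i per locus; delta_ij per locus; the 4
# additive x additive, 6 additive x dominance, 6 dominance x additive and
# 9 dominance x dominance interaction effects) are obtained from the 9
# genotypic values by weighted least squares under Kempthorne's
# restrictions: the allele-frequency-weighted sum of every effect class
# over each of its indices is zero.  With those restrictions the system is
# full rank (9 free degrees of freedom for 9 cells), the fit is exact, and
# the solution does not depend on the genotype-probability weights; the
# genotype distribution f_ij^(n) enters through the component means and
# (co)variances, which is where LD and inbreeding act.

CELL_IA <- (seq_len(9) - 1) %/% 3   # copies of A per cell
CELL_IB <- (seq_len(9) - 1) %% 3    # copies of B per cell

# 9 x 36 incidence matrix of the saturated two-locus model
kempthorne_design <- function() {
  X <- matrix(0, 9, 36)
  for (c in 1:9) {
    iA <- CELL_IA[c]; iB <- CELL_IB[c]
    nA <- iA; na <- 2 - iA; nB <- iB; nb <- 2 - iB
    g1 <- 3 - iA  # genotype index: 1 = AA, 2 = Aa, 3 = aa
    g2 <- 3 - iB
    X[c, 1] <- 1
    X[c, 2:3] <- c(nA, na)
    X[c, 4:5] <- c(nB, nb)
    X[c, 5 + g1] <- 1
    X[c, 8 + g2] <- 1
    X[c, 12:15] <- c(nA * nB, nA * nb, na * nB, na * nb)
    X[c, 15 + (0:1) * 3 + g2] <- c(nA, na)            # (alpha delta)_{u,kl}
    X[c, 21 + (g1 - 1) * 2 + (1:2)] <- c(nB, nb)      # (delta alpha)_{ij,v}
    X[c, 27 + (g1 - 1) * 3 + g2] <- 1                 # (delta delta)
  }
  X
}

KEMPTHORNE_X <- kempthorne_design()

# 36 x 36 matrix of Kempthorne's zero-sum restrictions at allele
# frequencies (p_a, p_b); some rows are redundant, the stacked system is
# solved by least squares (consistent, hence exact)
kempthorne_constraints <- function(p_a, p_b) {
  qa <- 1 - p_a; qb <- 1 - p_b
  C <- matrix(0, 36, 36)
  k <- 0
  add <- function(cols, w) {
    k <<- k + 1
    C[k, cols] <<- w
  }
  add(2:3, c(p_a, qa))                       # alpha^1
  add(4:5, c(p_b, qb))                       # alpha^2
  add(c(6, 7), c(p_a, qa))                   # delta^1 (second index A / a)
  add(c(7, 8), c(p_a, qa))
  add(c(9, 10), c(p_b, qb))                  # delta^2
  add(c(10, 11), c(p_b, qb))
  add(c(12, 14), c(p_a, qa))                 # (aa): sum over locus-1 allele
  add(c(13, 15), c(p_a, qa))
  add(c(12, 13), c(p_b, qb))                 # (aa): sum over locus-2 allele
  add(c(14, 15), c(p_b, qb))
  for (g2 in 1:3) add(15 + c(0, 3) + g2, c(p_a, qa))        # (ad) over u
  for (u in 0:1) for (l in 0:1)                             # (ad) over k|l
    add(15 + u * 3 + l + c(1, 2), c(p_b, qb))
  for (g1 in 1:3) add(21 + (g1 - 1) * 2 + c(1, 2), c(p_b, qb))  # (da) over v
  for (v in 1:2) for (j in 0:1)                             # (da) over i|j
    add(21 + j * 2 + c(0, 2) + v, c(p_a, qa))
  for (j in 0:1) for (g2 in 1:3)                            # (dd) locus 1
    add(27 + j * 3 + c(0, 3) + g2, c(p_a, qa))
  for (g1 in 1:3) for (l in 0:1)                            # (dd) locus 2
    add(27 + (g1 - 1) * 3 + l + c(1, 2), c(p_b, qb))
  C
}

#' Kempthorne effects of a two-locus genotypic-value grid
#'
#' Solves the restricted weighted normal equations for the 36 two-locus
#' parameters given the 9 genotypic values and the genotype distribution.
#' Under Kempthorne's allele-frequency-weighted zero-sum restrictions the
#' constrained system has full rank, the fitted values reproduce the input
#' grid exactly, and the effects depend on the distribution only through
#' the (generation-invariant) allele frequencies; the distribution supplied
#' here additionally furnishes the component means E(D), E(AA), E(AD),
#' E(DA), E(DD) at its generation.
#'
#' @param dist a `two_locus_dist` (supplies f_ij^(n) and allele
#'   frequencies; both must be segregating).
#' @param grid an `epistatic_grid`, or a named numeric(9) of genotypic
#'   values in cell order g00..g22.
#' @return object of class `effect_set`: list with `beta` (36 effects),
#'   `M`, `cells` (9 x 7 matrix of per-cell A, D, AA, AD, DA, DD, G),
#'   `means` (component means under `dist`), `p_a`, `p_b`, `f`.
#' @export
kempthorne_effects <- function(dist, grid) {
  y <- if (inherits(grid, "epistatic_grid")) grid$G else grid
  if (length(y) != 9) stop("grid must supply 9 genotypic values")
  hf <- hap_frequencies(dist)
  p_a <- hf[1] + hf[2]; p_b <- hf[1] + hf[3]
  if (p_a <= 0 || p_a >= 1) stop("locus a is fixed (p_a = ", p_a, ")")
  if (p_b <= 0 || p_b >= 1) stop("locus b is fixed (p_b = ", p_b, ")")
  A <- rbind(KEMPTHORNE_X, kempthorne_constraints(p_a, p_b))
  beta <- qr.solve(A, c(y, rep(0, 36)))
  cells <- cbind(
    A  = as.vector(KEMPTHORNE_X[, 2:5] %*% beta[2:5]),
    D  = as.vector(KEMPTHORNE_X[, 6:11] %*% beta[6:11]),
    AA = as.vector(KEMPTHORNE_X[, 12:15] %*% beta[12:15]),
    AD = as.vector(KEMPTHORNE_X[, 16:21] %*% beta[16:21]),
    DA = as.vector(KEMPTHORNE_X[, 22:27] %*% beta[22:27]),
    DD = as.vector(KEMPTHORNE_X[, 28:36] %*% beta[28:36]),
    G  = unname(y))
  rownames(cells) <- CELL_NAMES
  f <- cell_probabilities(dist)
  structure(list(beta = beta, M = beta[1], cells = cells,
                 means = colSums(f * cells), p_a = unname(p_a),
                 p_b = unname(p_b), f = f),
            class = "effect_set")
}

#' @export
print.effect_set <- function(x, ...) {
  cat("effect_set: M =", signif(x$M, 5), " p_a =", round(x$p_a, 4),
      " p_b =", round(x$p_b, 4), "\n component means:\n")
  print(signif(x$means, 5))
  invisible(x)
}

#' Parametric moments of the genetic components under a distribution
#'
#' Means, variances and all pairwise covariances of the six components
#' (A, D, AA, AD, DA, DD) of an `effect_set`, taken over the genotype
#' probabilities of `dist` — the enumeration route to the variance
#' components, exact for a single pair of loci.
#'
#' @param es an `effect_set`.
#' @param dist a `two_locus_dist` (any generation; allele frequencies must
#'   match those used for `es`).
#' @return list with `means` (length 7, incl. G) and `cov` (7 x 7 matrix).
#' @export
parametric_components <- function(es, dist) {
  f <- cell_probabilities(dist)
  m <- colSums(f * es$cells)
  centered <- sweep(es$cells, 2, m)
  V <- t(centered) %*% (f * centered)
  list(means = m, cov = V)
}

#' Single-locus effects in an inbred population
#'
#' For a biallelic gene with frequencies p/q, effects a and d, after
#' inbreeding to coefficient F: the average substitution effect is
#' alpha = a + (q - p) d; the inbred-population allelic effects are
#' alpha_A = q alpha + 2Fpqd and alpha_a = -p alpha + 2Fpqd; the
#' noninbred additive values A^(0) = (2 q alpha, (q - p) alpha, -2 p alpha)
#' shift by 4Fpqd to give A^(n), and the dominance values
#' D^(0) = (-2 q^2 d, 2pqd, -2 p^2 d) shift by 2Fpqd to give D^(n); the
#' population mean drops from M = m + (p - q) a + 2pqd to M_F = M - 2Fpqd.
#'
#' @param p frequency of the trait-increasing allele.
#' @param a homozygote half-difference.
#' @param d dominance deviation.
#' @param F inbreeding coefficient in \[0, 1\].
#' @param m homozygote midpoint (default 0).
#' @return object of class `single_locus_effects`: list with `p`, `q`,
#'   `a`, `d`, `m`, `alpha`, `alpha_A`, `alpha_a`, `M`, `M_F`, `A0`, `An`,
#'   `D0`, `Dn` (genotype order aa, Aa, AA), `freqs` (inbred genotype
#'   probabilities, same order) and `F`.
#' @export
single_locus_inbred_effects <- function(p, a, d, F = 0, m = 0) {
  if (p < 0 || p > 1 || F < 0 || F > 1) stop("p and F must be in [0, 1]")
  q <- 1 - p
  alpha <- a + (q - p) * d
  M <- m + (p - q) * a + 2 * p * q * d
  A0 <- c(aa = -2 * p * alpha, Aa = (q - p) * alpha, AA = 2 * q * alpha)
  D0 <- c(aa = -2 * p^2 * d, Aa = 2 * p * q * d, AA = -2 * q^2 * d)
  structure(list(
    p = p, q = q, a = a, d = d, m = m, alpha = alpha,
    alpha_A = q * alpha + 2 * F * p * q * d,
    alpha_a = -p * alpha + 2 * F * p * q * d,
    M = M, M_F = M - 2 * F * p * q * d,
    A0 = A0, An = A0 + 4 * F * p * q * d,
    D0 = D0, Dn = D0 + 2 * F * p * q * d,
    freqs = c(aa = q^2 + F * p * q, Aa = 2 * p * q * (1 - F),
              AA = p^2 + F * p * q),
    F = F), class = "single_locus_effects")
}

#' Cockerham's selfing components D1 and D2
#'
#' D1 = sum over loci of 2pq(p - q) alpha d (covariance of additive and
#' dominance effects) and D2 = sum of 4pq(p - q)^2 d^2 (variance of
#' dominance effects), the components of the covariance between selfed
#' relatives; both vanish when p = q at every locus.
#'
#' @param p,a,d vectors of per-locus frequencies and effects.
#' @return list with `D1`, `D2`.
#' @export
cockerham_components <- function(p, a, d) {
  q <- 1 - p
  alpha <- a + (q - p) * d
  list(D1 = sum(2 * p * q * (p - q) * alpha * d),
       D2 = sum(4 * p * q * (p - q)^2 * d^2))
}

#' Closed-form two-locus variances under selfing with LD
#'
#' Evaluates the closed-form additive variance, dominance variance and
#' additive-dominance covariance of two linked biallelic genes (no
#' epistasis) after n generations of selfing from a Hardy-Weinberg founder
#' with gametic-pool LD `delta`, using F = 1 - (1/2)^n,
#' c1 = 2(1 - \[(1-2r)/2\]^n)/(1 + 2r) and c = 1 - 2r(1 - r):
#' \deqn{\sigma^2_A = (1+F)(2p_aq_a\alpha_a^2 + 2p_bq_b\alpha_b^2) +
#'   2[2 + c_1(1-2r)]\Delta\alpha_a\alpha_b}
#' with the corresponding expressions for \eqn{\sigma^2_D} (involving
#' Cockerham's D2 and the c^n terms) and \eqn{\sigma_{A,D}} (involving D1);
#' \eqn{\sigma_{A,D} = 0} whenever p = q at both loci.
#'
#' @param ea,eb `single_locus_effects` (or lists with `p`, `a`, `d`) for
#'   the two loci.
#' @param delta gametic-pool LD coefficient of the founder.
#' @param r recombination fraction.
#' @param n selfing generations (0 gives the noninbred LD values).
#' @return list with `sigma2_A`, `sigma2_D`, `cov_A_D`, `sigma2_G`, `F`.
#' @export
closed_form_two_locus_variances <- function(ea, eb, delta, r, n) {
  k <- selfing_constants(r, n)
  F <- k$F; c1 <- k$c1; cn <- k$c^n
  pa <- ea$p; qa <- 1 - pa; da <- ea$d
  pb <- eb$p; qb <- 1 - pb; db <- eb$d
  aa <- ea$a + (qa - pa) * da
  ab <- eb$a + (qb - pb) * db
  s2A <- (1 + F) * (2 * pa * qa * aa^2 + 2 * pb * qb * ab^2) +
    2 * (2 + c1 * (1 - 2 * r)) * delta * aa * ab
  s2D <- (1 - F^2) * (4 * pa^2 * qa^2 * da^2 + 4 * pb^2 * qb^2 * db^2) +
    F * (4 * pa * qa * (pa - qa)^2 * da^2 +
         4 * pb * qb * (pb - qb)^2 * db^2) +
    8 * ((1 - F) * (cn - 1 + F) * pa * qa * pb * qb +
         (pa - qa) * (pb - qb) *
           ((1 - F) * cn - (1 - 2 * F) + c1 * (1 - 2 * r) / 2) * delta / 2 +
         (1 - F) * cn * delta^2) * da * db
  sAD <- 2 * F * (2 * pa * qa * (pa - qa) * aa * da +
                  2 * pb * qb * (pb - qb) * ab * db) +
    (2 * F + c1 * (1 - 2 * r)) * delta *
      ((pb - qb) * aa * db + (pa - qa) * ab * da)
  list(sigma2_A = s2A, sigma2_D = s2D, cov_A_D = sAD,
       sigma2_G = s2A + s2D + 2 * sAD, F = F)
}

#' Closed-form variances after random mating with LD decay
#'
#' After n generations of random crosses the additive and dominance
#' variances of two linked genes (no epistasis, no inbreeding) are the
#' noninbred LD expressions with Delta replaced by (1 - r)^n Delta; the
#' additive-dominance covariance is zero.
#'
#' @inheritParams closed_form_two_locus_variances
#' @return list with `sigma2_A`, `sigma2_D`, `cov_A_D` (0), `sigma2_G`.
#' @export
random_mating_two_locus_variances <- function(ea, eb, delta, r, n) {
  dn <- delta_random_mating(delta, r, n)
  pa <- ea$p; qa <- 1 - pa; da <- ea$d
  pb <- eb$p; qb <- 1 - pb; db <- eb$d
  aa <- ea$a + (qa - pa) * da
  ab <- eb$a + (qb - pb) * db
  s2A <- 2 * pa * qa * aa^2 + 2 * pb * qb * ab^2 + 4 * dn * aa * ab
  s2D <- 4 * pa^2 * qa^2 * da^2 + 4 * pb^2 * qb^2 * db^2 + 8 * dn^2 * da * db
  list(sigma2_A = s2A, sigma2_D = s2D, cov_A_D = 0, sigma2_G = s2A + s2D)
}

COMPONENT_NAMES <- c("A", "D", "AA", "AD", "DA", "DD")

#' Empirical variance components from per-individual genetic values
#'
#' Sample variances of the six genetic components, their 15 pairwise
#' covariances and the genotypic variance.  Because G is the sum of the
#' components plus a constant, Var(G) equals the sum of the variances plus
#' twice the sum of the covariances to machine precision.
#'
#' @param values data frame (or matrix) with columns A, D, AA, AD, DA, DD
#'   and G, one row per individual (as returned by [genetic_values()]).
#' @return object of class `variance_components`: one-row data frame with
#'   `sigma2_*` for the six components, `cov_x_y` for the 15 pairs,
#'   `sigma2_G` and `epistatic_fraction`.
#' @export
variance_components_from_sample <- function(values) {
  m <- as.matrix(values[, COMPONENT_NAMES, drop = FALSE])
  if (nrow(m) < 2) stop("need at least two individuals")
  V <- stats::cov(m)
  out <- as.list(diag(V))
  names(out) <- paste0("sigma2_", COMPONENT_NAMES)
  for (i in 1:5) for (j in (i + 1):6)
    out[[paste0("cov_", COMPONENT_NAMES[i], "_", COMPONENT_NAMES[j])]] <-
      V[i, j]
  out$sigma2_G <- if ("G" %in% colnames(values))
    stats::var(values[, "G"]) else sum(diag(V)) + 2 * sum(V[upper.tri(V)])
  out$epistatic_fraction <- if (out$sigma2_G > 0)
    (out$sigma2_AA + out$sigma2_AD + out$sigma2_DA + out$sigma2_DD) /
      out$sigma2_G else NA_real_
  structure(as.data.frame(out), class = c("variance_components",
                                          "data.frame"))
}
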