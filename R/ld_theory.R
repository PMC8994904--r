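# Two-locus machinery.  Haplotypes are ordered AB, Ab, aB, ab (A/B = the
# trait-increasing alleles).  The phase-aware genotype space has 10 states:
# 4 double homozygotes, 4 single heterozygotes and the two double-
# heterozygote phases (coupling AB/ab, repulsion Ab/aB), which behave
# differently under selfing and must be tracked separately even though they
# share the 9-cell genotype table.

HAP_NAMES <- c("AB", "Ab", "aB", "ab")

# haplotype composition of each of the 10 states
STATE_HAPS <- matrix(c(1, 1,  2, 2,  3, 3,  4, 4,
                       1, 2,  1, 3,  2, 4,  3, 4,
                       1, 4,  2, 3),
                     ncol = 2, byrow = TRUE)
STATE_NAMES <- apply(STATE_HAPS, 1, function(h)
  paste(HAP_NAMES[h[1]], HAP_NAMES[h[2]], sep = "/"))

# copies of A (haps 1,2) and of B (haps 1,3) per state
STATE_A <- rowSums(matrix(STATE_HAPS %in% c(1, 2), ncol = 2))
STATE_B <- rowSums(matrix(STATE_HAPS %in% c(1, 3), ncol = 2))

# canonical 9-cell order: index = 3*iA + iB + 1, iA/iB = copies of A/B
CELL_NAMES <- paste0("g", rep(0:2, each = 3), rep(0:2, times = 3))
STATE_CELL <- 3L * STATE_A + STATE_B + 1L

# probability of each gamete (columns AB, Ab, aB, ab) produced by each state
state_gamete_probs <- function(r) {
  g <- matrix(0, 10, 4, dimnames = list(STATE_NAMES, HAP_NAMES))
  for (s in 1:4) g[s, STATE_HAPS[s, 1]] <- 1
  for (s in 5:8) g[s, STATE_HAPS[s, ]] <- 0.5
  g[9, ]  <- c(1 - r, r, r, 1 - r) / 2   # coupling AB/ab
  g[10, ] <- c(r, 1 - r, 1 - r, r) / 2   # repulsion Ab/aB
  g
}

# collapse an (ordered) pair distribution over haplotypes to the 10 states
collapse_pairs <- function(M) {
  p <- numeric(10)
  for (s in 1:10) {
    h <- STATE_HAPS[s, ]
    p[s] <- if (h[1] == h[2]) M[h[1], h[1]] else M[h[1], h[2]] + M[h[2], h[1]]
  }
  names(p) <- STATE_NAMES
  p
}

#' Phase-aware two-locus genotype distribution
#'
#' Builds the 10-state distribution of two-locus genotypes from gametic
#' (haplotype) frequencies, assuming the two haplotypes of an individual
#' are independent draws from the gametic pool (Hardy-Weinberg).
#'
#' @param hap_freqs numeric(4): frequencies of haplotypes AB, Ab, aB, ab.
#' @param r recombination fraction between the loci, in \[0, 0.5\].
#' @param generation generation index carried as metadata.
#' @return object of class `two_locus_dist` with fields `state` (10 named
#'   probabilities), `r` and `generation`.
#' @export
two_locus_dist <- function(hap_freqs, r = 0.5, generation = 0) {
  if (length(hap_freqs) != 4 || any(hap_freqs < -1e-12) ||
      abs(sum(hap_freqs) - 1) > 1e-8)
    stop("hap_freqs must be 4 nonnegative frequencies summing to 1")
  hap_freqs <- pmax(hap_freqs, 0)
  st <- collapse_pairs(outer(hap_freqs, hap_freqs))
  structure(list(state = st, r = r, generation = generation),
            class = "two_locus_dist")
}

#' @export
print.two_locus_dist <- function(x, ...) {
  cat("two_locus_dist (generation", x$generation, ", r =", x$r, ")\n")
  print(round(x$state, 5))
  invisible(x)
}

#' 10-state selfing transition matrix
#'
#' Row s gives the genotype distribution of a selfed offspring of a parent
#' in state s: the offspring's two haplotypes are independent gametes of
#' the parent, with recombinant gametes produced at frequency r by the two
#' double-heterozygote phases (and trivially by all other states).
#'
#' @param r recombination fraction.
#' @return 10 x 10 row-stochastic matrix.
#' @export
selfing_transition_matrix <- function(r) {
  g <- state_gamete_probs(r)
  t(vapply(1:10, function(s) collapse_pairs(outer(g[s, ], g[s, ])),
           numeric(10)))
}

#' Advance a two-locus distribution by n generations of selfing
#'
#' Applies the exact 10-state selfing recursion n times.  Allele
#' frequencies are invariant and single-locus heterozygosity halves each
#' generation.
#'
#' @param init a `two_locus_dist`.
#' @param r recombination fraction (defaults to the one stored in `init`).
#' @param n number of selfing generations (>= 0).
#' @return a `two_locus_dist` at generation `init$generation + n`.
#' @export
selfing_two_locus_recursion <- function(init, r = init$r, n = 1) {
  if (!inherits(init, "two_locus_dist")) stop("init must be a two_locus_dist")
  st <- init$state
  if (any(st < -1e-10) || abs(sum(st) - 1) > 1e-8)
    stop("invalid state distribution")
  if (n > 0) {
    T <- selfing_transition_matrix(r)
    for (i in seq_len(n)) st <- as.vector(st %*% T)
    names(st) <- STATE_NAMES
  }
  structure(list(state = st, r = r, generation = init$generation + n),
            class = "two_locus_dist")
}

#' Genotype-cell probabilities of a two-locus distribution
#'
#' Collapses the 10 phase-aware states onto the 9 genotype cells
#' f_ij (i, j = copies of A and B); both double-heterozygote phases feed
#' cell g11.
#'
#' @param dist a `two_locus_dist`.
#' @return named numeric(9) in cell order g00, g01, ..., g22.
#' @export
cell_probabilities <- function(dist) {
  f <- as.vector(tapply(dist$state, STATE_CELL, sum))
  out <- numeric(9)
  out[sort(unique(STATE_CELL))] <- f
  names(out) <- CELL_NAMES
  out
}

#' Haplotype frequencies carried by a two-locus distribution
#'
#' Frequency of each haplotype among the chromosomes of the individuals
#' (two per individual).  For a distribution advanced under selfing this is
#' the gametic-pool composition on which the LD measures are defined.
#'
#' @param dist a `two_locus_dist`.
#' @return named numeric(4): frequencies of AB, Ab, aB, ab.
#' @export
hap_frequencies <- function(dist) {
  f <- numeric(4)
  for (s in 1:10) {
    h <- STATE_HAPS[s, ]
    f[h[1]] <- f[h[1]] + dist$state[s] / 2
    f[h[2]] <- f[h[2]] + dist$state[s] / 2
  }
  names(f) <- HAP_NAMES
  f
}

#' Parametric LD of a founder population from a two-population cross
#'
#' A founder population built by crossing two linkage-equilibrium
#' populations (allele frequencies p_a1/p_b1 and p_a2/p_b2) followed by one
#' generation of random crosses has gametic-pool LD
#' Delta = \[(1 - 2r)/4\] (p_a1 - p_a2)(p_b1 - p_b2): positive for genes in
#' coupling phase, negative in repulsion.
#'
#' @param p_a1,p_a2 allele frequencies of A in the two parental populations.
#' @param p_b1,p_b2 allele frequencies of B in the two parental populations.
#' @param r recombination fraction.
#' @return the LD coefficient Delta.
#' @export
founder_delta <- function(p_a1, p_a2, p_b1, p_b2, r) {
  (1 - 2 * r) / 4 * (p_a1 - p_a2) * (p_b1 - p_b2)
}

#' Founder haplotype frequencies from a two-population cross
#'
#' @inheritParams founder_delta
#' @return numeric(4): frequencies of AB, Ab, aB, ab in the founder gametic
#'   pool (equal to the marginal products plus/minus `founder_delta`).
#' @export
founder_hap_freqs <- function(p_a1, p_a2, p_b1, p_b2, r) {
  pa <- (p_a1 + p_a2) / 2
  pb <- (p_b1 + p_b2) / 2
  D <- founder_delta(p_a1, p_a2, p_b1, p_b2, r)
  c(AB = pa * pb + D, Ab = pa * (1 - pb) - D,
    aB = (1 - pa) * pb - D, ab = (1 - pa) * (1 - pb) + D)
}

#' LD decay under random mating
#'
#' Delta_n = (1 - r)^n Delta_0; allele frequencies are unchanged, so the
#' r-squared ratio is (1 - r)^(2n).
#'
#' @param delta0 initial LD coefficient.
#' @param r recombination fraction.
#' @param n generations of random mating.
#' @return Delta after n generations.
#' @export
delta_random_mating <- function(delta0, r, n) (1 - r)^n * delta0

#' Selfing constants of the closed-form variances
#'
#' F = 1 - (1/2)^n, c1 = 2(1 - \[(1 - 2r)/2\]^n) / (1 + 2r) and
#' c = 1 - 2r(1 - r), the constants entering the closed-form additive and
#' dominance variances after n generations of selfing with linkage.
#'
#' @param r recombination fraction.
#' @param n selfing generations.
#' @return list with `F`, `c1`, `c`.
#' @export
selfing_constants <- function(r, n) {
  list(F = 1 - 0.5^n,
       c1 = 2 * (1 - ((1 - 2 * r) / 2)^n) / (1 + 2 * r),
       c = 1 - 2 * r * (1 - r))
}

#' LD metrics from haplotype frequencies
#'
#' Delta = P_AB P_ab - P_Ab P_aB; r2 = Delta^2/(p_a q_a p_b q_b);
#' D' = Delta / Delta_max with Delta_max = min(p_a q_b, q_a p_b) for
#' Delta > 0 and min(p_a p_b, q_a q_b) for Delta < 0.  At a fixed locus the
#' metrics are undefined and returned as NA.
#'
#' @param hap_freqs numeric(4): frequencies of AB, Ab, aB, ab.
#' @return list with `Delta`, `r2`, `Dprime`, `p_a`, `p_b`.
#' @export
ld_metrics <- function(hap_freqs) {
  P <- hap_freqs
  pa <- P[1] + P[2]; pb <- P[1] + P[3]
  qa <- 1 - pa; qb <- 1 - pb
  D <- P[1] * P[4] - P[2] * P[3]
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    return(list(Delta = unname(D), r2 = NA_real_, Dprime = NA_real_,
                p_a = unname(pa), p_b = unname(pb)))
  r2 <- D^2 / (pa * qa * pb * qb)
  Dmax <- if (D >= 0) min(pa * qb, qa * pb) else min(pa * pb, qa * qb)
  list(Delta = unname(D), r2 = unname(r2), Dprime = unname(D / Dmax),
       p_a = unname(pa), p_b = unname(pb))
}

#' Parametric LD decay over all gene pairs of a chromosome
#'
#' For every pair of genes on one chromosome, computes the gametic-pool
#' r-squared of the founder population (from the two-population-cross
#' formula) and after n generations of random mating (geometric Delta
#' decay) or selfing (10-state recursion), and summarizes the average
#' percent change.  The summary is the unweighted mean of the per-pair
#' percent changes.
#'
#' @param map a `gene_map`.
#' @param p1,p2 per-gene allele frequencies of the two parental
#'   linkage-equilibrium populations (length `map$n_genes`).
#' @param scheme `"random"` or `"selfing"`.
#' @param n number of generations.
#' @param chromosome which chromosome to summarize.
#' @return list with `pairs` (data frame: gene_i, gene_j, distance_cM, r,
#'   Delta0, r2_0, r2_n, pct_change) and `avg_pct_change`.
#' @export
ld_decay_summary <- function(map, p1, p2, scheme = c("random", "selfing"),
                             n = 10, chromosome = 1) {
  scheme <- match.arg(scheme)
  idx <- which(map$chrom == chromosome)
  if (length(idx) < 2) stop("need at least two genes on the chromosome")
  pr <- t(utils::combn(idx, 2))
  res <- lapply(seq_len(nrow(pr)), function(k) {
    i <- pr[k, 1]; j <- pr[k, 2]
    d <- abs(map$pos_cM[i] - map$pos_cM[j])
    r <- recombination_fraction(d)
    P0 <- founder_hap_freqs(p1[i], p2[i], p1[j], p2[j], r)
    m0 <- ld_metrics(P0)
    Pn <- if (scheme == "random") {
      Dn <- delta_random_mating(m0$Delta, r, n)
      pa <- m0$p_a; pb <- m0$p_b
      c(pa * pb + Dn, pa * (1 - pb) - Dn, (1 - pa) * pb - Dn,
        (1 - pa) * (1 - pb) + Dn)
    } else {
      hap_frequencies(selfing_two_locus_recursion(two_locus_dist(P0, r), r, n))
    }
    mn <- ld_metrics(Pn)
    data.frame(gene_i = i, gene_j = j, distance_cM = d, r = r,
               Delta0 = m0$Delta, r2_0 = m0$r2, r2_n = mn$r2,
               pct_change = 100 * (mn$r2 - m0$r2) / m0$r2)
  })
  pairs <- do.call(rbind, res)
  list(pairs = pairs, avg_pct_change = mean(pairs$pct_change, na.rm = TRUE))
}

#' Pairwise LD matrix of a chromosome
#'
#' Symmetric gene-by-gene matrix of a founder LD statistic over one
#' chromosome, suitable for heatmap display or CSV export.
#'
#' @param map a `gene_map`.
#' @param p1,p2 per-gene parental allele frequencies.
#' @param stat `"r2"`, `"Dprime"` or `"Delta"`.
#' @param chromosome which chromosome.
#' @param path optional CSV file to write.
#' @return numeric matrix (diagonal NA), invisibly when written to file.
#' @export
ld_matrix <- function(map, p1, p2, stat = c("r2", "Dprime", "Delta"),
                      chromosome = 1, path = NULL) {
  stat <- match.arg(stat)
  idx <- which(map$chrom == chromosome)
  n <- length(idx)
  M <- matrix(NA_real_, n, n)
  s <- ld_decay_summary(map, p1, p2, "random", n = 0,
                        chromosome = chromosome)$pairs
  for (k in seq_len(nrow(s))) {
    i <- match(s$gene_i[k], idx); j <- match(s$gene_j[k], idx)
    v <- switch(stat, r2 = s$r2_0[k], Delta = s$Delta0[k],
                Dprime = {
                  r <- s$r[k]
                  m <- ld_metrics(founder_hap_freqs(
                    p1[s$gene_i[k]], p2[s$gene_i[k]],
                    p1[s$gene_j[k]], p2[s$gene_j[k]], r))
                  m$Dprime
                })
    M[i, j] <- M[j, i] <- v
  }
  dimnames(M) <- list(idx, idx)
  if (is.null(path)) return(M)
  utils::write.csv(M, path)
  invisible(M)
}
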