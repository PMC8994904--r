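# shared fixture builders (everything generated in code)

# random valid haplotype-frequency vector with interior allele frequencies
random_hap_freqs <- function() {
  repeat {
    h <- stats::rgamma(4, 2)
    h <- h / sum(h)
    m <- ld_metrics(h)
    if (min(m$p_a, m$p_b) > 0.05 && max(m$p_a, m$p_b) < 0.95) return(h)
  }
}

# random pair-effects list for grid construction
random_pair_effects <- function(hap) {
  m <- ld_metrics(hap)
  list(m_a = stats::runif(1, -1, 1), a_a = stats::runif(1, 0.5, 2),
       d_a = stats::runif(1, 0, 1.2),
       m_b = stats::runif(1, -1, 1), a_b = stats::runif(1, 0.5, 2),
       d_b = stats::runif(1, 0, 1.2),
       p_a = m$p_a, p_b = m$p_b)
}

# epistatic variance (variance of AA+AD+DA+DD) of an effect set under dist
epistatic_value_variance <- function(es, dist) {
  V <- parametric_components(es, dist)$cov[c("AA", "AD", "DA", "DD"),
                                           c("AA", "AD", "DA", "DD")]
  sum(V)
}

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g",
                              object, tol, expected))
}
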