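# Independent oracle: a literal transcription of the kappa definition,
# computed per-item with plain floating point -- deliberately a different
# code path from the package's pooled integer-sum implementation.
naive_fleiss <- function(m) {
  n <- sum(m[1, ])
  N <- nrow(m)
  P_i <- apply(m, 1, function(row) (sum(row^2) - n) / (n * (n - 1)))
  p_bar <- mean(P_i)
  p_j <- colSums(m) / (n * N)
  p_e <- sum(p_j^2)
  list(p_bar = p_bar, p_e = p_e,
       kappa = if (p_e == 1) NA_real_ else (p_bar - p_e) / (1 - p_e))
}

# Random count matrix: N pairs, n raters, l levels, rows multinomial.
random_counts <- function(N, n, l = 5) {
  probs <- as.vector(stats::rgamma(l, shape = 0.5) + 1e-6)
  m <- t(stats::rmultinom(N, size = n, prob = probs / sum(probs)))
  colnames(m) <- as.character(seq_len(l) - 1)
  attr(m, "n_raters") <- n
  m
}

# Long two-rater ratings table from explicit code pairs.
make_ratings <- function(codes_a, codes_b, prefix = "d") {
  n <- length(codes_a)
  ids_u <- sprintf("%sA%03d", prefix, seq_len(n))
  ids_v <- sprintf("%sB%03d", prefix, seq_len(n))
  dplyr::bind_rows(
    tibble::tibble(drug_u = ids_u, drug_v = ids_v,
                   rater = "edic_a", code = as.integer(codes_a)),
    tibble::tibble(drug_u = ids_u, drug_v = ids_v,
                   rater = "edic_b", code = as.integer(codes_b))
  )
}

# Catalog with the study's printed ATC Level-2 subcategory sizes.
paper_sized_catalog <- function() {
  synthetic_catalog(generator_spec(seed = 1L))
}
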