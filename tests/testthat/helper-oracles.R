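# shared fixtures and independent brute-force oracles

# the worked 3-gene / 3-sample example
toy_matrix <- function() {
  matrix(c(1, 2, 3,
           2, 1, 3,
           1, 3, 2),
         nrow = 3,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
}

random_expr <- function(n_genes, n_samples, seed, prefix = "g") {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 8, 2), n_genes,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# explicit per-pair majority vote over class samples (loops, no vectorization)
oracle_template_bits <- function(x) {
  genes <- sort(rownames(x))
  k <- length(genes)
  bits <- integer(0)
  probs <- numeric(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- mean(x[genes[i], ] < x[genes[j], ])
      probs <- c(probs, p)
      bits <- c(bits, as.integer(p > 0.5))
    }
  }
  list(probabilities = probs, bits = bits)
}

# per-sample comparison bits by loops
oracle_sample_bits <- function(v) {
  genes <- sort(names(v))
  k <- length(genes)
  bits <- integer(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      bits <- c(bits, as.integer(v[genes[i]] < v[genes[j]]))
    }
  }
  bits
}

oracle_rms <- function(v_bits, t_bits) {
  agree <- 0
  for (p in seq_along(t_bits)) if (v_bits[p] == t_bits[p]) agree <- agree + 1
  agree / length(t_bits)
}

# random strictly increasing scalar transform (positive inputs assumed where
# needed); returns a vectorized function
random_monotone <- function(seed) {
  set.seed(seed)
  kind <- sample(4, 1)
  a <- runif(1, 0.5, 2); b <- runif(1, -3, 3)
  switch(kind,
         function(x) a * x + b,
         function(x) log(x - min(x) + 1) * a + b,
         function(x) (x - min(x) + 1)^1.7 * a + b,
         function(x) exp(x / (max(x) - min(x) + 1)) * a + b)
}

expect_bits_equal <- function(a, b) expect_identical(as.integer(a), as.integer(b))

# small labelled expression object with a planted tight set in class A
small_regulated_expr <- function(seed = 1, n_per_class = 12, set_size = 8,
                                 sigma = 0.3) {
  cfg <- sim_config(n_per_class = n_per_class, n_background = 30,
                    sets = list(list(name = "S1", size = set_size,
                                     regulation = c(A = "tight", B = "loose"),
                                     delta = 1.5, sigma = sigma),
                                list(name = "S2", size = set_size,
                                     regulation = c(A = "loose", B = "loose"),
                                     delta = 1.5, sigma = sigma)),
                    test_fraction = 0)
  generate_dataset(cfg, seed = seed)
}

# access to the internal vectorized bit builder for enumeration tests
pair_bits_of <- function(x, pairs) diracnet:::pair_bits(x, pairs)
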