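# Shared fixtures and independent oracles, built in code at test time.

toy_tree_text <- c("mt-MRCA", "\tH\t2706A 7028C", "\t\tH1\t3010A")

# A small random reference whose bases at the toy tree's positions are
# forced to differ from the derived alleles, so derived vs reference is
# always distinguishable.
toy_reference <- function(len = 8000L, seed = 42L) {
  seq <- mitodemix:::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                                  replace = TRUE), collapse = ""))
  substr(seq, 2706, 2706) <- "G"  # derived A
  substr(seq, 7028, 7028) <- "T"  # derived C
  substr(seq, 3010, 3010) <- "G"  # derived A
  mito_reference(seq, name = "toyMT")
}

toy_tree <- function(reference = toy_reference()) {
  parse_phylotree(toy_tree_text, reference = reference)
}

# Independent dynamic-programming oracle for the edit distance.
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + (ca[i] != cb[j]))
    }
  }
  D[n + 1, m + 1]
}

random_dna <- function(n, len, seed) {
  mitodemix:::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)))
}

# Brute-force mixture-likelihood maximiser over a simplex grid, independent
# of the EM path. L is the fragments x candidates log-likelihood matrix.
grid_best_pi <- function(L, step = 0.001) {
  P <- exp(L - apply(L, 1, max))        # row-rescaled likelihoods
  H <- ncol(L)
  ll_of <- function(G) {                 # G: grid points x H
    # sum over fragments of log(P %*% pi), in chunks to bound memory
    out <- numeric(nrow(G))
    chunk <- 50000L
    for (s in seq(1L, nrow(G), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(G))
      M <- G[s:e, , drop = FALSE] %*% t(P)   # points x fragments
      out[s:e] <- rowSums(log(M))
    }
    out
  }
  if (H == 2L) {
    p <- seq(0, 1, by = step)
    G <- cbind(p, 1 - p)
  } else if (H == 3L) {
    k <- round(1 / step)
    ij <- expand.grid(i = 0:k, j = 0:k)
    ij <- ij[ij$i + ij$j <= k, ]
    G <- cbind(ij$i, ij$j, k - ij$i - ij$j) / k
  } else stop("grid oracle supports 2 or 3 candidates")
  ll <- ll_of(G)
  G[which.max(ll), ]
}

# A two-source synthetic mixture plus merged fragments and observations.
quick_mixture <- function(h1, h2, n1, n2, seed, tree, ref, ...) {
  s1 <- simulate_sole_source(ref, tree, haplogroup = h1, n_fragments = n1,
                             seed = mitodemix:::derive_seed(seed, 1), ...)
  s2 <- simulate_sole_source(ref, tree, haplogroup = h2, n_fragments = n2,
                             seed = mitodemix:::derive_seed(seed, 2), ...)
  mix <- mix_fastqs(list(s1, s2), ratio = c(n1, n2), total = n1 + n2,
                    seed = mitodemix:::derive_seed(seed, 3))
  pre <- correct_pairs(mix$pairs)
  fr <- merge_pairs(pre)
  obs <- build_observations(fr, tree, ref)
  list(mix = mix, obs = obs)
}
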