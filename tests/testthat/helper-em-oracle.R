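# Independent brute-force EM oracle: enumerates ALL 2^S haplotypes and all
# ordered haplotype pairs per individual, with no sharing of code or data
# structures with the package implementation. Only feasible for small S.
em_oracle <- function(geno, tol = 1e-13, max_iter = 20000) {
  geno <- as.matrix(geno)
  S <- ncol(geno)
  stopifnot(S <= 12, !anyNA(geno))
  n_hap <- 2^S
  alle <- matrix(0L, n_hap, S)
  for (h in seq_len(n_hap)) {
    x <- h - 1L
    for (s in S:1) { alle[h, s] <- x %% 2L; x <- x %/% 2L }
  }
  hap_names <- apply(alle, 1, paste, collapse = "")
  N <- nrow(geno)
  f <- rep(1 / n_hap, n_hap)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    counts <- numeric(n_hap)
    ll <- 0
    for (ind in seq_len(N)) {
      g <- geno[ind, ]
      w <- matrix(0, n_hap, n_hap)
      for (i in seq_len(n_hap)) for (j in seq_len(n_hap)) {
        if (all(alle[i, ] + alle[j, ] == g)) w[i, j] <- f[i] * f[j]
      }
      lik <- sum(w)
      ll <- ll + log(lik)
      post <- w / lik
      counts <- counts + rowSums(post) + colSums(post)
    }
    trace <- c(trace, ll)
    f_new <- counts / (2 * N)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  list(frequencies = stats::setNames(f, hap_names), loglik_trace = trace)
}

# draw a dosage matrix from known haplotype frequencies (random pairing)
sim_geno_from_freqs <- function(freqs, n) {
  haps <- names(freqs)
  h1 <- sample(haps, n, replace = TRUE, prob = freqs)
  h2 <- sample(haps, n, replace = TRUE, prob = freqs)
  a <- function(h) do.call(rbind, lapply(strsplit(h, ""), as.integer))
  g <- a(h1) + a(h2)
  rownames(g) <- sprintf("i%d", seq_len(n))
  g
}
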