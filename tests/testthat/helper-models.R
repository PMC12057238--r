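# Small fixed models and an enumeration oracle kept deliberately independent
# of the package's own state-probability code (explicit loops, no matrix
# algebra shortcuts).

two_node <- function(tau = c(0, 0), w = 0) {
  ising_model(tau, matrix(c(0, w, w, 0), 2), labels = c("a", "b"))
}

chain3 <- function(tau = c(-1, 0, 1), w12 = 1.5, w13 = 0, w23 = 0) {
  om <- matrix(0, 3, 3)
  om[1, 2] <- om[2, 1] <- w12
  om[1, 3] <- om[3, 1] <- w13
  om[2, 3] <- om[3, 2] <- w23
  ising_model(tau, om, labels = c("a", "b", "c"))
}

# brute-force Boltzmann probabilities over {0,1}^p via explicit loops
oracle_probs <- function(tau, omega) {
  p <- length(tau)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  w <- numeric(nrow(states))
  for (s in seq_len(nrow(states))) {
    x <- states[s, ]
    e <- 0
    for (i in seq_len(p)) {
      e <- e + tau[i] * x[i]
      if (i < p) for (j in (i + 1):p) e <- e + omega[i, j] * x[i] * x[j]
    }
    w[s] <- exp(e)
  }
  list(states = states, probs = w / sum(w))
}

# match empirical state frequencies against a probability table
state_key <- function(m) apply(m, 1, paste, collapse = "")

# binary matrix with independent Bernoulli columns
bernoulli_matrix <- function(n, p, prob = 0.5, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * p, 1, prob), n, p)
  colnames(m) <- paste0("V", seq_len(p))
  m
}
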