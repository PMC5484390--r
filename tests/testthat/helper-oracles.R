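# Independent oracles used to check the network simulation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact choice distribution of the CONF-type race by forward enumeration of
# the absorbing Markov chain. Under identify-best sublayers, equal weights w
# and Q = k*w with perfect memory, the network state reduces to a vector of
# per-alternative counts of "best on the sampled attribute" events;
# sampling attribute j (with replacement) increments the count of that
# attribute's best alternative b_j, and the chain absorbs the first time a
# count reaches k. This enumerates all count states reachable before
# absorption, which is finite (every count < k), so the distribution is
# exact.
conf_exact_distribution <- function(best, n_alt, k = 2L, probs = NULL) {
  M <- length(best)
  if (is.null(probs)) probs <- rep(1 / M, M)
  absorb <- numeric(n_alt)
  cur <- list()
  cur[[paste(integer(n_alt), collapse = ",")]] <- 1
  while (length(cur)) {
    nxt <- list()
    for (key in names(cur)) {
      p <- cur[[key]]
      counts <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      for (j in seq_len(M)) {
        b <- best[j]
        c2 <- counts
        c2[b] <- c2[b] + 1L
        if (c2[b] >= k) {
          absorb[b] <- absorb[b] + p * probs[j]
        } else {
          k2 <- paste(c2, collapse = ",")
          nxt[[k2]] <- (nxt[[k2]] %||% 0) + p * probs[j]
        }
      }
    }
    cur <- nxt
  }
  absorb
}

# Equilibrium of two interacting unsaturated nodes with the third clamped at
# zero: solves alpha1 = x1 - l*alpha2, alpha2 = x2 - l*alpha1 in closed form.
two_node_equilibrium <- function(x1, x2, l) {
  c((x1 - l * x2) / (1 - l^2), (x2 - l * x1) / (1 - l^2))
}

# A small standard choice set used across tests.
toy_set_2x2 <- function() {
  choice_set(rbind(c(0.8, 0.2), c(0.4, 0.9)), weights = c(0.03, 0.015))
}

canonical_inputs <- c(0.75, 0.5, 0.25)

canonical_set <- function() {
  choice_set(matrix(canonical_inputs, ncol = 1), weights = 1)
}
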