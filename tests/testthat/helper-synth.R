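# Small in-code fixtures shared across test files.

# A trial tensor built directly from a deterministic function of the indices
# (no session generation): D[t, v, a, r, c] = f(t, v, a, r, c).
toy_tensor <- function(nt, nv, na, nr, nc, f,
                       channel_kind = "neuron") {
  D <- array(0, dim = c(nt, nv, na, nr, nc))
  for (t in seq_len(nt)) for (v in seq_len(nv)) for (a in seq_len(na))
    for (r in seq_len(nr)) for (c in seq_len(nc))
      D[t, v, a, r, c] <- f(t, v, a, r, c)
  structure(D, class = "trial_tensor", bin_size = 0.03,
            window = c(-1, -1 + 0.03 * nt),
            rel_times = (round(-1 / 0.03) + 0:(nt - 1)) * 0.03,
            channel_kind = channel_kind,
            channel_ids = as.character(seq_len(nc)))
}

# Random trial tensor with attributes set; rel_times start at -1 s.
random_tensor <- function(nt, nv, na, nr, nc, sd = 1, seed = NULL,
                          channel_kind = "neuron") {
  if (!is.null(seed)) set.seed(seed)
  D <- array(rnorm(nt * nv * na * nr * nc, sd = sd),
             dim = c(nt, nv, na, nr, nc))
  structure(D, class = "trial_tensor", bin_size = 0.03,
            window = c(-1, -1 + 0.03 * nt),
            rel_times = (round(-1 / 0.03) + 0:(nt - 1)) * 0.03,
            channel_kind = channel_kind,
            channel_ids = as.character(seq_len(nc)))
}

# A tensor whose window matches the standard analysis (-1, 3.8): 160 bins,
# of which the last 127 are the encoding bins.
analysis_tensor <- function(nv, na, nr, nc, sd = 1, seed = NULL,
                            channel_kind = "neuron") {
  random_tensor(160, nv, na, nr, nc, sd = sd, seed = seed,
                channel_kind = channel_kind)
}

# Brute-force marginalization by explicit loops (independent oracle).
marginalize_bruteforce <- function(D) {
  d <- dim(D)
  nt <- d[1]; nv <- d[2]; na <- d[3]; nr <- d[4]; nc <- d[5]
  M <- array(0, c(nt, nc))
  V <- array(0, c(nt, nv, nc)); A <- array(0, c(nt, na, nc))
  I <- array(0, c(nt, nv, na, nc)); E <- array(0, dim = d)
  for (t in seq_len(nt)) for (c in seq_len(nc)) {
    M[t, c] <- mean(D[t, , , , c])
    for (v in seq_len(nv)) V[t, v, c] <- mean(D[t, v, , , c]) - M[t, c]
    for (a in seq_len(na)) A[t, a, c] <- mean(D[t, , a, , c]) - M[t, c]
    for (v in seq_len(nv)) for (a in seq_len(na)) {
      pav <- mean(D[t, v, a, , c])
      I[t, v, a, c] <- pav - M[t, c] - V[t, v, c] - A[t, a, c]
      for (r in seq_len(nr)) E[t, v, a, r, c] <- D[t, v, a, r, c] - pav
    }
  }
  list(M = M, V = V, A = A, I = I, E = E)
}

# Train/test marginal components of a tensor (convenience).
half_marginals <- function(D, split = repeat_split(dim(D)[4])) {
  list(train = marginalize(D[, , , split$train, , drop = FALSE]),
       test = marginalize(D[, , , split$test, , drop = FALSE]))
}
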