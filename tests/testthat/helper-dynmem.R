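# shared fixtures: everything is generated in code under fixed seeds

orth_pair <- function(N, seed = 1) {
  st <- seed_streams(seed)
  orthonormalize_item(sample_memory(st, N, orthonormal = TRUE))
}

# scalar triple-loop references for the plasticity terms (independent oracles)
ref_rate_control <- function(x, W, phi0) {
  N <- length(x)
  out <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    out[i, j] <- (phi0[i] - tanh(x[i])) * tanh(x[j]) * W[i, j]
  }
  out
}

ref_decorrelation <- function(x, xbar) {
  N <- length(x)
  out <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    out[i, j] <- (i == j) - tanh(x[i] - xbar[i]) * tanh(x[j])
  }
  out
}

ref_stdp <- function(phi_x, yP, yD, a_P, a_D) {
  N <- length(phi_x)
  out <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    out[i, j] <- a_P * phi_x[i] * yP[j] + a_D * phi_x[j] * yD[i]
  }
  out
}

ref_dissipation <- function(W, beta) {
  out <- W
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) out[i, j] <- -beta * W[i, j]
  out
}
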