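# fixtures built in code: seeded random images and tiny oracles

rand_img <- function(M, N = M, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(stats::runif(M * N, lo, hi), M, N)
}

const_img <- function(v, M = 16, N = M) matrix(v, M, N)

# circular shift of a matrix by (dr, dc)
circshift <- function(m, dr = 0, dc = 0) {
  M <- nrow(m); N <- ncol(m)
  ri <- ((seq_len(M) - 1 - dr) %% M) + 1
  ci <- ((seq_len(N) - 1 - dc) %% N) + 1
  m[ri, ci, drop = FALSE]
}

# O(N^4) brute-force forward DFT: F(u,v) = sum f(m,n) e^{-2i pi (um/M + vn/N)}
brute_dft2 <- function(x) {
  M <- nrow(x); N <- ncol(x)
  out <- matrix(0 + 0i, M, N)
  for (u in 0:(M - 1)) {
    for (v in 0:(N - 1)) {
      s <- 0 + 0i
      for (m in 0:(M - 1)) {
        for (n in 0:(N - 1)) {
          s <- s + x[m + 1, n + 1] * exp(-2i * pi * (u * m / M + v * n / N))
        }
      }
      out[u + 1, v + 1] <- s
    }
  }
  out
}

# O(N^4) brute-force normalized inverse DFT
brute_idft2 <- function(Fc) {
  M <- nrow(Fc); N <- ncol(Fc)
  out <- matrix(0 + 0i, M, N)
  for (a in 0:(M - 1)) {
    for (b in 0:(N - 1)) {
      s <- 0 + 0i
      for (k in 0:(M - 1)) {
        for (l in 0:(N - 1)) {
          s <- s + Fc[k + 1, l + 1] * exp(2i * pi * (k * a / M + l * b / N))
        }
      }
      out[a + 1, b + 1] <- s / (M * N)
    }
  }
  out
}

# a step-edge image (dark left half, bright right half)
step_img <- function(M = 16, N = M, lo = 100, hi = 150) {
  cbind(matrix(lo, M, N %/% 2), matrix(hi, M, N - N %/% 2))
}
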