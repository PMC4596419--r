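# Shared fixtures (memoized across test files: helpers load once per run)
# and independent oracles used by the tests.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixture_env)) assign(name, maker(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 120-gene trio with outgroup and the default xenolog plan
trio_small <- function() fixture("trio_small", function() {
  simulate_trio(trio_config(seed = 11, genome_length = 1.2e5, n_genes = 120,
                            d_outgroup = 0.08))
})

# 60-gene xenolog-free trio for conservation/synteny checks
trio_plain <- function() fixture("trio_plain", function() {
  simulate_trio(trio_config(seed = 3, genome_length = 6e4, n_genes = 60,
                            xenolog_plan = NULL))
})

# Exhaustive affine-gap Smith-Waterman (independent of the package path):
# gap of length L costs open + ext * L, matching the package convention.
sw_oracle <- function(a, b, open = 11, ext = 1) {
  mat <- get_blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

get_blosum62 <- function() fixture("blosum62", function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Quadratic longest strictly increasing subsequence
lis_oracle <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  dp <- rep(1L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (x[j] < x[i]) dp[i] <- max(dp[i], dp[j] + 1L)
  max(dp)
}

# deterministic sequence with an exact GC fraction (for constructed fixtures)
seq_with_gc <- function(len, gc) {
  n_gc <- round(len * gc)
  paste(c(rep(c("G", "C"), length.out = n_gc),
          rep(c("A", "T"), length.out = len - n_gc)), collapse = "")
}

# random protein helper
random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# p-distance between two genome base vectors
pdist_vec <- function(a, b) mean(a != b)
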