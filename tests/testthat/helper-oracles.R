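# Independent oracles used to validate the package's core numerics.

# Plain-R affine-gap global alignment score, written independently of the
# compiled aligner (same scoring convention: match/mismatch, a gap of length L
# costs open + L * extend, N is neutral). Score only.
nw_score_oracle <- function(a, b, match = 5, mismatch = -4, open = 10,
                            ext = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  sub <- function(x, y) if (x == "N" || y == "N") 0 else
    if (x == y) match else mismatch
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub(a[i], b[j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                           X[i + 1, j] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exact Mann-Whitney p by full enumeration of all group labelings (no ties).
mw_exact_oracle <- function(x, y,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  nx <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge,
              less = p_le)
  list(U = u_obs, p = p)
}

# Small single-codon design: ATG AAA CCA GGT, region = codons 2-3.
tiny_design <- function(scheme = "NNN") {
  library_design("ATGAAACCAGGT", 2, 3, scheme = scheme)
}
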