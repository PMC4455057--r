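# Independent oracles used by the equivalence tests. Deliberately naive
# implementations: quadratic dynamic programming, union-find, closed-form
# statistics. They share no code with the package internals they check.

# Smith-Waterman with affine gaps (gap of length L costs open + L * ext),
# returning the optimal local alignment score.
sw_score_oracle <- function(a, b, mat, open = 11, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)    # ends in a match/mismatch
  Ix <- matrix(-Inf, n + 1, m + 1) # gap in y (consumes x)
  Iy <- matrix(-Inf, n + 1, m + 1) # gap in x (consumes y)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[x[i - 1], y[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                   Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    best <- max(best, M[i, j])
  }
  best
}

# Ungapped local alignment oracle for two equal-length indel-free
# sequences: enumerates every main-diagonal segment, returns the optimal
# score and the (identity, span) of every co-optimal segment — local
# alignments can tie, so the implementation must match one of them.
diagonal_oracle <- function(a, b, mat) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  s <- vapply(seq_along(x), function(i) mat[x[i], y[i]], 0)
  cs <- cumsum(c(0, s))
  n <- length(s)
  best <- 0; opts <- list()
  for (i in 1:n) for (j in i:n) {
    sc <- cs[j + 1] - cs[i]
    if (sc > best) { best <- sc; opts <- list() }
    if (sc == best && best > 0)
      opts[[length(opts) + 1L]] <-
        list(identity = 100 * mean(x[i:j] == y[i:j]), span = j - i + 1L)
  }
  list(score = best, optima = opts)
}

# Connected components by union-find.
union_find_components <- function(vertices, edges) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges$from[k]); rb <- find(edges$to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(vertices, find, "")
  unname(lapply(split(vertices, roots), sort))
}

# Pearson chi-square on a 2x2 table, closed form, upper tail at 1 df.
chi2_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# The search stage's scoring matrix (BLOSUM62 with X zeroed), fetched the
# same way a user would.
oracle_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), n,
               replace = TRUE), collapse = "")
}

# Mutate a fraction of positions to a different residue (no indels).
mutate_protein <- function(seq, rate) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  x <- strsplit(seq, "")[[1]]
  hit <- runif(length(x)) < rate
  x[hit] <- vapply(x[hit], function(ch)
    sample(setdiff(aa, ch), 1L), "")
  paste(x, collapse = "")
}
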