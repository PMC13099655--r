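# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic stages route through
# this so that a single integer seed makes them bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and an index, kept within 32-bit
# integer range. Deterministic and collision-poor for the scales used here.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %% 2147483647L)
}

# Polygon area by the shoelace formula (vertices in order, not closed).
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# Shannon diversity (nats) of a vector of category labels or counts.
shannon_entropy <- function(x) {
  counts <- if (is.numeric(x)) x else as.numeric(table(x))
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log(p))
}

cosine_similarity <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) return(NA_real_)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Squared Euclidean cross-distance matrix between two coordinate matrices.
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

cross_dist <- function(a, b) {
  d2 <- cross_dist2(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
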