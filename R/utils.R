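# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit,
# so package functions never clobber a user's random stream.
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

# Sample from a log-normal distribution truncated to [lo, hi] by inverse-CDF.
rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  u <- stats::runif(n, plo, phi)
  stats::qlnorm(u, meanlog, sdlog)
}

# Population skewness m3 / m2^(3/2); NA for (near-)constant input.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Largest-remainder apportionment of n items to the given fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

# Controlled rounding of a labels-by-subsets allocation: returns an integer
# matrix whose rows sum to the label sizes, whose columns sum to the global
# largest-remainder apportionment of sum(sizes), and whose every cell is
# within 1 of size * fraction. Each row's extras (above the cell floors) are
# placed by augmenting-path matching (Kuhn-style) over the columns' remaining
# capacity, restricted to cells with a positive fractional remainder, so the
# {floor, floor + 1} cell bound is kept whenever a feasible rounding exists.
controlled_round <- function(sizes, fractions) {
  L <- length(sizes)
  S <- length(fractions)
  raw <- outer(sizes, fractions)
  counts <- floor(raw)
  rem <- raw - counts
  need <- as.integer(round(sizes - rowSums(counts)))
  cap <- apportion(sum(sizes), fractions) - colSums(counts)
  grant <- matrix(0L, L, S)
  try_assign <- function(l, visited) {
    ord_s <- order(rem[l, ], decreasing = TRUE)
    open <- function(s) rem[l, s] > 1e-9 && grant[l, s] == 0L && !(s %in% visited)
    for (s in ord_s) {
      if (open(s) && sum(grant[, s]) < cap[s]) {
        grant[l, s] <<- 1L
        return(TRUE)
      }
    }
    for (s in ord_s) {
      if (!open(s)) next
      for (h in which(grant[, s] == 1L)) {
        grant[h, s] <<- 0L
        if (try_assign(h, c(visited, s))) {
          grant[l, s] <<- 1L
          return(TRUE)
        }
        grant[h, s] <<- 1L
      }
    }
    FALSE
  }
  for (l in rep(seq_len(L), need)) {
    if (!try_assign(l, integer(0))) {
      # no feasible {floor, floor+1} placement (not expected): relax the bound
      s <- which(colSums(grant) < cap)[1]
      counts[l, s] <- counts[l, s] + 1L
    }
  }
  counts <- counts + grant
  dimnames(counts) <- list(names(sizes), names(fractions))
  counts
}
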