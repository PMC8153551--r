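# Independent brute-force oracles used by the property tests.

# Exhaustive left-to-right edit-script search for the block-transposition
# edit distance: memoized recursion over suffix pairs, trying every
# operation (match/substitute, delete, insert, block swap) at each step.
oracle_mdld <- function(a, b, block_limit = 2L) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  m <- length(av)
  n <- length(bv)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  rec <- function(i, j) {
    if (i > m) return(n - j + 1L)
    if (j > n) return(m - i + 1L)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1L, j + 1L) + (if (av[i] == bv[j]) 0L else 1L)
    d <- rec(i + 1L, j) + 1L
    if (d < best) best <- d
    d <- rec(i, j + 1L) + 1L
    if (d < best) best <- d
    for (k in seq_len(block_limit)) {
      if (i + 2L * k - 1L <= m && j + 2L * k - 1L <= n &&
          all(av[i:(i + k - 1L)] == bv[(j + k):(j + 2L * k - 1L)]) &&
          all(av[(i + k):(i + 2L * k - 1L)] == bv[j:(j + k - 1L)])) {
        d <- rec(i + 2L * k, j + 2L * k) + k
        if (d < best) best <- d
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L)
}

# all strings over `alphabet` of length 0..max_len
all_strings <- function(alphabet, max_len) {
  out <- ""
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, c(rep(list(alphabet), L),
                                   stringsAsFactors = FALSE))
    out <- c(out, apply(grid, 1L, paste, collapse = ""))
  }
  out
}

# blank-locked edit distance by plain recursion (no matrices) for the
# query-correction oracle; Inf when the blank constraints cannot be met or
# the cost exceeds `budget`
oracle_blank_locked <- function(a, b, budget = 3) {
  if (budget < abs(nchar(a) - nchar(b))) return(Inf)
  if (!nzchar(a)) {
    return(if (grepl(" ", b, fixed = TRUE)) Inf else nchar(b))
  }
  if (!nzchar(b)) {
    return(if (grepl(" ", a, fixed = TRUE)) Inf else nchar(a))
  }
  ha <- substr(a, 1L, 1L)
  hb <- substr(b, 1L, 1L)
  ta <- substr(a, 2L, nchar(a))
  tb <- substr(b, 2L, nchar(b))
  best <- Inf
  if (ha == hb) {
    best <- oracle_blank_locked(ta, tb, budget)
  } else if (budget >= 1) {
    if (ha != " " && hb != " ") {
      best <- oracle_blank_locked(ta, tb, budget - 1) + 1
    }
    if (ha != " ") best <- min(best, oracle_blank_locked(ta, b, budget - 1) + 1)
    if (hb != " ") best <- min(best, oracle_blank_locked(a, tb, budget - 1) + 1)
  }
  best
}

# minimum constrained correction cost over every window of every name,
# scanning lengths nchar(q)-1 .. nchar(q)+1
oracle_query_cost <- function(q, names_all, cap = 2L) {
  ql <- tolower(q)
  nq <- nchar(ql)
  best <- Inf
  for (nm in tolower(names_all)) {
    nn <- nchar(nm)
    for (L in (nq - 1L):(nq + 1L)) {
      if (L < 1L || L > nn) next
      for (s in seq_len(nn - L + 1L)) {
        w <- substr(nm, s, s + L - 1L)
        cost <- oracle_blank_locked(ql, w)
        if (cost < best) best <- cost
      }
    }
  }
  if (best > cap) Inf else best
}
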