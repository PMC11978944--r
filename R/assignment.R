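# Hungarian algorithm (shortest augmenting path with potentials) for the
# rectangular min-cost assignment problems arising in frame-to-frame bubble
# linking. Cost matrices here are tiny (tens of rows), so an O(n^3) pure-R
# solver is adequate.

# cost: n x m matrix, n <= m (pad beforehand otherwise).
# Returns integer vector a with a[i] = column assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n)
  v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j] = row matched to column j (0 = free)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    way <- integer(m)
    used <- logical(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[seq_len(m)]
      upd <- !used[seq_len(m)] & cur < minv
      minv[upd] <- cur[upd]
      way[upd] <- j0
      free <- which(!used[seq_len(m)])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) a[p[j]] <- j
  a
}

# Brute-force reference: enumerate all permutations (n <= 7). Used only by
# tests as the independent oracle.
assignment_brute_force <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], rest)
    out
  }
  best <- NULL; best_cost <- Inf
  for (pm in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), pm)])
    if (cc < best_cost) { best_cost <- cc; best <- pm }
  }
  list(assignment = best, cost = best_cost)
}
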