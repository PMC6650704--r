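# Shared fixtures and independent oracles, all built in code.

# random directed binary adjacency matrix
rand_digraph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  adj <- matrix(rbinom(n * n, 1L, p), n, n)
  diag(adj) <- 0L
  dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  adj
}

# random directed count adjacency matrix
rand_countgraph <- function(n, lambda = 1.2, seed = 1) {
  set.seed(seed)
  adj <- matrix(rpois(n * n, lambda), n, n)
  diag(adj) <- 0L
  dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  adj
}

rand_attrs <- function(ids, seed = 1) {
  set.seed(seed)
  data.frame(id = ids,
             sex = sample(c("male", "female"), length(ids), replace = TRUE),
             age_class = sample(c("adult", "subadult", "juvenile"),
                                length(ids), replace = TRUE),
             stringsAsFactors = FALSE)
}

# brute-force triad counts by exhaustive ordered-triple enumeration
brute_triads <- function(adj) {
  n <- nrow(adj)
  trans <- 0L; cyc3 <- 0L
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i == j || j == k || i == k) next
    if (adj[i, j] & adj[j, k] & adj[i, k]) trans <- trans + 1L
    if (adj[i, j] & adj[j, k] & adj[k, i]) cyc3 <- cyc3 + 1L
  }
  c(transitive = trans, cyclical = cyc3 / 3)
}

# brute-force valued triad statistics (min within path, max over paths)
brute_valued_triad <- function(adj, cyclical = FALSE) {
  n <- nrow(adj)
  s <- 0
  for (p in 1:n) for (q in 1:n) {
    if (p == q) next
    base <- if (cyclical) adj[q, p] else adj[p, q]
    if (base == 0) next
    best <- 0
    for (m in 1:n) {
      if (m == p || m == q) next
      best <- max(best, min(adj[p, m], adj[m, q]))
    }
    s <- s + min(base, best)
  }
  s
}

# all permutations of 1..n as a matrix (rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(1:n, function(k) {
    rest <- (1:n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# exhaustive I&SI optimum over every ordering (oracle for small n)
brute_isi <- function(wins) {
  n <- nrow(wins)
  perms <- all_perms(n)
  best <- c(I = Inf, SI = Inf)
  for (r in seq_len(nrow(perms))) {
    sc <- inconsistencies(wins, perms[r, ])
    if (sc[1] < best[1] || (sc[1] == best[1] && sc[2] < best[2])) best <- sc
  }
  best
}

rand_wins <- function(n, seed = 1, lambda = 1.5) {
  set.seed(seed)
  w <- matrix(rpois(n * n, lambda), n, n)
  diag(w) <- 0L
  dimnames(w) <- list(letters[1:n], letters[1:n])
  w
}

# tiny interaction log used across tests
toy_log <- function() {
  interaction_log(data.frame(
    initiator = c("A", "A", "A", "B", "A", "C"),
    receiver  = c("B", "B", "B", "A", "C", "B"),
    behaviour = c("submissive", "submissive", "submissive", "submissive",
                  "aggressive", "dominance"),
    stringsAsFactors = FALSE))
}

quick_ctl <- function(seed = 1, samplesize = 300, ...) {
  ergm_control(samplesize = samplesize, seed = seed, ...)
}
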