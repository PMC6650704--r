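#' Dominance wins matrix from submissive interactions
#'
#' Submission gives the clearest winner/loser assignment in canid
#' agonistic data: the recipient of a submissive act is scored as the
#' winner of that contest. `wins[i, j]` is therefore the number of
#' submissive events initiated by `j` and received by `i`.
#'
#' @param log an `interaction_log` containing submissive events
#' @param attrs optional attribute table fixing the node set (isolates kept)
#' @return square integer matrix of win counts, ids as dimnames
#' @export
wins_matrix <- function(log, attrs = NULL) {
  stopifnot(inherits(log, "interaction_log"))
  if (!any(log$behaviour == "submissive"))
    stop("no submissive interactions in the log; cannot score contests")
  net <- build_network(log, "submissive", directed = TRUE, weighted = TRUE,
                       attrs = attrs)
  t(net$adj)
}

#' David's scores from a wins matrix
#'
#' The dyadic-proportion David's score `w + w2 - l - l2`, where `w` is
#' the sum of an individual's win proportions `P_ij`, `w2` the win
#' proportions of its victims weighted by `P_ij`, and `l`, `l2` the loss
#' counterparts. Dyads with no interactions contribute 0. Scores sum to
#' zero across individuals. Used here to initialise the inconsistency
#' minimisation.
#'
#' @param wins square matrix of win counts (zero diagonal)
#' @return named numeric vector of scores
#' @export
davids_score <- function(wins) {
  wins <- check_wins(wins)
  n <- nrow(wins)
  tot <- wins + t(wins)
  P <- matrix(0, n, n)
  nz <- tot > 0
  P[nz] <- wins[nz] / tot[nz]
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.numeric(P %*% w)
  l2 <- as.numeric(t(P) %*% l)
  setNames(w + w2 - l - l2, rownames(wins))
}

check_wins <- function(wins) {
  wins <- as.matrix(wins)
  if (nrow(wins) != ncol(wins)) stop("wins matrix must be square")
  if (any(wins < 0) || any(wins != round(wins)))
    stop("wins matrix entries must be non-negative integers")
  if (any(diag(wins) != 0)) stop("wins matrix must have a zero diagonal")
  if (is.null(rownames(wins)))
    dimnames(wins) <- list(sprintf("n%02d", seq_len(nrow(wins))),
                           sprintf("n%02d", seq_len(nrow(wins))))
  wins
}

#' Count rank-order inconsistencies
#'
#' A dyad is inconsistent under an ordering when the lower-ranked
#' individual has won strictly more contests against the higher-ranked
#' one; ties and silent dyads never count. `I` is the number of such
#' dyads and `SI` the sum of their rank differences (the strength of the
#' inconsistencies).
#'
#' @param wins wins matrix
#' @param order character vector of ids (or integer permutation), most
#'   dominant first
#' @return named numeric vector `c(I = , SI = )`
#' @export
inconsistencies <- function(wins, order) {
  wins <- check_wins(wins)
  ids <- rownames(wins)
  if (is.character(order)) {
    if (!setequal(order, ids) || length(order) != length(ids))
      stop("order must be a permutation of the matrix ids")
    ord <- match(order, ids)
  } else {
    if (!setequal(order, seq_len(nrow(wins))))
      stop("order must be a permutation of 1..n")
    ord <- as.integer(order)
  }
  w <- wins[ord, ord, drop = FALSE]
  n <- nrow(w)
  lower_wins <- t(w)[upper.tri(w)]  # wins of lower-ranked over higher
  upper_wins <- w[upper.tri(w)]
  inc <- lower_wins > upper_wins
  rd <- (col(w) - row(w))[upper.tri(w)]
  c(I = sum(inc), SI = sum(rd[inc]))
}

#' Ordinal dominance ranking by inconsistency minimisation (I&SI)
#'
#' Finds an ordering of individuals minimising, lexicographically, the
#' number of inconsistent dyads `I` and then their total strength `SI`.
#' The search starts from the descending David's score order (ties
#' broken by total wins, then id) and repeatedly sweeps the inconsistent
#' dyads, trialling a swap of the two members and a relocation of the
#' lower-ranked member to just above the higher-ranked one, keeping any
#' move that lowers `(I, SI)`; sweeps stop at a fixed point. A small
#' number of randomised restarts guards against local optima.
#'
#' @param wins wins matrix (see [wins_matrix()])
#' @param max_sweeps maximum improvement sweeps per start
#' @param restarts randomised additional starts (0 = deterministic
#'   David's-score start only)
#' @param seed integer seed for the restart shuffles
#' @return an object of class `isi_rank`: the ordering (`$order`, most
#'   dominant first; rank 1 = top), `$ranks` (named rank per id), the
#'   attained `$I` and `$SI`, and search diagnostics.
#' @export
isi_rank <- function(wins, max_sweeps = 100L, restarts = 3L, seed = 1L) {
  wins <- check_wins(wins)
  n <- nrow(wins)
  if (n < 2) stop("ranking needs at least 2 individuals")
  ids <- rownames(wins)
  ds <- davids_score(wins)
  tw <- rowSums(wins)
  start <- order(-ds, -tw, ids)
  res <- isi_sweep(wins, start, max_sweeps)
  starts_used <- 1L
  if (restarts > 0) {
    rng_local(seed, {
      for (r in seq_len(restarts)) {
        cand <- isi_sweep(wins, sample.int(n), max_sweeps)
        starts_used <- starts_used + 1L
        if (lex_better(c(cand$I, cand$SI), c(res$I, res$SI))) res <- cand
      }
    })
  }
  ord <- res$ord
  structure(list(order = ids[ord],
                 ranks = setNames(match(seq_len(n), ord), ids),
                 I = res$I, SI = res$SI,
                 sweeps = res$sweeps, restarts = starts_used - 1L,
                 wins = wins),
            class = "isi_rank")
}

lex_better <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])

# compiled fast path of inconsistencies() for the search loops
fast_is <- function(wins, ord) {
  v <- cpp_inconsistencies(wins, as.integer(ord))
  c(I = v[1], SI = v[2])
}

# one hill-climbing run from a given start order (integer permutation)
isi_sweep <- function(wins, ord, max_sweeps) {
  cur <- fast_is(wins, ord)
  sweeps <- 0L
  repeat {
    if (cur[["I"]] == 0L || sweeps >= max_sweeps) break
    sweeps <- sweeps + 1L
    improved <- FALSE
    n <- length(ord)
    for (p in seq_len(n - 1L)) {
      for (q in seq((p + 1L), n)) {
        hi <- ord[p]; lo <- ord[q]
        if (wins[lo, hi] <= wins[hi, lo]) next  # consistent or tied
        # candidate 1: swap the two members
        cand <- ord; cand[p] <- lo; cand[q] <- hi
        sc <- inconsistencies(wins, cand)
        if (lex_better(sc, cur)) { ord <- cand; cur <- sc; improved <- TRUE; next }
        # candidate 2: relocate the winner to just above the loser
        cand <- append(ord[-q], lo, after = p - 1L)
        sc <- inconsistencies(wins, cand)
        if (lex_better(sc, cur)) { ord <- cand; cur <- sc; improved <- TRUE }
      }
    }
    if (!improved) {
      # full-neighbourhood polish: SI can often be lowered by moving
      # individuals that are not themselves in an inconsistent dyad
      for (p in seq_len(n - 1L)) {
        for (q in seq((p + 1L), n)) {
          cand <- ord; cand[c(p, q)] <- cand[c(q, p)]
          sc <- inconsistencies(wins, cand)
          if (lex_better(sc, cur)) { ord <- cand; cur <- sc; improved <- TRUE; next }
          cand <- append(ord[-q], ord[q], after = p - 1L)  # lift q above p
          sc <- inconsistencies(wins, cand)
          if (lex_better(sc, cur)) { ord <- cand; cur <- sc; improved <- TRUE; next }
          cand <- append(ord[-p], ord[p], after = q - 1L)  # drop p below q
          sc <- inconsistencies(wins, cand)
          if (lex_better(sc, cur)) { ord <- cand; cur <- sc; improved <- TRUE }
        }
      }
    }
    if (!improved) break
  }
  list(ord = ord, I = unname(cur[["I"]]), SI = unname(cur[["SI"]]), sweeps = sweeps)
}

# evaluate expr under a temporary RNG state
rng_local <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  eval.parent(substitute(expr))
}

#' @export
print.isi_rank <- function(x, ...) {
  cat(sprintf("<isi_rank> %d individuals: I = %d, SI = %d (%d sweeps, %d restarts)\n",
              length(x$order), x$I, x$SI, x$sweeps, x$restarts))
  cat("  top ranks:", paste(head(x$order, 5), collapse = " > "),
      if (length(x$order) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.isi_rank <- function(object, ...) {
  df <- data.frame(id = object$order,
                   rank = seq_along(object$order),
                   wins = rowSums(object$wins)[object$order],
                   losses = colSums(object$wins)[object$order],
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Export an inferred ranking
#'
#' Writes the per-individual rank CSV (`id,rank[,sex,age_class]`) and a
#' JSON summary of the search (I, SI, sweeps, restarts).
#'
#' @param ranking an `isi_rank`
#' @param path output CSV path; the JSON summary goes to the same path
#'   with extension `.json`
#' @param attrs optional attribute table merged onto the output
#' @export
write_ranks <- function(ranking, path, attrs = NULL) {
  stopifnot(inherits(ranking, "isi_rank"))
  df <- data.frame(id = ranking$order, rank = seq_along(ranking$order),
                   stringsAsFactors = FALSE)
  if (!is.null(attrs)) df <- merge(df, attrs, by = "id", sort = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(I = ranking$I, SI = ranking$SI,
                            sweeps = ranking$sweeps, restarts = ranking$restarts),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
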