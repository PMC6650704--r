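#' Per-dyad initiation proportions oriented by dominance
#'
#' For every unordered pair with at least one interaction, the
#' proportion of events initiated by the more dominant (higher-ranked)
#' member: `p = n(dom -> sub) / (n(dom -> sub) + n(sub -> dom))`. Dyads
#' with no interactions are undefined and flagged, never imputed.
#'
#' @param net a directed weighted [agonet]
#' @param ranking an `isi_rank` (or named rank vector) covering the
#'   network's nodes; rank 1 = most dominant
#' @return data frame with one row per unordered dyad: ids, ranks,
#'   counts in both directions, `p` (NA when undefined) and `defined`
#' @export
dyad_initiation <- function(net, ranking) {
  stopifnot(inherits(net, "agonet"))
  if (!net$directed) stop("initiation proportions need a directed network")
  if (!net$weighted) stop("initiation proportions need a weighted network")
  ranks <- as_ranks(ranking, net$ids)
  n <- length(net$ids)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- pairs[, 1]; b <- pairs[, 2]
  # orient: i = more dominant (smaller rank)
  swap <- ranks[a] > ranks[b]
  i <- ifelse(swap, b, a); j <- ifelse(swap, a, b)
  ndown <- net$adj[cbind(i, j)]  # dominant -> subordinate
  nup <- net$adj[cbind(j, i)]
  tot <- ndown + nup
  data.frame(i = net$ids[i], j = net$ids[j],
             rank_i = unname(ranks[i]), rank_j = unname(ranks[j]),
             n_down = ndown, n_up = nup,
             p = ifelse(tot > 0, ndown / tot, NA_real_),
             defined = tot > 0,
             stringsAsFactors = FALSE)
}

as_ranks <- function(ranking, ids) {
  r <- if (inherits(ranking, "isi_rank")) ranking$ranks else ranking
  if (is.null(names(r))) stop("ranking must carry individual ids")
  if (!all(ids %in% names(r))) stop("ranking does not cover the network's nodes")
  r[ids]
}

#' Rank-resolved goodness-of-fit surface
#'
#' For each dyad with interactions in the observed network, compares the
#' observed proportion of interactions initiated by the more dominant
#' member against the same proportion in each simulated network in which
#' that dyad interacted; the per-dyad goodness of fit is the median of
#' these per-simulation differences (`p_obs - p_sim`, so positive values
#' mean the dominant individual initiates more than the model expects).
#' The surface is summarised over hierarchy position (mean or minimum of
#' the two ranks, binned to integers) by absolute rank difference.
#'
#' @param obs observed directed weighted [agonet]
#' @param sims list of simulated networks on the same node set
#' @param ranking as in [dyad_initiation()]
#' @param position `"mean"` (default) or `"min"`: how a dyad's hierarchy
#'   position is computed from its two ranks
#' @param low_support_frac dyads whose proportion is defined in fewer
#'   than this fraction of simulations are flagged `low_support`
#' @return object of class `gof_surface`: per-dyad data frame (`$dyads`)
#'   with `gof` and `n_sims_used`, and the binned median matrix
#'   (`$binned`, position x rank distance)
#' @export
gof_surface <- function(obs, sims, ranking, position = c("mean", "min"),
                        low_support_frac = 0.05) {
  position <- match.arg(position)
  stopifnot(inherits(obs, "agonet"), length(sims) >= 1)
  for (s in sims) check_same_nodes(obs, s)
  di <- dyad_initiation(obs, ranking)
  nd <- nrow(di)
  ids <- obs$ids
  ii <- match(di$i, ids); jj <- match(di$j, ids)
  nsim <- length(sims)
  diffs <- matrix(NA_real_, nd, nsim)
  for (s in seq_len(nsim)) {
    adj <- sims[[s]]$adj
    down <- adj[cbind(ii, jj)]; up <- adj[cbind(jj, ii)]
    tot <- down + up
    ok <- tot > 0
    diffs[ok, s] <- di$p[ok] - down[ok] / tot[ok]
  }
  used <- rowSums(!is.na(diffs))
  gof <- apply(diffs, 1, function(x) if (any(!is.na(x))) median(x, na.rm = TRUE)
               else NA_real_)
  gof[!di$defined] <- NA_real_
  used[!di$defined] <- 0L
  pos_raw <- if (position == "mean") (di$rank_i + di$rank_j) / 2
             else pmin(di$rank_i, di$rank_j)
  df <- data.frame(di,
                   position = floor(pos_raw + 0.5),
                   distance = abs(di$rank_j - di$rank_i),
                   gof = gof, n_sims_used = used,
                   low_support = di$defined & used < low_support_frac * nsim,
                   stringsAsFactors = FALSE)
  keep <- df$defined & df$n_sims_used > 0
  pos_lev <- sort(unique(df$position))
  dist_lev <- sort(unique(df$distance))
  binned <- matrix(NA_real_, length(pos_lev), length(dist_lev),
                   dimnames = list(position = pos_lev, distance = dist_lev))
  for (pi in seq_along(pos_lev)) for (qi in seq_along(dist_lev)) {
    v <- df$gof[keep & df$position == pos_lev[pi] & df$distance == dist_lev[qi]]
    if (length(v)) binned[pi, qi] <- median(v)
  }
  structure(list(dyads = df, binned = binned, n_sims = nsim,
                 position = position),
            class = "gof_surface")
}

#' @export
print.gof_surface <- function(x, ...) {
  d <- x$dyads
  cat(sprintf("<gof_surface> %d dyads (%d defined, %d low-support) vs %d simulations\n",
              nrow(d), sum(d$defined & d$n_sims_used > 0), sum(d$low_support),
              x$n_sims))
  v <- d$gof[!is.na(d$gof)]
  if (length(v))
    cat(sprintf("  gof: median %.3f, IQR [%.3f, %.3f]\n",
                median(v), quantile(v, 0.25), quantile(v, 0.75)))
  invisible(x)
}

#' Heat map of a goodness-of-fit surface
#'
#' Hierarchy position against rank difference, diverging palette with
#' red for positive values (observed initiation by the dominant more
#' likely than the model expects) and blue for negative.
#'
#' @param x a `gof_surface`
#' @param ... unused
#' @export
plot.gof_surface <- function(x, ...) {
  b <- x$binned
  lim <- max(abs(b), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(51)
  graphics::image(x = as.numeric(rownames(b)), y = as.numeric(colnames(b)),
                  z = b, zlim = c(-lim, lim), col = pal,
                  xlab = "hierarchy position of dyad",
                  ylab = "difference in rank",
                  main = "initiation goodness of fit (obs - sim)")
  invisible(x)
}

#' In-band versus out-of-band instability contrast
#'
#' Tests whether model misfit of initiation direction concentrates in a
#' named region of the hierarchy. The comparison is made among dyads
#' whose rank difference falls in `distance_band` (misfit varies
#' systematically with rank difference, so only same-distance dyads are
#' exchangeable): those whose position falls in `central_band` form the
#' in-band set, the rest of the distance band the out-of-band set.
#' Reports mean absolute and mean signed gof in and out, and a
#' permutation p-value for the absolute contrast obtained by shuffling
#' band labels over dyads.
#'
#' @param surface a `gof_surface`
#' @param central_band length-2 numeric: inclusive range of dyad
#'   hierarchy positions
#' @param distance_band length-2 integer: inclusive range of rank
#'   differences
#' @param n_perm number of label permutations
#' @param seed RNG seed for the permutations
#' @return list with in/out means, the observed contrast
#'   `mean |gof| in - out`, and `p_value`
#' @export
instability_summary <- function(surface, central_band, distance_band,
                                n_perm = 999, seed = 1L) {
  stopifnot(inherits(surface, "gof_surface"))
  d <- surface$dyads
  d <- d[!is.na(d$gof) & d$distance >= distance_band[1] &
           d$distance <= distance_band[2], , drop = FALSE]
  if (!nrow(d)) stop("no defined dyads in the surface")
  inband <- d$position >= central_band[1] & d$position <= central_band[2]
  if (!any(inband)) stop("empty central band: no dyads fall in it")
  if (all(inband)) stop("band covers every dyad: no contrast possible")
  obs_stat <- mean(abs(d$gof[inband])) - mean(abs(d$gof[!inband]))
  perm <- rng_local(seed, {
    vapply(seq_len(n_perm), function(k) {
      lab <- sample(inband)
      mean(abs(d$gof[lab])) - mean(abs(d$gof[!lab]))
    }, 0)
  })
  p <- (1 + sum(abs(perm) >= abs(obs_stat))) / (n_perm + 1)
  list(n_in = sum(inband), n_out = sum(!inband),
       mean_abs_in = mean(abs(d$gof[inband])),
       mean_abs_out = mean(abs(d$gof[!inband])),
       mean_signed_in = mean(d$gof[inband]),
       mean_signed_out = mean(d$gof[!inband]),
       contrast = obs_stat, p_value = p)
}

#' Export a goodness-of-fit surface
#'
#' Per-dyad CSV (`i,j,rank_i,rank_j,position,distance,p_obs,gof,
#' n_sims_used`) plus the binned-median matrix CSV alongside.
#'
#' @param surface a `gof_surface`
#' @param path output CSV path (binned matrix written with suffix
#'   `_binned.csv`)
#' @export
write_surface <- function(surface, path) {
  d <- surface$dyads
  out <- data.frame(i = d$i, j = d$j, rank_i = d$rank_i, rank_j = d$rank_j,
                    position = d$position, distance = d$distance,
                    p_obs = d$p, gof = d$gof, n_sims_used = d$n_sims_used)
  write.csv(out, path, row.names = FALSE)
  bp <- sub("\\.csv$", "_binned.csv", path)
  write.csv(data.frame(position = rownames(surface$binned), surface$binned,
                       check.names = FALSE), bp, row.names = FALSE)
  invisible(path)
}
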