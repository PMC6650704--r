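#' Pack composition (counts per sex-age cell)
#'
#' Defaults to the composition of the study pack this package's
#' analyses are designed around: 27 free-living dogs comprising six
#' adult males, five adult females, four subadult males, one subadult
#' female, six juvenile males and five juvenile females.
#'
#' @param adult_m,adult_f,subadult_m,subadult_f,juvenile_m,juvenile_f
#'   non-negative counts
#' @export
pack_composition <- function(adult_m = 6, adult_f = 5, subadult_m = 4,
                             subadult_f = 1, juvenile_m = 6, juvenile_f = 5) {
  comp <- c(adult_m = adult_m, adult_f = adult_f, subadult_m = subadult_m,
            subadult_f = subadult_f, juvenile_m = juvenile_m,
            juvenile_f = juvenile_f)
  if (any(comp < 0)) stop("cell counts must be non-negative")
  if (sum(comp) < 3) stop("pack needs at least 3 individuals")
  comp
}

#' Generator parameters for synthetic agonistic interaction data
#'
#' The generator emulates the statistical structure the analyses
#' assume: a latent sex-age-graded hierarchy; dyadic interaction counts
#' that rise towards the top of the hierarchy and, for aggression, for
#' central and closely ranked dyads; and initiation directions that
#' follow the hierarchy with tunable steepness, degraded by instability
#' among central close-but-non-adjacent dyads.
#'
#' @param steepness logistic slope of the probability that the
#'   latent-dominant individual "wins" the initiation of an event
#'   (initiates dominance/aggression; receives submission) per unit rank
#'   difference
#' @param base_rates expected events per dyad per behaviour before rank
#'   effects (Poisson means; defaults give behaviour totals in the
#'   hundreds for a 27-dog pack, the magnitude of a year-long study)
#' @param top_rank_gradient log-rate increase with dyad proximity to
#'   rank 1 (all behaviours)
#' @param centre_aggression log-rate increase of aggression with dyad
#'   proximity to the hierarchy centre
#' @param close_rank_aggression log-rate elevation of aggression for
#'   closely ranked dyads: adjacent dyads get the full amount, declining
#'   linearly by that amount per `k_max` ranks of separation
#' @param instability in `[0, 1]`: shrinkage of initiation asymmetry
#'   towards 50/50 for unstable dyads (those with rank difference
#'   between 2 and `k_max` whose mean rank lies in the central band)
#' @param k_max largest rank difference counted as "close but not
#'   adjacent"
#' @param central_frac fraction of ranks, centred mid-hierarchy,
#'   forming the central band
#' @param seed master RNG seed
#' @export
pack_params <- function(steepness = 1.0,
                        base_rates = c(submissive = 1.5, dominance = 1.0,
                                       aggressive = 0.8),
                        top_rank_gradient = 0.8,
                        centre_aggression = 0.6,
                        close_rank_aggression = 0.6,
                        instability = 0.5,
                        k_max = 4L,
                        central_frac = 1 / 3,
                        seed = 1L) {
  stopifnot(steepness >= 0, all(base_rates > 0),
            instability >= 0, instability <= 1, k_max >= 2,
            central_frac > 0, central_frac <= 1)
  if (is.null(names(base_rates))) names(base_rates) <- BEHAVIOURS
  stopifnot(setequal(names(base_rates), BEHAVIOURS))
  list(steepness = steepness, base_rates = base_rates[BEHAVIOURS],
       top_rank_gradient = top_rank_gradient,
       centre_aggression = centre_aggression,
       close_rank_aggression = close_rank_aggression,
       instability = instability, k_max = as.integer(k_max),
       central_frac = central_frac, seed = as.integer(seed))
}

#' Central band of a hierarchy
#'
#' The middle `frac` of ranks (inclusive integer range), used both by
#' the generator's instability region and by [instability_summary()].
#' @param n number of individuals
#' @param frac central fraction
#' @export
central_band <- function(n, frac = 1 / 3) {
  half <- n * frac / 2
  mid <- (n + 1) / 2
  c(ceiling(mid - half), floor(mid + half))
}

#' Create a synthetic pack with a latent sex-age-graded hierarchy
#'
#' Individuals are assigned ids, sex and age class according to the
#' composition, and a latent rank consistent with a sex-age-graded
#' hierarchy: every adult out-ranks every subadult, every subadult every
#' juvenile, and males out-rank females within an age class; order
#' within a sex-age cell is uniform-random (seeded).
#'
#' @param comp a [pack_composition()]
#' @param seed RNG seed
#' @return list of class `pack`: `attrs` (id, sex, age_class, sorted by
#'   id) and `truth` (named latent rank vector and the seed)
#' @export
make_pack <- function(comp = pack_composition(), seed = 1L) {
  comp <- pack_composition(comp[["adult_m"]], comp[["adult_f"]],
                           comp[["subadult_m"]], comp[["subadult_f"]],
                           comp[["juvenile_m"]], comp[["juvenile_f"]])
  n <- sum(comp)
  cells <- data.frame(
    age_class = rep(rep(AGE_CLASSES, each = 2), times = as.integer(comp)),
    sex = rep(rep(SEXES, times = 3), times = as.integer(comp)),
    stringsAsFactors = FALSE)
  rng_local(seed, {
    # ranks follow the cell-block order; shuffle within each cell
    rank <- integer(n)
    pos <- 0L
    for (cell in seq_along(comp)) {
      k <- as.integer(comp[cell])
      if (k > 0) rank[pos + sample.int(k)] <- pos + seq_len(k)
      pos <- pos + k
    }
    cells$rank <- rank
    # ids assigned independently of rank
    ids <- sprintf("d%02d", seq_len(n))
    cells$id <- ids[sample.int(n)]
  })
  attrs <- cells[order(cells$id), c("id", "sex", "age_class")]
  rownames(attrs) <- NULL
  truth <- setNames(cells$rank, cells$id)[sort(cells$id)]
  structure(list(attrs = attrs, truth = truth, composition = comp,
                 seed = as.integer(seed)),
            class = "pack")
}

#' @export
print.pack <- function(x, ...) {
  cat(sprintf("<pack> %d individuals (%s)\n", nrow(x$attrs),
              paste(sprintf("%s=%d", names(x$composition), x$composition),
                    collapse = ", ")))
  invisible(x)
}

dyad_grid <- function(ranks) {
  n <- length(ranks)
  ids <- names(ranks)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- ids[pr[, 1]]; b <- ids[pr[, 2]]
  ra <- ranks[a]; rb <- ranks[b]
  swap <- ra > rb
  data.frame(dom = ifelse(swap, b, a), sub = ifelse(swap, a, b),
             r_dom = pmin(ra, rb), r_sub = pmax(ra, rb),
             stringsAsFactors = FALSE)
}

#' Simulate an interaction log from a synthetic pack
#'
#' For every unordered dyad and behaviour, the event count is Poisson
#' with log-rate `log(base) + top_rank_gradient * top-proximity` (plus,
#' for aggression, the centre- and rank-closeness terms); each event's
#' initiator is the latent-dominant member with probability
#' `plogis(steepness * rank difference)` for dominance and aggression,
#' and the latent-subordinate with that probability for submission.
#' For unstable dyads (central band, `2 <= rank difference <= k_max`)
#' the asymmetry is shrunk towards 50/50 by the instability factor.
#' Events are emitted in random order.
#'
#' @param pack a [make_pack()] result
#' @param params a [pack_params()]
#' @return an `interaction_log`
#' @export
simulate_interactions <- function(pack, params = pack_params()) {
  stopifnot(inherits(pack, "pack"))
  ranks <- pack$truth
  n <- length(ranks)
  dg <- dyad_grid(ranks)
  meanrank <- (dg$r_dom + dg$r_sub) / 2
  delta <- dg$r_sub - dg$r_dom
  top_prox <- (n - meanrank) / (n - 1)
  centre_prox <- 1 - abs(meanrank - (n + 1) / 2) / ((n - 1) / 2)
  # log-linear in rank difference with scale k_max: adjacent dyads get
  # the full close_rank_aggression elevation, which falls off by that
  # amount every k_max ranks of separation
  close_prox <- 1 - (delta - 1) / params$k_max
  band <- central_band(n, params$central_frac)
  unstable <- meanrank >= band[1] & meanrank <= band[2] &
    delta >= 2 & delta <= params$k_max
  p <- plogis(params$steepness * delta)
  p[unstable] <- 0.5 + (1 - params$instability) * (p[unstable] - 0.5)
  rows <- rng_local(params$seed, {
    out <- vector("list", 3L)
    for (bi in seq_along(BEHAVIOURS)) {
      beh <- BEHAVIOURS[bi]
      lograte <- log(params$base_rates[[beh]]) +
        params$top_rank_gradient * top_prox
      if (beh == "aggressive")
        lograte <- lograte + params$centre_aggression * centre_prox +
          params$close_rank_aggression * close_prox
      counts <- rpois(nrow(dg), exp(lograte))
      idx <- rep(seq_len(nrow(dg)), counts)
      if (!length(idx)) { out[[bi]] <- NULL; next }
      # "winner" of the initiation draw: the latent-dominant initiates
      # dominance/aggression; the latent-subordinate initiates submission
      winner <- rbinom(length(idx), 1L, p[idx]) == 1L
      if (beh == "submissive") {
        init <- ifelse(winner, dg$sub[idx], dg$dom[idx])
        recv <- ifelse(winner, dg$dom[idx], dg$sub[idx])
      } else {
        init <- ifelse(winner, dg$dom[idx], dg$sub[idx])
        recv <- ifelse(winner, dg$sub[idx], dg$dom[idx])
      }
      out[[bi]] <- data.frame(initiator = init, receiver = recv,
                              behaviour = beh, stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, out)
    if (is.null(ev) || !nrow(ev))
      stop("generator produced no events; raise the base rates")
    ev[sample.int(nrow(ev)), , drop = FALSE]
  })
  rownames(rows) <- NULL
  # isolates stay in the networks: attach the full individual set
  log <- interaction_log(rows)
  attr(log, "individuals") <- sort(unique(c(individuals(log), pack$attrs$id)))
  log
}

#' Parameter-recovery experiment over synthetic packs
#'
#' Repeatedly generates a pack and its interaction log, runs the
#' analysis pipeline (I&SI ranking; binary structural ERGM of the
#' submissive network; directed rank model of the dominance network; a
#' simulated ensemble and the rank-resolved goodness-of-fit surface
#' with its in-band/out-of-band contrast) and records how well each
#' stage recovers the generating truth.
#'
#' @param comp a [pack_composition()]
#' @param params a [pack_params()] (its `seed` is ignored; per-replicate
#'   seeds derive from `seed`)
#' @param n_reps number of replicates (>= 2)
#' @param seed master seed
#' @param n_sims ensemble size for the goodness-of-fit stage
#' @param control [ergm_control()] for the model fits
#' @param stages character subset of `c("ergm", "gof")`; ranking always
#'   runs
#' @return object of class `recovery_report`: per-replicate data frame
#'   (`$replicates`, failures flagged, not dropped) and aggregate means
#'   with Monte-Carlo standard errors (`$aggregate`)
#' @export
recovery_experiment <- function(comp = pack_composition(),
                                params = pack_params(), n_reps = 20,
                                seed = 1L, n_sims = 1000,
                                control = ergm_control(),
                                stages = c("ergm", "gof")) {
  stopifnot(n_reps >= 2)
  rows <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    rep_seed <- seed + 104729L * (rep - 1L)
    row <- list(replicate = rep, seed = rep_seed, failed = FALSE,
                error = NA_character_)
    res <- tryCatch({
      pack <- make_pack(comp, seed = rep_seed)
      pp <- params; pp$seed <- rep_seed + 1L
      log <- simulate_interactions(pack, pp)
      ranking <- isi_rank(wins_matrix(log, pack$attrs), seed = rep_seed + 2L)
      out <- list(spearman = cor(pack$truth[names(ranking$ranks)],
                                 ranking$ranks, method = "spearman"),
                  I = ranking$I, SI = ranking$SI)
      if ("ergm" %in% stages) {
        bnet <- build_network(log, "submissive", weighted = FALSE,
                              attrs = pack$attrs)
        ctl <- control; ctl$seed <- rep_seed + 3L
        bfit <- packergm(bnet ~ edges + mutual + transitive + cyclical,
                         control = ctl)
        th <- coef(bfit)
        out$transitive_pos <- th[["transitive"]] > 0
        out$cyclical_neg <- th[["cyclical"]] < 0
        out$mutual_neg <- th[["mutual"]] < 0
      }
      if ("gof" %in% stages) {
        dnet <- build_network(log, "dominance", attrs = pack$attrs)
        ctl <- control; ctl$seed <- rep_seed + 4L
        rfit <- fit_directed_rank_model(dnet, ranking, control = ctl)
        sims <- simulate(rfit, nsim = n_sims, seed = rep_seed + 5L)
        surf <- gof_surface(dnet, sims, ranking)
        band <- central_band(length(pack$truth), params$central_frac)
        inst <- instability_summary(surf, band, c(2, params$k_max),
                                    seed = rep_seed + 6L)
        out$sender_rank <- coef(rfit)[["sender.rank"]]
        out$gof_abs_in <- inst$mean_abs_in
        out$gof_abs_out <- inst$mean_abs_out
        out$gof_p <- inst$p_value
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$failed <- TRUE
      row$error <- conditionMessage(res)
    } else row <- c(row, res)
    rows[[rep]] <- row
  }
  cols <- unique(unlist(lapply(rows, names)))
  reps <- do.call(rbind, lapply(rows, function(r) {
    r <- r[cols]; names(r) <- cols
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
  num <- vapply(reps, is.numeric, TRUE) | vapply(reps, is.logical, TRUE)
  num[names(num) %in% c("replicate", "seed", "failed")] <- FALSE
  agg <- data.frame(
    metric = names(reps)[num],
    mean = vapply(reps[num], function(v) mean(as.numeric(v), na.rm = TRUE), 0),
    mc_se = vapply(reps[num], function(v) {
      v <- as.numeric(v[!is.na(v)])
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }, 0), row.names = NULL)
  structure(list(replicates = reps, aggregate = agg, params = params,
                 n_reps = n_reps, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates (%d failed)\n",
              x$n_reps, sum(x$replicates$failed)))
  print(transform(x$aggregate, mean = round(mean, 3), mc_se = round(mc_se, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Write synthetic data in the pipeline's input formats
#'
#' Emits the interaction-log CSV and attribute CSV consumed by
#' [read_interactions()], and the ground truth as JSON.
#'
#' @param pack a `pack`
#' @param log an `interaction_log` from [simulate_interactions()]
#' @param dir output directory (created if needed)
#' @return paths, invisibly
#' @export
write_pack <- function(pack, log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lp <- file.path(dir, "interactions.csv")
  ap <- file.path(dir, "attributes.csv")
  tp <- file.path(dir, "truth.json")
  write.csv(as.data.frame(log), lp, row.names = FALSE)
  write.csv(pack$attrs, ap, row.names = FALSE)
  jsonlite::write_json(list(ranks = as.list(pack$truth),
                            composition = as.list(pack$composition),
                            seed = pack$seed),
                       tp, auto_unbox = TRUE)
  invisible(c(log = lp, attrs = ap, truth = tp))
}
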