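ranked_ids <- function(n) setNames(1:n, sprintf("n%02d", 1:n))

net_counts <- function(adj, attrs = NULL) agonet(adj, attrs = attrs)

test_that("dyad initiation proportions are oriented by the dominant member", {
  ids <- names(ranked_ids(3))
  adj <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  adj["n01", "n02"] <- 3L; adj["n02", "n01"] <- 1L  # dominant initiates 3 of 4
  adj["n03", "n01"] <- 2L                            # subordinate one-sided
  di <- dyad_initiation(net_counts(adj), ranked_ids(3))
  expect_equal(di$p[di$i == "n01" & di$j == "n02"], 0.75)
  expect_equal(di$p[di$i == "n01" & di$j == "n03"], 0)
  # silent dyad undefined, flagged
  r23 <- di[di$i == "n02" & di$j == "n03", ]
  expect_true(is.na(r23$p))
  expect_false(r23$defined)
  expect_error(dyad_initiation(agonet(adj + t(adj), directed = FALSE),
                               ranked_ids(3)), "directed")
})

test_that("reversing the ranking maps p to 1 - p", {
  set.seed(4)
  ids <- names(ranked_ids(6))
  adj <- rand_countgraph(6, seed = 4)
  di <- dyad_initiation(net_counts(adj), ranked_ids(6))
  rev_ranks <- setNames(6:1, ids)
  di_rev <- dyad_initiation(net_counts(adj), rev_ranks)
  key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
  mi <- match(key(di), key(di_rev))
  expect_equal(di$p, 1 - di_rev$p[mi])
})

test_that("gof surface matches hand-computed medians and contracts", {
  ids <- names(ranked_ids(3))
  mk <- function(ab, ba, ac = 1L, bc = 1L) {
    adj <- matrix(0L, 3, 3, dimnames = list(ids, ids))
    adj["n01", "n02"] <- ab; adj["n02", "n01"] <- ba
    adj["n01", "n03"] <- ac; adj["n02", "n03"] <- bc
    net_counts(adj)
  }
  obs <- mk(4L, 0L)            # p_obs = 1 on dyad (1,2)
  sims <- list(mk(1L, 1L), mk(2L, 2L), mk(3L, 0L))  # p_sim = .5, .5, 1
  surf <- gof_surface(obs, sims, ranked_ids(3))
  g12 <- surf$dyads$gof[surf$dyads$i == "n01" & surf$dyads$j == "n02"]
  expect_equal(g12, median(c(0.5, 0.5, 0)))
  # self-comparison gives exactly zero
  surf0 <- gof_surface(obs, list(obs, obs), ranked_ids(3))
  expect_true(all(surf0$dyads$gof[!is.na(surf0$dyads$gof)] == 0))
  # dyad present in obs but silent in every simulation: undefined, flagged
  sims_silent <- list(mk(0L, 0L), mk(0L, 0L))
  surf2 <- gof_surface(obs, sims_silent, ranked_ids(3))
  r <- surf2$dyads[surf2$dyads$i == "n01" & surf2$dyads$j == "n02", ]
  expect_equal(r$n_sims_used, 0L)
  expect_true(is.na(r$gof))
  # order of simulations is irrelevant
  surf3 <- gof_surface(obs, rev(sims), ranked_ids(3))
  expect_equal(surf3$dyads$gof, surf$dyads$gof)
})

test_that("gof surface bins by hierarchy position and rank distance", {
  set.seed(6)
  n <- 8
  adj <- rand_countgraph(n, lambda = 2, seed = 6)
  obs <- net_counts(adj)
  sims <- lapply(1:5, function(s) net_counts(rand_countgraph(n, lambda = 2,
                                                             seed = 50 + s)))
  surf <- gof_surface(obs, sims, ranked_ids(n))
  d <- surf$dyads
  expect_true(all(d$distance >= 1))
  expect_true(all(abs(d$gof) <= 1, na.rm = TRUE))
  expect_equal(d$position,
               floor((d$rank_i + d$rank_j) / 2 + 0.5))
  # min-rank alternative
  surf_min <- gof_surface(obs, sims, ranked_ids(n), position = "min")
  expect_equal(surf_min$dyads$position, pmin(d$rank_i, d$rank_j))
  # binned cells contain medians of their dyads
  cell <- surf$binned["3", "1"]
  if (!is.na(cell)) {
    v <- d$gof[d$position == 3 & d$distance == 1 & !is.na(d$gof)]
    expect_equal(cell, median(v))
  }
  expect_error(gof_surface(obs, list(net_counts(rand_countgraph(5))),
                           ranked_ids(n)), "node set")
})

test_that("instability contrast detects an injected central-band excess", {
  set.seed(13)
  n <- 15
  ids <- sprintf("n%02d", 1:n)
  ranks <- setNames(1:n, ids)
  # synthetic surface: start from near-zero gof everywhere
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  adj[pairs] <- 5L
  obs <- net_counts(adj)
  band <- central_band(n)
  surf <- gof_surface(obs, list(obs), ranks)
  # inject |gof| only into central, close-but-not-adjacent dyads
  d <- surf$dyads
  inband <- d$position >= band[1] & d$position <= band[2] &
    d$distance >= 2 & d$distance <= 4
  surf$dyads$gof <- ifelse(inband, 0.5, rnorm(nrow(d), 0, 0.01))
  inst <- instability_summary(surf, band, c(2, 4), seed = 3)
  expect_gt(inst$mean_abs_in, inst$mean_abs_out)
  expect_lt(inst$p_value, 0.05)
  # flat surface: no contrast
  surf$dyads$gof <- rep(0, nrow(d))
  inst0 <- instability_summary(surf, band, c(2, 4), seed = 3)
  expect_equal(inst0$contrast, 0)
  expect_gt(inst0$p_value, 0.5)
  # degenerate bands error
  expect_error(instability_summary(surf, c(99, 100), c(2, 4)), "empty")
  expect_error(instability_summary(surf, c(1, n), c(1, n)), "every dyad")
})

test_that("surface export writes per-dyad and binned CSVs", {
  td <- withr::local_tempdir()
  adj <- rand_countgraph(5, lambda = 2, seed = 9)
  obs <- net_counts(adj)
  surf <- gof_surface(obs, list(obs), ranked_ids(5))
  p <- file.path(td, "surf.csv")
  write_surface(surf, p)
  df <- read.csv(p)
  expect_named(df, c("i", "j", "rank_i", "rank_j", "position", "distance",
                     "p_obs", "gof", "n_sims_used"))
  expect_true(file.exists(file.path(td, "surf_binned.csv")))
})
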