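test_that("pack creation respects composition and sex-age grading", {
  pack <- make_pack(seed = 1)
  a <- pack$attrs
  expect_equal(nrow(a), 27)
  expect_equal(sum(a$sex == "male" & a$age_class == "adult"), 6)
  expect_equal(sum(a$sex == "female" & a$age_class == "subadult"), 1)
  r <- pack$truth
  byid <- a[match(names(r), a$id), ]
  # every adult out-ranks every subadult, every subadult every juvenile
  expect_lt(max(r[byid$age_class == "adult"]), min(r[byid$age_class == "subadult"]))
  expect_lt(max(r[byid$age_class == "subadult"]), min(r[byid$age_class == "juvenile"]))
  # males out-rank females within each age class
  for (ac in c("adult", "subadult", "juvenile")) {
    rm_ <- r[byid$age_class == ac & byid$sex == "male"]
    rf_ <- r[byid$age_class == ac & byid$sex == "female"]
    if (length(rm_) && length(rf_)) expect_lt(max(rm_), min(rf_))
  }
  # determinism and seed sensitivity
  expect_identical(make_pack(seed = 1)$truth, pack$truth)
  expect_false(identical(make_pack(seed = 2)$truth, pack$truth))
  # one individual per cell: fully deterministic grading
  p1 <- make_pack(pack_composition(1, 1, 1, 1, 1, 1), seed = 5)
  byid1 <- p1$attrs[match(names(sort(p1$truth)), p1$attrs$id), ]
  expect_equal(byid1$age_class, rep(c("adult", "subadult", "juvenile"), each = 2))
  expect_equal(byid1$sex, rep(c("male", "female"), 3))
  expect_error(make_pack(pack_composition(1, 0, 0, 0, 0, 0)), "at least 3")
})

test_that("steep hierarchies produce perfectly linear submissive data", {
  pack <- make_pack(seed = 3)
  # effectively infinite steepness: dominant always wins the draw; the
  # submissive rate is raised so that every dyad is observed at least
  # once (exact rank recovery is only identified with full dyad coverage)
  prm <- pack_params(steepness = 50, instability = 0, seed = 3,
                     base_rates = c(submissive = 10, dominance = 1,
                                    aggressive = 0.8))
  log <- simulate_interactions(pack, prm)
  agg <- log[log$behaviour != "submissive", ]
  r <- pack$truth
  expect_true(all(r[agg$initiator] < r[agg$receiver]))
  sub <- log[log$behaviour == "submissive", ]
  expect_true(all(r[sub$initiator] > r[sub$receiver]))
  rk <- isi_rank(wins_matrix(log, pack$attrs), seed = 1)
  expect_equal(rk$I, 0)
  expect_equal(unname(rk$ranks[names(r)]), unname(r))
})

test_that("zero steepness gives symmetric initiation", {
  pack <- make_pack(seed = 4)
  prm <- pack_params(steepness = 0, seed = 4)
  log <- simulate_interactions(pack, prm)
  r <- pack$truth
  dom <- log[log$behaviour == "dominance", ]
  p_hat <- mean(r[dom$initiator] < r[dom$receiver])
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / nrow(dom)))
})

test_that("expected event totals match the dyadic Poisson means", {
  pack <- make_pack(seed = 5)
  prm <- pack_params(seed = 5)
  n <- 27
  r <- pack$truth
  dg <- packdom:::dyad_grid(r)
  meanrank <- (dg$r_dom + dg$r_sub) / 2
  expected <- sum(prm$base_rates[["submissive"]] *
                    exp(prm$top_rank_gradient * (n - meanrank) / (n - 1)))
  tots <- vapply(1:12, function(s) {
    pp <- prm; pp$seed <- 1000 + s
    sum(simulate_interactions(pack, pp)$behaviour == "submissive")
  }, 0)
  mc_se <- sd(tots) / sqrt(length(tots))
  expect_lt(abs(mean(tots) - expected), 3 * mc_se + 1e-9)
})

test_that("interaction logs are reproducible and shuffled", {
  pack <- make_pack(seed = 6)
  prm <- pack_params(seed = 6)
  l1 <- simulate_interactions(pack, prm)
  l2 <- simulate_interactions(pack, prm)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  # behaviours interleaved, not blocked
  expect_gt(length(rle(l1$behaviour)$lengths), 100)
})

test_that("recovery experiment aggregates replicates and is deterministic", {
  rep1 <- recovery_experiment(n_reps = 2, seed = 11, stages = character(0))
  rep2 <- recovery_experiment(n_reps = 2, seed = 11, stages = character(0))
  expect_identical(rep1$replicates, rep2$replicates)
  expect_equal(nrow(rep1$replicates), 2)
  expect_true(all(c("spearman", "I", "SI") %in% names(rep1$replicates)))
  expect_true(all(!rep1$replicates$failed))
  expect_true("spearman" %in% rep1$aggregate$metric)
  expect_error(recovery_experiment(n_reps = 1), "n_reps")
})

test_that("pack CSV exports feed straight back into the readers", {
  td <- withr::local_tempdir()
  pack <- make_pack(seed = 7)
  log <- simulate_interactions(pack, pack_params(seed = 7))
  paths <- write_pack(pack, log, td)
  back <- read_interactions(file.path(td, "interactions.csv"),
                            file.path(td, "attributes.csv"))
  expect_equal(nrow(back$log), nrow(log))
  expect_equal(back$attrs$id, pack$attrs$id)
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_equal(unlist(truth$ranks)[names(pack$truth)], pack$truth)
})
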