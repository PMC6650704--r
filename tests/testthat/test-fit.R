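test_that("edges-only MPLE equals logit of density", {
  adj <- rand_digraph(10, p = 0.4, seed = 2)
  net <- agonet(adj, weighted = FALSE)
  fit <- fit_mple(ergm_model(net, ~ edges))
  d <- sum(adj) / (10 * 9)
  expect_equal(unname(fit$theta), log(d / (1 - d)), tolerance = 1e-8)
})

test_that("sum-only count MPLE equals log mean dyad count", {
  adj <- rand_countgraph(9, lambda = 2, seed = 3)
  net <- agonet(adj)
  fit <- fit_mple(ergm_model(net, ~ sum, response = "count"))
  expect_equal(unname(fit$theta), log(mean(adj[row(adj) != col(adj)])),
               tolerance = 1e-6)
})

test_that("binary MPLE equals a logistic fit on the explicit dyad table", {
  adj <- rand_digraph(10, p = 0.35, seed = 9)
  ids <- rownames(adj)
  attrs <- rand_attrs(ids, 9)
  net <- agonet(adj, weighted = FALSE, attrs = attrs)
  fit <- fit_mple(ergm_model(net, ~ edges + nodematch("sex", "male")))
  # oracle: build the dyad/covariate table directly from the definitions
  rows <- expand.grid(i = 1:10, j = 1:10)
  rows <- rows[rows$i != rows$j, ]
  y <- adj[cbind(rows$i, rows$j)]
  male <- attrs$sex == "male"
  x_match <- as.numeric(male[rows$i] & male[rows$j])
  oracle <- glm(y ~ x_match, family = binomial())
  expect_equal(unname(fit$theta),
               unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(oracle)$coefficients[, 2]), tolerance = 1e-6)
})

test_that("count MPLE equals a Poisson fit for dyad-independent models", {
  adj <- rand_countgraph(9, lambda = 1.5, seed = 12)
  ids <- rownames(adj)
  attrs <- rand_attrs(ids, 12)
  net <- agonet(adj, attrs = attrs)
  fit <- fit_mple(ergm_model(net, ~ sum + nodematch("sex", "male"),
                             response = "count"))
  # for dyad-independent count models the pseudolikelihood is an exact
  # Poisson likelihood, so glm is an independent oracle
  rows <- expand.grid(i = 1:9, j = 1:9)
  rows <- rows[rows$i != rows$j, ]
  y <- adj[cbind(rows$i, rows$j)]
  male <- attrs$sex == "male"
  x_match <- as.numeric(male[rows$i] & male[rows$j])
  oracle <- glm(y ~ x_match, family = poisson())
  expect_equal(unname(fit$theta), unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(summary(oracle)$coefficients[, 2]),
               tolerance = 1e-3)
})

test_that("degenerate specifications are refused with the term named", {
  adj <- rand_digraph(8, p = 0.4, seed = 5)
  attrs <- rand_attrs(rownames(adj), 5)
  attrs$const <- 1
  net <- agonet(adj, weighted = FALSE, attrs = attrs)
  # a constant sender covariate is collinear with edges
  expect_error(fit_mple(ergm_model(net, ~ edges + sender("const"))),
               "inestimable|degenerate")
  # complete graph: edges statistic at its boundary -> separation
  full <- matrix(1L, 6, 6); diag(full) <- 0L
  fnet <- agonet(full, weighted = FALSE)
  expect_error(fit_mple(ergm_model(fnet, ~ edges)), "degenerate|separation")
})

test_that("MCMC-MLE agrees with MPLE for a dyad-independent model", {
  adj <- rand_digraph(12, p = 0.3, seed = 21)
  attrs <- rand_attrs(rownames(adj), 21)
  net <- agonet(adj, weighted = FALSE, attrs = attrs)
  fit <- packergm(net ~ edges + nodematch("sex", "male"),
                  control = quick_ctl(seed = 4))
  mple <- fit$mple
  comb <- sqrt(fit$se^2 + mple$se^2)
  expect_true(all(abs(coef(fit) - mple$theta) <= 3 * comb))
  expect_true(fit$converged)
})

test_that("moment condition holds at the reported MCMC-MLE", {
  pack <- make_pack(seed = 8)
  log <- simulate_interactions(pack, pack_params(seed = 8))
  net <- build_network(log, "submissive", weighted = FALSE, attrs = pack$attrs)
  fit <- packergm(net ~ edges + mutual + transitive + cyclical,
                  control = quick_ctl(seed = 2, samplesize = 400))
  stats <- simulate(fit, nsim = 400, seed = 99, output = "stats")
  mu <- colMeans(stats)
  mcse <- apply(stats, 2, function(x) sd(x) / sqrt(packdom:::ess(x)))
  expect_true(all(abs(mu - fit$observed_stats) <= 3 * mcse))
})

test_that("summary table carries estimates, Wald tests and significance", {
  adj <- rand_digraph(10, p = 0.3, seed = 31)
  net <- agonet(adj, weighted = FALSE)
  fit <- packergm(net ~ edges, method = "mple")
  s <- summary(fit)
  expect_s3_class(s, "summary.packergm")
  expect_named(s$table, c("term", "estimate", "std_error", "z", "p_value", "sig"))
  expect_output(print(s), "MPLE")
  td <- withr::local_tempdir()
  write_fit(fit, file.path(td, "fit.csv"))
  expect_true(file.exists(file.path(td, "fit.json")))
  expect_equal(read.csv(file.path(td, "fit.csv"))$term, "edges")
})
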