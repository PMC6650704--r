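net_from <- function(adj, weighted = TRUE, directed = TRUE, attrs = NULL) {
  agonet(adj, directed = directed, weighted = weighted, attrs = attrs)
}

test_that("triad statistics match their definitions on canonical examples", {
  ids <- c("A", "B", "C")
  adj <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  adj["A", "B"] <- adj["B", "C"] <- adj["A", "C"] <- 1L
  net <- net_from(adj, weighted = FALSE)
  m <- ergm_model(net, ~ edges + mutual + transitive + cyclical)
  expect_equal(unname(ergm_stats(m)), c(3, 0, 1, 0))
  # 3-cycle
  adj2 <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  adj2["A", "B"] <- adj2["B", "C"] <- adj2["C", "A"] <- 1L
  m2 <- ergm_model(net_from(adj2, weighted = FALSE), ~ transitive + cyclical + mutual)
  expect_equal(unname(ergm_stats(m2)), c(0, 1, 0))
})

test_that("triad statistics equal exhaustive enumeration on random digraphs", {
  for (s in 1:20) {
    adj <- rand_digraph(8, p = 0.35, seed = s)
    net <- net_from(adj, weighted = FALSE)
    m <- ergm_model(net, ~ transitive + cyclical)
    expect_equal(unname(ergm_stats(m)), unname(brute_triads(adj)),
                 info = paste("seed", s))
  }
})

test_that("valued triad statistics equal brute-force evaluation", {
  for (s in 1:10) {
    adj <- rand_countgraph(7, lambda = 1, seed = s)
    net <- net_from(adj)
    m <- ergm_model(net, ~ transitive + cyclical, response = "count")
    expect_equal(unname(ergm_stats(m)),
                 c(brute_valued_triad(adj, FALSE), brute_valued_triad(adj, TRUE)),
                 info = paste("seed", s))
  }
})

test_that("attribute statistics count what they claim", {
  ids <- c("A", "B", "C", "D")
  attrs <- data.frame(id = ids, sex = c("male", "male", "female", "female"),
                      age_class = c("adult", "juvenile", "adult", "juvenile"),
                      score = c(2, 1, 4, 3), stringsAsFactors = FALSE)
  adj <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  adj["A", "B"] <- 1L  # male -> male, adult -> juvenile
  adj["C", "D"] <- 1L  # female -> female
  adj["A", "C"] <- 1L  # male -> female, adult-adult
  net <- net_from(adj, weighted = FALSE, attrs = attrs)
  m <- ergm_model(net, ~ nodematch("sex", "male") + nodematch("sex", "female") +
                    nodemix("sex", "male", "female") +
                    nodemix("age_class", "adult", "juvenile") +
                    sender("score") + nodecov("score") + absdiff("score"))
  st <- ergm_stats(m)
  expect_equal(unname(st["nodematch.sex.male"]), 1)
  expect_equal(unname(st["nodematch.sex.female"]), 1)
  expect_equal(unname(st["mix.sex.male.female"]), 1)
  expect_equal(unname(st["mix.age_class.adult.juvenile"]), 2)
  expect_equal(unname(st["sender.score"]), 2 + 4 + 2)
  expect_equal(unname(st["nodecov.score"]), (2 + 1) + (4 + 3) + (2 + 4))
  expect_equal(unname(st["absdiff.score"]), 1 + 1 + 2)
})

test_that("statistics are invariant under node relabelling", {
  adj <- rand_countgraph(9, seed = 5)
  attrs <- rand_attrs(rownames(adj), 5)
  net <- net_from(adj, attrs = attrs)
  m <- ergm_model(net, ~ sum + transitive + cyclical + nodematch("sex", "male"),
                  response = "count")
  set.seed(77)
  perm <- sample(9)
  adj2 <- adj[perm, perm]
  ids2 <- sprintf("m%02d", 1:9)  # fresh labels, same structure
  dimnames(adj2) <- list(ids2, ids2)
  attrs2 <- attrs[perm, ]; attrs2$id <- ids2
  m2 <- ergm_model(net_from(adj2, attrs = attrs2),
                   ~ sum + transitive + cyclical + nodematch("sex", "male"),
                   response = "count")
  expect_equal(ergm_stats(m2), ergm_stats(m))
})

test_that("change statistics equal full recomputation on random updates", {
  # binary directed terms
  adj <- rand_digraph(9, p = 0.3, seed = 3)
  attrs <- rand_attrs(rownames(adj), 3)
  net <- net_from(adj, weighted = FALSE, attrs = attrs)
  m <- ergm_model(net, ~ edges + mutual + transitive + cyclical +
                    nodematch("sex", "male") + nodemix("sex", "male", "female"))
  set.seed(10)
  for (k in 1:60) {
    i <- sample(9, 1); j <- sample(setdiff(1:9, i), 1)
    v <- 1L - adj[i, j]
    delta <- ergm_changestat(m, i, j, v)
    adj2 <- adj; adj2[i, j] <- v
    m2 <- ergm_model(net_from(adj2, weighted = FALSE, attrs = attrs),
                     ~ edges + mutual + transitive + cyclical +
                       nodematch("sex", "male") + nodemix("sex", "male", "female"))
    expect_equal(delta, ergm_stats(m2) - ergm_stats(m), info = paste("toggle", k))
  }
  # toggling a dyad twice restores the statistics
  d1 <- ergm_changestat(m, 2, 5, 1L - adj[2, 5])
  adjt <- adj; adjt[2, 5] <- 1L - adj[2, 5]
  mt <- ergm_model(net_from(adjt, weighted = FALSE, attrs = attrs),
                   ~ edges + mutual + transitive + cyclical +
                     nodematch("sex", "male") + nodemix("sex", "male", "female"))
  d2 <- ergm_changestat(mt, 2, 5, adj[2, 5])
  expect_equal(d1 + d2, setNames(rep(0, 6), names(d1)))
})

test_that("valued change statistics (incl. triad weights) match recomputation", {
  adj <- rand_countgraph(8, lambda = 1, seed = 6)
  attrs <- rand_attrs(rownames(adj), 6)
  rhs <- ~ sum + transitive + cyclical + sender("rankv") + absdiff("rankv")
  attrs$rankv <- seq_len(8)
  net <- net_from(adj, attrs = attrs)
  m <- ergm_model(net, rhs, response = "count")
  set.seed(20)
  for (k in 1:60) {
    i <- sample(8, 1); j <- sample(setdiff(1:8, i), 1)
    v <- sample(0:5, 1)
    delta <- ergm_changestat(m, i, j, v)
    adj2 <- adj; adj2[i, j] <- v
    m2 <- ergm_model(net_from(adj2, attrs = attrs), rhs, response = "count")
    expect_equal(delta, ergm_stats(m2) - ergm_stats(m), info = paste("update", k))
  }
})

test_that("undirected change statistics match recomputation", {
  adj <- rand_countgraph(7, seed = 8)
  adj <- adj + t(adj)
  attrs <- rand_attrs(rownames(adj), 8)
  attrs$rankv <- 7:1
  rhs <- ~ sum + nodecov("rankv") + absdiff("rankv")
  net <- net_from(adj, directed = FALSE, attrs = attrs)
  m <- ergm_model(net, rhs, response = "count")
  set.seed(30)
  for (k in 1:40) {
    i <- sample(7, 1); j <- sample(setdiff(1:7, i), 1)
    v <- sample(0:6, 1)
    delta <- ergm_changestat(m, i, j, v)
    adj2 <- adj; adj2[i, j] <- v; adj2[j, i] <- v
    m2 <- ergm_model(net_from(adj2, directed = FALSE, attrs = attrs),
                     rhs, response = "count")
    expect_equal(delta, ergm_stats(m2) - ergm_stats(m), info = paste("update", k))
  }
})

test_that("model validation enforces term/network compatibility", {
  adj <- rand_countgraph(5, seed = 1)
  un <- net_from(adj + t(adj), directed = FALSE)
  expect_error(ergm_model(un, ~ sum + mutual, response = "count"), "directed")
  expect_error(ergm_model(un, ~ sum + cyclical, response = "count"), "directed")
  dnet <- net_from(adj)
  expect_error(ergm_model(dnet, ~ sum + mutual, response = "count"), "mutual")
  expect_error(ergm_model(dnet, ~ sum + nodematch("colour", "red"),
                          response = "count"), "no node attribute")
  bnet <- net_from((adj > 0) + 0L, weighted = FALSE)
  expect_error(ergm_model(bnet, ~ edges, response = "count"), "weighted")
  expect_error(ergm_model(dnet, ~ edges, response = "binary"), "binary network")
})
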