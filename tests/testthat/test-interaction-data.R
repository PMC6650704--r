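test_that("interaction logs parse, validate and round-trip through CSV", {
  td <- withr::local_tempdir()
  lp <- file.path(td, "log.csv"); ap <- file.path(td, "attrs.csv")
  write.csv(data.frame(initiator = c("A", "B", "A"),
                       receiver = c("B", "A", "C"),
                       behaviour = c("submissive", "submissive", "aggressive")),
            lp, row.names = FALSE)
  write.csv(data.frame(id = c("A", "B", "C"),
                       sex = c("male", "female", "male"),
                       age_class = c("adult", "adult", "juvenile")),
            ap, row.names = FALSE)
  res <- read_interactions(lp, ap)
  expect_s3_class(res$log, "interaction_log")
  expect_equal(nrow(res$log), 3L)
  expect_equal(individuals(res$log), c("A", "B", "C"))

  # orphan individual in the log triggers a warning naming it
  write.csv(data.frame(initiator = "A", receiver = "Z", behaviour = "dominance"),
            lp, row.names = FALSE)
  expect_warning(read_interactions(lp, ap), "Z")
})

test_that("invalid records are rejected with informative errors", {
  expect_error(interaction_log(data.frame(initiator = "A", receiver = "A",
                                          behaviour = "submissive")),
               "self-interaction.*1")
  expect_error(interaction_log(data.frame(initiator = "A", receiver = "B",
                                          behaviour = "grooming")),
               "unknown behaviour")
  expect_error(interaction_log(data.frame(initiator = "A", behaviour = "dominance")),
               "missing required column")
})

test_that("network construction matches counting conventions", {
  log <- interaction_log(data.frame(
    initiator = c(rep("A", 3), "B"),
    receiver = c(rep("B", 3), "A"),
    behaviour = "submissive"))
  dw <- build_network(log, "submissive")
  expect_equal(unname(net_matrix(dw)), rbind(c(0L, 3L), c(1L, 0L)))
  uw <- build_network(log, "submissive", directed = FALSE)
  expect_true(isSymmetric(net_matrix(uw)))
  expect_equal(net_matrix(uw)["A", "B"], 4L)
  db <- build_network(log, "submissive", weighted = FALSE)
  expect_equal(unname(net_matrix(db)), rbind(c(0L, 1L), c(1L, 0L)))
  # binarisation is idempotent
  expect_equal(net_matrix(db) > 0, net_matrix(dw) > 0)
  expect_error(build_network(log, "grooming"), "unknown behaviour")
  expect_warning(build_network(log, "aggressive"), "no aggressive events")
})

test_that("network invariants hold on generated logs", {
  pack <- make_pack(seed = 11)
  log <- simulate_interactions(pack, pack_params(seed = 11))
  for (beh in c("submissive", "dominance", "aggressive")) {
    dw <- build_network(log, beh, attrs = pack$attrs)
    # total directed weight equals the number of events of that behaviour
    expect_equal(sum(net_matrix(dw)), sum(log$behaviour == beh))
    uw <- build_network(log, beh, directed = FALSE, attrs = pack$attrs)
    expect_equal(net_matrix(uw), net_matrix(dw) + t(net_matrix(dw)))
    # isolates retained: node set constant across behaviours
    expect_equal(dw$ids, sort(pack$attrs$id))
  }
})

test_that("networks round-trip through GraphML, edge lists and adjacency", {
  td <- withr::local_tempdir()
  adj <- rand_countgraph(6, seed = 4)
  net <- agonet(adj, attrs = rand_attrs(rownames(adj), 4), behaviour = "dominance")
  gp <- file.path(td, "net.graphml")
  write_network(net, gp, "graphml")
  back <- read_network(gp, "graphml")
  expect_equal(net_matrix(back), net_matrix(net))
  expect_equal(back$attrs$sex, net$attrs$sex)
  expect_equal(back$behaviour, "dominance")
  expect_true(back$directed)

  ep <- file.path(td, "net.csv")
  write_network(net, ep, "edgelist")
  back2 <- read_network(ep, "edgelist", directed = TRUE, attrs = net$attrs)
  expect_equal(net_matrix(back2), net_matrix(net))

  ap <- file.path(td, "adj.csv")
  write_network(net, ap, "adjacency")
  back3 <- read_network(ap, "adjacency", directed = TRUE)
  expect_equal(unname(net_matrix(back3)), unname(net_matrix(net)))

  # undirected edge list: one row per unordered pair
  un <- agonet(adj + t(adj), directed = FALSE)
  up <- file.path(td, "un.csv")
  write_network(un, up, "edgelist")
  df <- read.csv(up)
  expect_equal(nrow(df), sum(upper.tri(adj) & (adj + t(adj)) > 0))

  # empty network still round-trips
  e <- agonet(matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  ep0 <- file.path(td, "empty.graphml")
  write_network(e, ep0)
  expect_equal(read_network(ep0)$ids, c("a", "b", "c"))
})

test_that("agonet validation rejects malformed matrices", {
  m <- matrix(1L, 2, 2)
  expect_error(agonet(m), "self-loops")
  m2 <- rbind(c(0L, 1L), c(2L, 0L))
  expect_error(agonet(m2, directed = FALSE), "symmetric")
  expect_error(agonet(rbind(c(0L, 2L), c(0L, 0L)), weighted = FALSE), "binary")
})
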