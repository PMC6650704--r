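#' @useDynLib packdom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median coef vcov simulate optim glm binomial quantile
#'   setNames sd cor rpois rbinom plogis runif acf
#' @importFrom utils read.csv write.csv head
NULL

BEHAVIOURS <- c("submissive", "dominance", "aggressive")
SEXES <- c("male", "female")
AGE_CLASSES <- c("adult", "subadult", "juvenile")

#' Agonistic interaction network
#'
#' Constructs a network of agonistic interactions over a fixed set of
#' identified individuals: a square count (or 0/1) matrix plus node
#' attributes. Networks may be directed (initiator to receiver) or
#' undirected (total interaction frequency per pair), and weighted
#' (interaction counts) or binary (whether any interaction occurred).
#'
#' @param adj square numeric matrix of non-negative integer counts with
#'   zero diagonal; rows are initiators, columns receivers. Dimnames, if
#'   present, must agree with `ids`.
#' @param directed logical; `FALSE` requires a symmetric matrix.
#' @param weighted logical; `FALSE` requires entries in `{0, 1}`.
#' @param behaviour the behavioural category the network was built from
#'   (`"submissive"`, `"dominance"`, `"aggressive"`), or `NA`.
#' @param attrs data frame of node attributes with an `id` column
#'   matching the matrix order, typically also `sex` and `age_class`.
#' @return an object of class `agonet`.
#' @export
agonet <- function(adj, directed = TRUE, weighted = TRUE, behaviour = NA_character_,
                   attrs = NULL) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square")
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(n))
  storage.mode(adj) <- "integer"
  dimnames(adj) <- list(ids, ids)
  if (any(is.na(adj)) || any(adj < 0)) stop("weights must be non-negative integers")
  if (any(diag(adj) != 0)) stop("self-loops are not allowed (non-zero diagonal)")
  if (!directed && !isTRUE(all.equal(adj, t(adj), check.attributes = FALSE)))
    stop("undirected network requires a symmetric weight matrix")
  if (!weighted && any(adj > 1L))
    stop("binary network requires entries in {0, 1}")
  if (is.null(attrs)) {
    attrs <- data.frame(id = ids, stringsAsFactors = FALSE)
  } else {
    attrs <- as.data.frame(attrs)
    if (!"id" %in% names(attrs)) stop("attrs must contain an 'id' column")
    if (!setequal(attrs$id, ids)) stop("attrs ids do not match network node ids")
    attrs <- attrs[match(ids, attrs$id), , drop = FALSE]
    rownames(attrs) <- NULL
  }
  if (!is.na(behaviour) && !behaviour %in% BEHAVIOURS)
    stop("unknown behaviour label: ", behaviour)
  structure(list(adj = adj, ids = ids, directed = directed, weighted = weighted,
                 behaviour = behaviour, attrs = attrs),
            class = "agonet")
}

#' @export
print.agonet <- function(x, ...) {
  cat(sprintf("<agonet> %s, %s network of %s interactions: %d nodes, %s\n",
              if (x$directed) "directed" else "undirected",
              if (x$weighted) "weighted" else "binary",
              if (is.na(x$behaviour)) "unspecified" else x$behaviour,
              length(x$ids),
              if (x$weighted) sprintf("%d events", net_total(x))
              else sprintf("%d edges", net_total(x))))
  extra <- setdiff(names(x$attrs), "id")
  if (length(extra)) cat("  node attributes:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

net_total <- function(net) {
  s <- sum(net$adj)
  if (!net$directed) s <- s / 2L
  as.integer(s)
}

#' Extract the weight matrix of a network
#' @param net an [agonet] object
#' @return integer matrix with node ids as dimnames
#' @export
net_matrix <- function(net) net$adj

n_nodes <- function(net) length(net$ids)

#' Read an interaction log and attribute table
#'
#' Reads the event-level interaction log (one row per observed agonistic
#' event) and the per-individual attribute table, validating both. Each
#' event records who initiated the behaviour and who received it.
#'
#' @param path CSV with columns `initiator,receiver,behaviour` and
#'   optionally `context` and `date`.
#' @param attr_path CSV with columns `id,sex,age_class`.
#' @return a list with components `log` (an `interaction_log`) and
#'   `attrs` (validated attribute data frame). Individuals appearing in
#'   the log but missing from the attribute table trigger a warning
#'   naming them.
#' @export
read_interactions <- function(path, attr_path) {
  if (!file.exists(path)) stop("interaction log not found: ", path)
  if (!file.exists(attr_path)) stop("attribute table not found: ", attr_path)
  rec <- read.csv(path, stringsAsFactors = FALSE)
  attrs <- read.csv(attr_path, stringsAsFactors = FALSE)
  log <- interaction_log(rec)
  attrs <- validate_attrs(attrs)
  orphans <- setdiff(individuals(log), attrs$id)
  if (length(orphans))
    warning("individuals in the log but absent from the attribute table: ",
            paste(orphans, collapse = ", "))
  list(log = log, attrs = attrs)
}

#' Build an interaction log from a record data frame
#'
#' @param records data frame with columns `initiator`, `receiver`,
#'   `behaviour` (one of `"submissive"`, `"dominance"`, `"aggressive"`)
#'   and optional `context`/`date` columns, carried through unused.
#' @return an `interaction_log`: the validated records with the set of
#'   individuals attached.
#' @export
interaction_log <- function(records) {
  records <- as.data.frame(records)
  need <- c("initiator", "receiver", "behaviour")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  records$initiator <- as.character(records$initiator)
  records$receiver <- as.character(records$receiver)
  records$behaviour <- as.character(records$behaviour)
  bad <- which(records$initiator == records$receiver)
  if (length(bad))
    stop("self-interaction (initiator == receiver) in row(s): ",
         paste(head(bad, 10), collapse = ", "))
  unk <- setdiff(unique(records$behaviour), BEHAVIOURS)
  if (length(unk))
    stop("unknown behaviour label(s): ", paste(unk, collapse = ", "),
         " (expected submissive/dominance/aggressive)")
  structure(records,
            individuals = sort(unique(c(records$initiator, records$receiver))),
            class = c("interaction_log", "data.frame"))
}

#' @export
print.interaction_log <- function(x, ...) {
  cat(sprintf("<interaction_log> %d events among %d individuals\n",
              nrow(x), length(individuals(x))))
  tab <- table(factor(x$behaviour, levels = BEHAVIOURS))
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Individuals referenced by an interaction log
#' @param log an `interaction_log`
#' @export
individuals <- function(log) attr(log, "individuals")

validate_attrs <- function(attrs) {
  need <- c("id", "sex", "age_class")
  miss <- setdiff(need, names(attrs))
  if (length(miss)) stop("attribute table missing column(s): ", paste(miss, collapse = ", "))
  attrs$id <- as.character(attrs$id)
  if (anyDuplicated(attrs$id)) stop("duplicate individual ids in attribute table")
  if (any(is.na(attrs$sex)) || any(is.na(attrs$age_class)))
    stop("missing sex or age_class for modelled individuals")
  badsex <- setdiff(unique(attrs$sex), SEXES)
  if (length(badsex)) stop("unknown sex level(s): ", paste(badsex, collapse = ", "))
  badage <- setdiff(unique(attrs$age_class), AGE_CLASSES)
  if (length(badage)) stop("unknown age_class level(s): ", paste(badage, collapse = ", "))
  attrs[order(attrs$id), , drop = FALSE]
}

#' Build a behaviour-specific network from an interaction log
#'
#' Directed weighted entry (i, j) is the number of events with initiator
#' i and receiver j for the chosen behaviour; the undirected weighted
#' entry is the total frequency of interactions within the pair
#' regardless of direction; binary networks are the indicator of the
#' weighted ones. The node set is held fixed across behaviours:
#' individuals with no events of a behaviour remain as isolates, so that
#' models of different behaviours are comparable.
#'
#' @param log an `interaction_log`
#' @param behaviour which behavioural category to use
#' @param directed,weighted network form (see [agonet])
#' @param attrs optional attribute table; if supplied its `id` column
#'   defines the node set (plus any log-only individuals), otherwise the
#'   node set is every individual in the log. Nodes are ordered
#'   lexicographically by id.
#' @return an [agonet]
#' @export
build_network <- function(log, behaviour, directed = TRUE, weighted = TRUE,
                          attrs = NULL) {
  stopifnot(inherits(log, "interaction_log"))
  if (!behaviour %in% BEHAVIOURS)
    stop("unknown behaviour label: ", behaviour)
  ids <- individuals(log)
  if (!is.null(attrs)) {
    attrs <- validate_attrs(attrs)
    ids <- sort(union(attrs$id, ids))
    if (!all(ids %in% attrs$id)) {
      # orphans already warned about at read time; keep them with NA attrs
      extra <- setdiff(ids, attrs$id)
      pad <- attrs[rep(NA_integer_, length(extra)), , drop = FALSE]
      pad$id <- extra
      attrs <- rbind(attrs, pad)
      attrs <- attrs[order(attrs$id), , drop = FALSE]
    }
  }
  sub <- log[log$behaviour == behaviour, , drop = FALSE]
  if (nrow(sub) == 0L)
    warning("no ", behaviour, " events in the log; returning an empty network")
  n <- length(ids)
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(sub)) {
    tab <- table(factor(sub$initiator, levels = ids),
                 factor(sub$receiver, levels = ids))
    adj <- matrix(as.integer(tab), n, n, dimnames = list(ids, ids))
  }
  if (!directed) adj <- adj + t(adj)
  if (!weighted) adj <- (adj > 0L) + 0L
  agonet(adj, directed = directed, weighted = weighted,
         behaviour = behaviour, attrs = attrs)
}

#' Write a network to file
#'
#' @param net an [agonet]
#' @param path output file path
#' @param format `"graphml"` (node attributes as data, weights as the
#'   `weight` edge attribute), `"edgelist"` (CSV, one row per (ordered or
#'   unordered) connected pair), or `"adjacency"` (dense CSV).
#' @seealso [read_network()] for the inverse; `read_network(write_network(net))`
#'   reproduces the network exactly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist", "adjacency")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "agonet"))
  if (format == "graphml") {
    g <- igraph::graph_from_adjacency_matrix(net$adj,
      mode = if (net$directed) "directed" else "undirected",
      weighted = TRUE, diag = FALSE)
    igraph::V(g)$name <- net$ids
    for (col in setdiff(names(net$attrs), "id"))
      g <- igraph::set_vertex_attr(g, col, value = as.character(net$attrs[[col]]))
    g <- igraph::set_graph_attr(g, "behaviour", as.character(net$behaviour))
    g <- igraph::set_graph_attr(g, "weighted", as.character(net$weighted))
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    idx <- which(if (net$directed) net$adj > 0 else upper.tri(net$adj) & net$adj > 0,
                 arr.ind = TRUE)
    df <- data.frame(from = net$ids[idx[, 1]], to = net$ids[idx[, 2]],
                     weight = net$adj[idx], stringsAsFactors = FALSE)
    df <- df[order(df$from, df$to), , drop = FALSE]
    write.csv(df, path, row.names = FALSE)
  } else {
    write.csv(data.frame(id = net$ids, net$adj, check.names = FALSE),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' Only GraphML preserves the full object (attributes, directedness,
#' behaviour label); the CSV formats need them re-supplied.
#'
#' @param path file path
#' @param format as in [write_network()]
#' @param directed,weighted,behaviour,attrs metadata for the CSV formats
#' @export
read_network <- function(path, format = c("graphml", "edgelist", "adjacency"),
                         directed = TRUE, weighted = TRUE,
                         behaviour = NA_character_, attrs = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ids <- igraph::V(g)$name
    adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g)) "weight" else NULL,
                                                 sparse = FALSE))
    dimnames(adj) <- list(ids, ids)
    # igraph adds its own "id" node attribute on write; node identity is "name"
    acols <- setdiff(igraph::vertex_attr_names(g), c("name", "id"))
    attrs <- data.frame(id = ids, stringsAsFactors = FALSE)
    for (col in acols) attrs[[col]] <- igraph::vertex_attr(g, col)
    beh <- igraph::graph_attr(g, "behaviour")
    wt <- identical(igraph::graph_attr(g, "weighted"), "TRUE")
    ord <- order(ids)
    agonet(adj[ord, ord, drop = FALSE], directed = igraph::is_directed(g),
           weighted = wt, behaviour = if (is.null(beh) || beh == "NA") NA_character_ else beh,
           attrs = attrs[ord, , drop = FALSE])
  } else if (format == "edgelist") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    ids <- sort(unique(c(df$from, df$to, if (!is.null(attrs)) attrs$id)))
    adj <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    for (r in seq_len(nrow(df))) {
      adj[df$from[r], df$to[r]] <- df$weight[r]
      if (!directed) adj[df$to[r], df$from[r]] <- df$weight[r]
    }
    agonet(adj, directed, weighted, behaviour, attrs)
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df$id)
    adj <- as.matrix(df[, -1, drop = FALSE])
    dimnames(adj) <- list(ids, ids)
    agonet(adj, directed, weighted, behaviour, attrs)
  }
}
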