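# Term type codes shared with src/ergm.cpp
TERM_EDGES <- 0L; TERM_MUTUAL <- 1L; TERM_TRANSITIVE <- 2L; TERM_CYCLICAL <- 3L
TERM_NODEMATCH <- 4L; TERM_NODEMIX <- 5L; TERM_SENDER <- 6L
TERM_NODECOV <- 7L; TERM_ABSDIFF <- 8L

new_term <- function(type, name, x = numeric(0), z = numeric(0)) {
  list(type = type, name = name, x = as.numeric(x), z = as.numeric(z))
}

attr_vector <- function(net, attrname, numeric = FALSE) {
  v <- net$attrs[[attrname]]
  if (is.null(v)) stop("network has no node attribute '", attrname, "'")
  if (numeric) {
    v <- suppressWarnings(as.numeric(v))
    if (any(is.na(v))) stop("node attribute '", attrname, "' is not numeric")
  }
  v
}

indicator <- function(net, attrname, level) {
  v <- as.character(attr_vector(net, attrname))
  if (!level %in% v)
    stop("level '", level, "' not found in attribute '", attrname, "'")
  as.numeric(v == level)
}

# evaluation environment for RHS model terms; `net` and `valued` are
# captured so constructors can resolve attributes and pick stat names
term_constructors <- function(net, valued) {
  n <- length(net$ids)
  env <- new.env(parent = baseenv())
  env$edges <- function() new_term(TERM_EDGES, if (valued) "sum" else "edges",
                                   numeric(n), numeric(n))
  env$sum <- env$edges
  env$mutual <- function() new_term(TERM_MUTUAL, "mutual", numeric(n), numeric(n))
  env$transitive <- function() new_term(TERM_TRANSITIVE, "transitive", numeric(n), numeric(n))
  env$cyclical <- function() new_term(TERM_CYCLICAL, "cyclical", numeric(n), numeric(n))
  env$nodematch <- function(attrname, level)
    new_term(TERM_NODEMATCH, paste("nodematch", attrname, level, sep = "."),
             indicator(net, attrname, level), numeric(n))
  env$nodemix <- function(attrname, from, to)
    new_term(TERM_NODEMIX, paste("mix", attrname, from, to, sep = "."),
             indicator(net, attrname, from), indicator(net, attrname, to))
  env$sender <- function(attrname)
    new_term(TERM_SENDER, paste("sender", attrname, sep = "."),
             attr_vector(net, attrname, numeric = TRUE), numeric(n))
  env$nodecov <- function(attrname)
    new_term(TERM_NODECOV, paste("nodecov", attrname, sep = "."),
             attr_vector(net, attrname, numeric = TRUE), numeric(n))
  env$absdiff <- function(attrname)
    new_term(TERM_ABSDIFF, paste("absdiff", attrname, sep = "."),
             attr_vector(net, attrname, numeric = TRUE), numeric(n))
  env
}

#' Specify an exponential random graph model
#'
#' Binds a network to an ordered list of sufficient-statistic terms and
#' a response type. Binary models describe the probability of an
#' interaction occurring; count models (Poisson reference) describe
#' interaction frequency.
#'
#' Available terms: `edges`/`sum` (density or total weight), `mutual`
#' (reciprocated dyads; binary directed only), `transitive` and
#' `cyclical` (triadic closure and cycling; on count networks these use
#' the min-within-path, max-over-paths weight transform),
#' `nodematch(attr, level)`, `nodemix(attr, from, to)` (directed
#' class-mixing, e.g. interactions from males towards females),
#' `sender(attr)` (initiator covariate), `nodecov(attr)` and
#' `absdiff(attr)`. On count networks attribute terms are
#' weight-multiplied.
#'
#' @param net an [agonet]
#' @param rhs one-sided formula of terms, e.g.
#'   `~ edges + mutual + transitive + cyclical + nodematch("sex", "male")`
#' @param response `"binary"` or `"count"`; defaults to match the network
#' @return an object of class `ergm_model`
#' @export
ergm_model <- function(net, rhs, response = NULL) {
  stopifnot(inherits(net, "agonet"))
  if (is.null(response)) response <- if (net$weighted) "count" else "binary"
  response <- match.arg(response, c("binary", "count"))
  if (response == "binary" && net$weighted)
    stop("binary model requires a binary network (build with weighted = FALSE)")
  if (response == "count" && !net$weighted)
    stop("count model requires a weighted network")
  valued <- response == "count"
  labels <- attr(stats::terms(rhs), "term.labels")
  if (!length(labels)) stop("model must contain at least one term")
  env <- term_constructors(net, valued)
  terms <- lapply(labels, function(lab) {
    ex <- str2lang(lab)
    if (is.name(ex)) ex <- as.call(list(ex))
    if (!exists(as.character(ex[[1]]), envir = env, inherits = FALSE))
      stop("unknown model term: ", lab)
    eval(ex, env)
  })
  for (tm in terms) {
    if (tm$type %in% c(TERM_MUTUAL, TERM_CYCLICAL, TERM_NODEMIX, TERM_SENDER) &&
        !net$directed)
      stop("term '", tm$name, "' requires a directed network")
    if (tm$type == TERM_MUTUAL && valued)
      stop("mutual terms are not supported in count models ",
           "(they prevent convergence of the valued fits)")
  }
  nm <- vapply(terms, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate model terms: ", nm[duplicated(nm)][1])
  structure(list(net = net, terms = terms, response = response,
                 term_names = nm, formula = rhs),
            class = "ergm_model")
}

#' @export
print.ergm_model <- function(x, ...) {
  cat(sprintf("<ergm_model> %s response, %d terms: %s\n", x$response,
              length(x$terms), paste(x$term_names, collapse = " + ")))
  invisible(x)
}

term_args <- function(model) {
  list(type = vapply(model$terms, `[[`, 0L, "type"),
       xs = lapply(model$terms, `[[`, "x"),
       zs = lapply(model$terms, `[[`, "z"))
}

#' Network sufficient statistics g(y)
#'
#' @param model an [ergm_model]
#' @param net network to evaluate on (defaults to the model's network;
#'   must share the node set)
#' @return named numeric vector, one statistic per term
#' @export
ergm_stats <- function(model, net = model$net) {
  stopifnot(inherits(model, "ergm_model"))
  check_same_nodes(model$net, net)
  ta <- term_args(model)
  setNames(cpp_stats(net$adj, net$directed, model$response == "count",
                     ta$type, ta$xs, ta$zs),
           model$term_names)
}

#' Change statistics for a single-dyad update
#'
#' The difference `g(y') - g(y)` where `y'` equals `y` except that dyad
#' `(i, j)` is set to `value` (both directions for undirected networks).
#' Computed locally, without a full recount.
#'
#' @param model an [ergm_model]
#' @param i,j node indices or ids (off-diagonal)
#' @param value new dyad value (0/1 for binary models)
#' @param net network to evaluate on (defaults to the model's)
#' @return named numeric vector of statistic changes
#' @export
ergm_changestat <- function(model, i, j, value, net = model$net) {
  stopifnot(inherits(model, "ergm_model"))
  if (is.character(i)) i <- match(i, net$ids)
  if (is.character(j)) j <- match(j, net$ids)
  if (is.na(i) || is.na(j) || i == j) stop("dyad must be two distinct nodes")
  ta <- term_args(model)
  setNames(cpp_changestat(net$adj, net$directed, model$response == "count",
                          ta$type, ta$xs, ta$zs, i, j, as.integer(value)),
           model$term_names)
}

check_same_nodes <- function(a, b) {
  if (!identical(a$ids, b$ids))
    stop("networks do not share the same node set")
  invisible(TRUE)
}
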