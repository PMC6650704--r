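#' Control parameters for network simulation
#'
#' @param n_networks number of networks to draw (1000 by default, the
#'   ensemble size used for the goodness-of-fit surface)
#' @param burnin proposals before the first retained draw
#' @param interval proposals between retained draws; `NULL` uses one
#'   expected sweep of the free dyads
#' @param seed integer RNG seed
#' @export
sim_control <- function(n_networks = 1000, burnin = 1e4, interval = NULL,
                        seed = 1L) {
  stopifnot(n_networks >= 1, burnin >= 0, is.null(interval) || interval >= 1)
  structure(list(n_networks = as.integer(n_networks),
                 burnin = as.integer(burnin),
                 interval = if (is.null(interval)) NULL else as.integer(interval),
                 seed = as.integer(seed)),
            class = "sim_control")
}

#' Simulate networks from an ERGM at given coefficients
#'
#' Metropolis-Hastings over single-dyad updates: binary models toggle a
#' uniformly chosen dyad with acceptance probability
#' `exp(theta . delta)`; count models propose +/-1 steps (rejected below
#' zero) with the Poisson reference ratio included in the acceptance
#' probability. The template supplies the node set, attributes and the
#' starting state; it is never modified. Identical inputs (including
#' the control seed) give identical output.
#'
#' @param model an [ergm_model]
#' @param theta coefficient vector, one per model term
#' @param template starting network (defaults to the model's network)
#' @param control a [sim_control()]
#' @param output `"networks"` for a list of [agonet] draws (with the
#'   statistics matrix attached as attribute `"stats"`), or `"stats"`
#'   for just the statistics matrix
#' @return list of networks, or a numeric matrix of statistics
#' @export
simulate_networks <- function(model, theta, template = model$net,
                              control = sim_control(),
                              output = c("networks", "stats")) {
  output <- match.arg(output)
  stopifnot(inherits(model, "ergm_model"), inherits(control, "sim_control"))
  check_same_nodes(model$net, template)
  theta <- as.numeric(theta)
  if (length(theta) != length(model$terms))
    stop("theta must have one coefficient per model term")
  if (any(!is.finite(theta))) stop("theta must be finite")
  ta <- term_args(model)
  valued <- model$response == "count"
  set.seed(control$seed)
  sim <- cpp_ergm_sample(template$adj, template$directed, valued,
                         ta$type, ta$xs, ta$zs, theta,
                         control$burnin, resolve_interval(control$interval, template),
                         control$n_networks, output == "networks",
                         sim_vmax(template, valued))
  stats <- sim$stats
  colnames(stats) <- model$term_names
  if (output == "stats") return(stats)
  nets <- lapply(sim$nets, function(adj) {
    dimnames(adj) <- dimnames(template$adj)
    agonet(adj, directed = template$directed, weighted = template$weighted,
           behaviour = template$behaviour, attrs = template$attrs)
  })
  attr(nets, "stats") <- stats
  nets
}

#' @describeIn packergm simulate networks from a fitted model at its
#'   estimated coefficients.
#' @param object a fitted `packergm`
#' @param nsim number of networks
#' @param seed RNG seed for the draw
#' @param ... passed to [sim_control()] (`burnin`, `interval`)
#' @export
simulate.packergm <- function(object, nsim = 1000, seed = 1L, ...,
                              output = c("networks", "stats")) {
  ctl <- sim_control(n_networks = nsim, seed = seed, ...)
  simulate_networks(object$model, coef(object), control = ctl,
                    output = match.arg(output))
}

#' Statistics of a simulated ensemble
#'
#' Evaluates the model's sufficient statistics on each network of an
#' ensemble and summarises them (mean and Monte-Carlo standard error
#' per term).
#'
#' @param nets non-empty list of [agonet] networks (e.g. from
#'   [simulate_networks()])
#' @param model an [ergm_model]
#' @return data frame of per-network statistics with a `summary`
#'   attribute (term, mean, mcse)
#' @export
ensemble_statistics <- function(nets, model) {
  stopifnot(length(nets) >= 1)
  stats <- t(vapply(nets, function(nt) ergm_stats(model, nt),
                    numeric(length(model$terms))))
  colnames(stats) <- model$term_names
  df <- as.data.frame(stats)
  smry <- data.frame(term = model$term_names,
                     mean = colMeans(stats),
                     mcse = apply(stats, 2, function(x)
                       if (length(x) > 1) sd(x) / sqrt(ess(x)) else 0),
                     row.names = NULL)
  attr(df, "summary") <- smry
  df
}
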