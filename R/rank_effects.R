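#' Rank covariates for hierarchy-position models
#'
#' Per individual: ordinal `rank` (1 = most dominant) and
#' `centre_distance`, the absolute distance of the rank from the centre
#' of the hierarchy `(N + 1) / 2` (zero mid-hierarchy, maximal at both
#' ends). The dyadic absolute rank difference enters models through the
#' `absdiff("rank")` term.
#'
#' @param ranking an `isi_rank` or named rank vector
#' @param standardize z-score the two node covariates
#' @return data frame `id, rank, centre_distance`
#' @export
rank_covariates <- function(ranking, standardize = FALSE) {
  r <- if (inherits(ranking, "isi_rank")) ranking$ranks else ranking
  if (is.null(names(r))) stop("ranking must carry individual ids")
  n <- length(r)
  out <- data.frame(id = names(r), rank = as.numeric(r),
                    centre_distance = abs(as.numeric(r) - (n + 1) / 2),
                    stringsAsFactors = FALSE)
  if (standardize) {
    out$rank <- as.numeric(scale(out$rank))
    out$centre_distance <- as.numeric(scale(out$centre_distance))
  }
  out[order(out$id), , drop = FALSE]
}

with_rank_attrs <- function(net, ranking, standardize = FALSE) {
  rc <- rank_covariates(ranking, standardize)
  attrs <- net$attrs
  attrs$rank <- NULL; attrs$centre_distance <- NULL
  attrs <- merge(attrs, rc, by = "id", sort = TRUE)
  agonet(net$adj, net$directed, net$weighted, net$behaviour, attrs)
}

check_rank_model_net <- function(net, directed) {
  stopifnot(inherits(net, "agonet"))
  if (identical(net$behaviour, "submissive"))
    stop("rank-based models are not fitted to submissive networks: ",
         "ranks are derived from submissive interactions, so the model ",
         "would be circular")
  if (!net$weighted) stop("rank models are count models; need a weighted network")
  if (directed && !net$directed) stop("this model needs a directed network")
  if (!directed && net$directed) stop("this model needs an undirected network")
}

#' Directed rank model of interaction initiation
#'
#' A count ERGM of the weighted directed network in which an
#' individual's rank explains the interactions it initiates: total
#' weight, valued transitive and cyclical closure, and a sender rank
#' covariate. Because rank 1 is the most dominant, a negative sender
#' coefficient means higher-ranked individuals initiate more. Fits of
#' this model seed the goodness-of-fit ensemble. Refused for submissive
#' networks, whose data defined the ranks.
#'
#' @param net directed weighted [agonet] of dominance or aggressive
#'   interactions
#' @param ranking an `isi_rank` or named rank vector
#' @param control an [ergm_control()]
#' @param transitivity include the valued transitive/cyclical terms
#' @param standardize z-score the rank covariate
#' @param method `"mcmle"` or `"mple"`
#' @return a `packergm`
#' @export
fit_directed_rank_model <- function(net, ranking, control = ergm_control(),
                                    transitivity = TRUE, standardize = FALSE,
                                    method = "mcmle") {
  check_rank_model_net(net, directed = TRUE)
  net2 <- with_rank_attrs(net, ranking, standardize)
  rhs <- if (transitivity) net2 ~ sum + transitive + cyclical + sender("rank")
         else net2 ~ sum + sender("rank")
  environment(rhs) <- environment()
  packergm(rhs, response = "count", method = method, control = control)
}

#' Undirected rank model of interaction frequency
#'
#' A count ERGM of the weighted undirected network in which rank
#' explains how often dyads interact: total weight plus three rank
#' covariates - node rank, node distance from the hierarchy centre, and
#' the dyad's absolute rank difference. Negative centre-distance and
#' rank-difference coefficients mean interactions concentrate among
#' central, closely ranked individuals.
#'
#' @inheritParams fit_directed_rank_model
#' @param transitivity include a valued transitive term (off by
#'   default; the covariate set is the minimal faithful one)
#' @return a `packergm`
#' @export
fit_undirected_rank_model <- function(net, ranking, control = ergm_control(),
                                      transitivity = FALSE, standardize = FALSE,
                                      method = "mcmle") {
  check_rank_model_net(net, directed = FALSE)
  if (length(net$ids) < 3) stop("rank model needs at least 3 individuals")
  net2 <- with_rank_attrs(net, ranking, standardize)
  rhs <- if (transitivity)
    net2 ~ sum + transitive + nodecov("rank") + nodecov("centre_distance") + absdiff("rank")
  else
    net2 ~ sum + nodecov("rank") + nodecov("centre_distance") + absdiff("rank")
  environment(rhs) <- environment()
  packergm(rhs, response = "count", method = method, control = control)
}

#' Conditional estimates and confidence intervals of a rank model
#'
#' @param fit a `packergm` from one of the rank-model fitters
#' @param level confidence level
#' @return data frame `term, estimate, lower, upper` (forest-plot
#'   layout, one row per covariate)
#' @export
rank_effects_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "packergm"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- coef(fit); se <- fit$se
  data.frame(term = names(est), estimate = unname(est),
             lower = unname(est - z * se), upper = unname(est + z * se),
             stringsAsFactors = FALSE)
}

#' Forest plot of rank-model estimates
#'
#' @param fit a `packergm`
#' @param level confidence level
#' @export
plot_rank_effects <- function(fit, level = 0.95) {
  tab <- rank_effects_table(fit, level)
  n <- nrow(tab)
  graphics::plot(tab$estimate, seq_len(n), xlim = range(c(tab$lower, tab$upper, 0)),
                 ylim = c(0.5, n + 0.5), yaxt = "n", pch = 19,
                 xlab = "conditional estimate", ylab = "")
  graphics::segments(tab$lower, seq_len(n), tab$upper, seq_len(n))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(n), labels = tab$term, las = 1, cex.axis = 0.8)
  invisible(tab)
}
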