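#' Control parameters for ERGM estimation
#'
#' @param burnin proposals discarded before the first retained network
#' @param interval proposals between retained networks; `NULL` (the
#'   default) uses one expected sweep of the free dyads, the smallest
#'   interval at which retained draws can be close to independent
#' @param samplesize networks retained per estimation iteration
#' @param maxit maximum Monte-Carlo likelihood iterations
#' @param tol convergence tolerance: the fit is accepted when every
#'   term's simulated mean lies within `tol` simulation standard
#'   deviations of its observed statistic
#' @param seed integer RNG seed; estimation is deterministic given the
#'   seed
#' @param vmax support cap for the count-model pseudolikelihood (per-dyad
#'   full conditionals are evaluated on 0..vmax); `NULL` picks a cap
#'   well above the largest observed count
#' @param degeneracy_sd drift threshold (in simulation SDs) for the
#'   degeneracy guard
#' @return a list of class `ergm_control`
#' @export
ergm_control <- function(burnin = 1e4, interval = NULL, samplesize = 1000,
                         maxit = 20, tol = 0.1, seed = 1L, vmax = NULL,
                         degeneracy_sd = 5) {
  stopifnot(burnin >= 0, is.null(interval) || interval >= 1, samplesize >= 10,
            maxit >= 1, tol > 0)
  if (!is.null(interval)) interval <- as.integer(interval)
  structure(list(burnin = as.integer(burnin), interval = interval,
                 samplesize = as.integer(samplesize), maxit = as.integer(maxit),
                 tol = tol, seed = as.integer(seed), vmax = vmax,
                 degeneracy_sd = degeneracy_sd),
            class = "ergm_control")
}

# per-dyad design for the pseudolikelihood; binary: change statistic of
# 0 -> 1; count: statistic profile over v = 0..vmax
mple_table <- function(model, vmax = NULL) {
  net <- model$net
  ta <- term_args(model)
  valued <- model$response == "count"
  if (!valued) vmax <- 1L
  if (is.null(vmax)) vmax <- max(3L * max(net$adj) + 15L, 30L)
  cpp_dyad_table(net$adj, net$directed, valued, ta$type, ta$xs, ta$zs,
                 as.integer(vmax))
}

#' Maximum pseudolikelihood estimation
#'
#' Binary response: logistic regression of each dyad's state on its
#' change statistics. Count response (Poisson reference): maximises the
#' product over dyads of the full-conditional probability mass, each
#' dyad's conditional evaluated on a truncated support `0..vmax`, by
#' BFGS with analytic gradient; standard errors from the observed
#' pseudo-information.
#'
#' @param model an [ergm_model]
#' @param vmax see [ergm_control()]
#' @return a list with `theta`, `se`, `vcov`, `method = "MPLE"`
#' @export
fit_mple <- function(model, vmax = NULL) {
  stopifnot(inherits(model, "ergm_model"))
  tab <- mple_table(model, vmax)
  p <- length(model$terms)
  nd <- length(tab$yobs)
  dims <- dim(tab$delta)
  if (model$response == "binary") {
    X <- matrix(tab$delta[, 2L, ], nd, p)
    colnames(X) <- model$term_names
    qrX <- qr(X)
    if (qrX$rank < p) {
      dropped <- model$term_names[-qrX$pivot[seq_len(qrX$rank)]]
      stop("degenerate model: term(s) inestimable (aliased): ",
           paste(dropped, collapse = ", "))
    }
    fit <- suppressWarnings(glm(tab$yobs ~ X - 1, family = binomial()))
    th <- unname(coef(fit))
    if (any(!is.finite(th)) || any(abs(th) > 15))
      stop("degenerate model: apparent separation in term '",
           model$term_names[which.max(abs(th))], "'")
    sm <- summary(fit)
    se <- unname(sm$coefficients[, "Std. Error"])
    V <- unname(sm$cov.unscaled)
  } else {
    Q <- dims[2]
    lf <- lgamma(seq_len(Q))            # log(v!) for v = 0..vmax
    D <- matrix(tab$delta, nd * Q, p)   # (dyad, v) rows
    yid <- cbind(seq_len(nd), tab$yobs + 1L)
    nll <- function(th) {
      eta <- matrix(D %*% th, nd, Q) - rep(lf, each = nd)
      m <- apply(eta, 1, max)
      logZ <- m + log(rowSums(exp(eta - m)))
      sum(logZ - eta[yid])
    }
    rows_obs <- seq_len(nd) + nd * tab$yobs
    obs <- colSums(D[rows_obs, , drop = FALSE])
    grad <- function(th) {
      eta <- matrix(D %*% th, nd, Q) - rep(lf, each = nd)
      m <- apply(eta, 1, max)
      w <- exp(eta - m); w <- w / rowSums(w)
      as.numeric(crossprod(as.numeric(w), D)) - obs
    }
    th0 <- numeric(p)
    est <- optim(th0, nll, grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    th <- est$par
    # pseudo-information: sum over dyads of Var of the change profile
    eta <- matrix(D %*% th, nd, Q) - rep(lf, each = nd)
    m <- apply(eta, 1, max)
    w <- exp(eta - m); w <- w / rowSums(w)
    H <- matrix(0, p, p)
    for (t1 in seq_len(p)) {
      Dt1 <- matrix(D[, t1], nd, Q)
      E1 <- rowSums(w * Dt1)
      for (t2 in t1:p) {
        Dt2 <- matrix(D[, t2], nd, Q)
        E2 <- rowSums(w * Dt2)
        H[t1, t2] <- H[t2, t1] <- sum(rowSums(w * Dt1 * Dt2) - E1 * E2)
      }
    }
    V <- tryCatch(solve(H), error = function(e)
      stop("degenerate model: singular pseudo-information ",
           "(a term may be constant across dyads)"))
    se <- sqrt(pmax(diag(V), 0))
    if (any(!is.finite(th)) || any(se == 0))
      stop("degenerate model: term '",
           model$term_names[which(se == 0)[1]], "' carries no information")
  }
  list(theta = setNames(th, model$term_names),
       se = setNames(se, model$term_names), vcov = V, method = "MPLE")
}

logmeanexp <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }

n_free_dyads <- function(net) {
  n <- length(net$ids)
  if (net$directed) n * (n - 1L) else as.integer(n * (n - 1L) / 2)
}

resolve_interval <- function(interval, net) {
  if (is.null(interval)) as.integer(n_free_dyads(net)) else as.integer(interval)
}

# support cap for the count sampler's full conditionals
sim_vmax <- function(net, valued) {
  if (valued) max(3L * max(net$adj) + 20L, 30L) else 1L
}

# effective sample size from the initial-positive-sequence autocorrelation
ess <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(n)
  a <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(a < 0)
  if (length(neg)) a <- a[seq_len(neg[1] - 1)]
  max(1, n / (1 + 2 * sum(a)))
}

geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  v <- var(a) / ess(a) + var(b) / ess(b)
  if (v <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(v)
}

sim_summary <- function(stats, g_obs) {
  data.frame(term = colnames(stats),
             observed = as.numeric(g_obs),
             sim_mean = colMeans(stats),
             sim_sd = apply(stats, 2, sd),
             ess = apply(stats, 2, ess),
             mcse = apply(stats, 2, function(x) sd(x) / sqrt(ess(x))),
             geweke_z = apply(stats, 2, geweke_z),
             row.names = NULL)
}

#' Fit an exponential random graph model
#'
#' The main fitting function. The left-hand side of the formula is an
#' [agonet]; the right-hand side lists model terms (see [ergm_model()]).
#' Estimation starts from the maximum pseudolikelihood estimate and, for
#' `method = "mcmle"`, refines it by Monte-Carlo maximum likelihood:
#' networks are simulated at the current coefficients and the
#' coefficients updated by importance-sampling Newton steps until the
#' simulated mean statistics match the observed ones to within
#' `control$tol` simulation standard deviations. Standard errors come
#' from the inverse of the simulated-statistic covariance (the Fisher
#' information of an exponential family); MPLE fits use the
#' pseudolikelihood information instead.
#'
#' @param formula `network ~ term + term + ...`
#' @param response `"binary"` or `"count"` (default matches the network)
#' @param method `"mcmle"` (default) or `"mple"`
#' @param control an [ergm_control()]
#' @return an object of class `packergm` with `coef`, `vcov`, `summary`,
#'   `simulate` and `plot` methods
#' @examples
#' pack <- make_pack(seed = 1)
#' log <- simulate_interactions(pack, pack_params(seed = 1))
#' net <- build_network(log, "submissive", weighted = FALSE, attrs = pack$attrs)
#' fit <- packergm(net ~ edges + mutual + transitive + cyclical,
#'                 control = ergm_control(samplesize = 300, seed = 1))
#' summary(fit)
#' @export
packergm <- function(formula, response = NULL, method = c("mcmle", "mple"),
                     control = ergm_control()) {
  method <- match.arg(method)
  stopifnot(inherits(control, "ergm_control"))
  net <- eval(formula[[2]], environment(formula))
  rhs <- formula(paste("~", deparse1(formula[[3]])))
  model <- ergm_model(net, rhs, response)
  g_obs <- ergm_stats(model)
  mple <- fit_mple(model, control$vmax)
  out <- list(model = model, observed_stats = g_obs, mple = mple,
              control = control, call = match.call())
  if (method == "mple") {
    out <- c(out, list(coefficients = mple$theta, se = mple$se,
                       vcov = mple$vcov, method = "MPLE",
                       converged = TRUE, iterations = 0L,
                       diagnostics = NULL, sim_stats = NULL))
    class(out) <- "packergm"
    return(out)
  }
  mc <- tryCatch(mcmle_refine(model, g_obs, mple$theta, control),
                 error = function(e) e)
  if (inherits(mc, "error") || !mc$converged) {
    # near-degenerate triadic models can put the MPLE in the wrong basin;
    # retry from the density-matching baseline, with a larger iteration
    # budget since partial steps approach slowly from far away
    ctl2 <- control
    ctl2$maxit <- 3L * control$maxit
    mc2 <- tryCatch(mcmle_refine(model, g_obs, baseline_theta(model), ctl2),
                    error = function(e) e)
    mc <- if (inherits(mc2, "error")) mc
          else if (inherits(mc, "error") || mc2$converged ||
                   max(abs(mc2$diagnostics$moment_z)) <
                     max(abs(mc$diagnostics$moment_z))) mc2
          else mc
    if (inherits(mc, "error")) stop(mc)
  }
  out <- c(out, mc)
  class(out) <- "packergm"
  out
}

# zero coefficients except a density-matching edges/sum term
baseline_theta <- function(model) {
  p <- length(model$terms)
  th <- numeric(p)
  net <- model$net
  valued <- model$response == "count"
  k <- which(vapply(model$terms, `[[`, 0L, "type") == TERM_EDGES)
  if (length(k)) {
    nd <- n_free_dyads(net)
    mean_y <- sum(net$adj) / (if (net$directed) 1 else 2) / nd
    th[k[1]] <- if (valued) log(max(mean_y, 1e-4))
                else { d <- max(min(mean_y, 1 - 1e-4), 1e-4); log(d / (1 - d)) }
  }
  setNames(th, model$term_names)
}

# Monte-Carlo MLE refinement loop
mcmle_refine <- function(model, g_obs, theta, control) {
  p <- length(theta)
  ta <- term_args(model)
  net <- model$net
  valued <- model$response == "count"
  prev_z <- NULL
  converged <- FALSE
  stats <- NULL
  interval <- resolve_interval(control$interval, net)
  vmax <- sim_vmax(net, valued)
  base_theta <- baseline_theta(model)
  theta_prev <- NULL
  best <- list(score = Inf)
  frozen_tries <- 0L
  for (it in seq_len(control$maxit)) {
    set.seed(control$seed + 7919L * it)
    sim <- cpp_ergm_sample(net$adj, net$directed, valued, ta$type, ta$xs, ta$zs,
                           as.numeric(theta), control$burnin, interval,
                           control$samplesize, FALSE, vmax)
    stats <- sim$stats
    colnames(stats) <- model$term_names
    mu <- colMeans(stats)
    sdv <- apply(stats, 2, sd)
    if (any(sdv == 0)) {
      frozen <- which(sdv == 0)
      if (any(abs(mu[frozen] - g_obs[frozen]) > 1e-8)) {
        # chain absorbed away from the data (typically at the empty or
        # complete graph after an overshooting step): back the step off
        frozen_tries <- frozen_tries + 1L
        if (frozen_tries > 6L)
          stop("degenerate model: simulated '",
               model$term_names[frozen[1]],
               "' is frozen away from its observed value")
        theta <- if (!is.null(theta_prev)) (theta + theta_prev) / 2
                 else (theta + base_theta) / 2
        next
      }
      sdv[sdv == 0] <- 1e-8
    }
    z <- (mu - g_obs) / sdv
    if (max(abs(z)) < best$score)
      best <- list(score = max(abs(z)), theta = theta, stats = stats, it = it)
    if (max(abs(z)) < control$tol) { converged <- TRUE; break }
    if (!is.null(prev_z)) {
      # divergence signal: the absolute moment gap grows while already
      # far outside the simulated spread, in a consistent direction --
      # back the last step off, and only give up when backing off has
      # been exhausted
      drift <- sign(z) == sign(prev_z$z) &
        abs(z) > control$degeneracy_sd &
        abs(prev_z$z) > control$degeneracy_sd &
        abs(mu - g_obs) > 1.5 * abs(prev_z$gap)
      if (any(drift)) {
        frozen_tries <- frozen_tries + 1L
        if (frozen_tries > 6L)
          stop("degenerate model: statistic '",
               model$term_names[which(drift)[1]],
               "' drifts away from its observed value (",
               sprintf("%.1f", z[which(drift)[1]]), " SD)")
        theta <- if (!is.null(theta_prev)) (theta + theta_prev) / 2
                 else (theta + base_theta) / 2
        next
      }
    }
    frozen_tries <- 0L
    prev_z <- list(z = z, gap = abs(mu - g_obs))
    theta_prev <- theta
    theta <- mcmle_step(theta, stats, g_obs)
  }
  if (!converged && is.finite(best$score)) {
    # an oscillating search can end worse than it passed through:
    # report the best coefficients visited
    theta <- best$theta
    stats <- best$stats
  }
  if (is.null(stats))
    stop("degenerate model: no usable simulation obtained")
  V <- stats::cov(stats)
  Vi <- tryCatch(solve(V), error = function(e) solve(V + diag(1e-8, p)))
  se <- sqrt(pmax(diag(Vi), 0))
  diag_df <- sim_summary(stats, g_obs)
  # floor the SD so a statistic frozen exactly at its observed value
  # (e.g. an all-zero mixing cell) yields z = 0, not 0/0
  diag_df$moment_z <- (diag_df$sim_mean - diag_df$observed) /
    pmax(diag_df$sim_sd, 1e-8)
  list(coefficients = setNames(as.numeric(theta), model$term_names),
       se = setNames(se, model$term_names), vcov = Vi, method = "MCMC-MLE",
       converged = converged, iterations = it, diagnostics = diag_df,
       sim_stats = stats)
}

# damped Newton update with partial stepping: the score of the MC
# log-likelihood ratio is g_obs - mu and its Hessian the simulated
# covariance. When the observed statistics lie far outside the simulated
# cloud the local quadratic model is unreliable (and with triadic terms
# invites the degenerate zigzag between near-empty and near-complete
# graphs), so the step targets a point at most ~2 Mahalanobis units out;
# it is then halved until the implied importance weights retain a
# healthy effective sample size
mcmle_step <- function(theta, stats, g_obs) {
  S <- nrow(stats)
  V <- stats::cov(stats)
  mu <- colMeans(stats)
  gap <- g_obs - mu
  d <- tryCatch(solve(V + diag(1e-8 * pmax(diag(V), 1), nrow(V)), gap),
                error = function(e) gap / pmax(diag(V), 1e-12))
  dist <- sqrt(max(sum(gap * d), 0))
  if (is.finite(dist) && dist > 2) d <- d * (2 / dist)
  # coefficient-space cap: with a near-degenerate simulated covariance a
  # short Mahalanobis step can still be an enormous theta move straight
  # into the super-critical regime
  sc <- max(abs(d))
  if (is.finite(sc) && sc > 0.5) d <- d * (0.5 / sc)
  for (k in 1:40) {
    lw <- as.numeric(stats %*% d); lw <- lw - max(lw)
    w <- exp(lw); w <- w / sum(w)
    if (1 / sum(w^2) >= 0.2 * S) break
    d <- d / 2
  }
  theta + as.numeric(d)
}

#' @export
coef.packergm <- function(object, ...) object$coefficients

#' @export
vcov.packergm <- function(object, ...) object$vcov

#' @export
print.packergm <- function(x, ...) {
  cat(sprintf("<packergm> %s fit (%s response): %s\n", x$method,
              x$model$response,
              paste(x$model$term_names, collapse = " + ")))
  print(round(x$coefficients, 3))
  if (!is.null(x$converged) && !x$converged)
    cat("  warning: moment condition not met within maxit iterations\n")
  invisible(x)
}

#' @export
summary.packergm <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  stars <- cut(pval, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  tab <- data.frame(term = names(est), estimate = unname(est),
                    std_error = unname(se), z = unname(z),
                    p_value = unname(pval), sig = as.character(stars),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, method = object$method,
                 response = object$model$response,
                 behaviour = object$model$net$behaviour,
                 converged = object$converged,
                 iterations = object$iterations,
                 diagnostics = object$diagnostics),
            class = "summary.packergm")
}

#' @export
print.summary.packergm <- function(x, ...) {
  cat(sprintf("%s %s-response model of %s interactions\n", x$method,
              x$response,
              if (is.na(x$behaviour)) "network" else x$behaviour))
  tab <- x$table
  tab$estimate <- sprintf("% .3f", tab$estimate)
  tab$std_error <- sprintf("%.3f", tab$std_error)
  tab$z <- sprintf("% .2f", tab$z)
  tab$p_value <- sprintf("%.4f", tab$p_value)
  print(tab, row.names = FALSE)
  if (!is.null(x$diagnostics))
    cat(sprintf("moment condition: max |z| = %.3f over %d iterations%s\n",
                max(abs(x$diagnostics$moment_z)), x$iterations,
                if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' MCMC diagnostics plot for a fitted model
#'
#' One panel per term: the trace of the simulated statistic from the
#' final estimation sample with the observed value overlaid.
#' @param x a `packergm` from an MCMC-MLE fit
#' @param ... unused
#' @export
plot.packergm <- function(x, ...) {
  if (is.null(x$sim_stats)) {
    warning("no simulation trace stored (MPLE fit); nothing to plot")
    return(invisible(x))
  }
  p <- ncol(x$sim_stats)
  op <- graphics::par(mfrow = c(p, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (t in seq_len(p)) {
    graphics::plot(x$sim_stats[, t], type = "l", ylab = colnames(x$sim_stats)[t],
                   xlab = "")
    graphics::abline(h = x$observed_stats[t], col = "red", lwd = 2)
  }
  invisible(x)
}

#' Export a fitted model
#'
#' Writes the coefficient table as CSV (estimate, standard error,
#' Wald z, p, significance stars) and the full fit (coefficients,
#' standard errors, method, convergence diagnostics) as JSON.
#'
#' @param fit a `packergm`
#' @param path output CSV path (JSON written alongside with `.json`)
#' @export
write_fit <- function(fit, path) {
  s <- summary(fit)
  write.csv(s$table, path, row.names = FALSE)
  jsonlite::write_json(
    list(method = fit$method, response = fit$model$response,
         behaviour = fit$model$net$behaviour,
         terms = fit$model$term_names,
         theta = unname(fit$coefficients), se = unname(fit$se),
         converged = fit$converged, iterations = fit$iterations,
         observed_stats = unname(fit$observed_stats),
         diagnostics = fit$diagnostics),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
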