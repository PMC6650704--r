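#' Default pipeline configuration
#'
#' Returns the default configuration list for [run_pipeline()]. A
#' configuration needs either an `input` block (paths to the
#' interaction-log and attribute CSVs) or a `generator` block (synthetic
#' pack), and a master `seed` - there is no default seed: runs must be
#' explicitly reproducible.
#'
#' @param seed master seed (mandatory)
#' @param outdir output directory
#' @param input list with `log` and `attrs` paths, or `NULL`
#' @param generator list with optional `composition` and `params`
#'   overrides, or `NULL`; used when `input` is `NULL`
#' @param mixing `"nodemix"` (directed class-mixing terms, the default
#'   reading of "interactions: X versus Y") or `"sender"` (sender-
#'   covariate alternative)
#' @param control,sim,gof stage-control overrides (see [ergm_control()],
#'   [sim_control()], [gof_surface()])
#' @param figures write heat-map / forest-plot PNGs
#' @param log_level `"info"` or `"quiet"`
#' @export
pipeline_config <- function(seed, outdir = "packdom-out", input = NULL,
                            generator = list(), mixing = c("nodemix", "sender"),
                            control = list(), sim = list(), gof = list(),
                            figures = TRUE, log_level = "info") {
  cfg <- list(seed = if (missing(seed)) NULL else seed, outdir = outdir,
              input = input, generator = generator,
              mixing = match.arg(mixing), control = control, sim = sim,
              gof = gof, figures = figures, log_level = log_level)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.finite(as.numeric(cfg$seed)))
    stop("pipeline config must set an integer master seed")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$input) && is.null(cfg$generator))
    stop("config needs an 'input' or a 'generator' block")
  if (!is.null(cfg$input) && (is.null(cfg$input$log) || is.null(cfg$input$attrs)))
    stop("input block must give 'log' and 'attrs' paths")
  if (!is.null(cfg$rank_behaviours)) {
    if ("submissive" %in% cfg$rank_behaviours)
      stop("rank-based models cannot be requested for the submissive ",
           "network: ranks are derived from it")
  } else cfg$rank_behaviours <- c("dominance", "aggressive")
  bad <- setdiff(cfg$rank_behaviours, BEHAVIOURS)
  if (length(bad)) stop("unknown behaviour in rank_behaviours: ", bad[1])
  cfg$mixing <- if (is.null(cfg$mixing)) "nodemix" else
    match.arg(cfg$mixing, c("nodemix", "sender"))
  cfg$control <- do.call(ergm_control, c(cfg$control[setdiff(names(cfg$control), "seed")],
                                         list(seed = cfg$seed)))
  cfg$sim <- do.call(sim_control, c(cfg$sim[setdiff(names(cfg$sim), "seed")],
                                    list(seed = cfg$seed + 1L)))
  if (is.null(cfg$gof$central_frac)) cfg$gof$central_frac <- 1 / 3
  if (is.null(cfg$gof$k_max)) cfg$gof$k_max <- 4L
  if (is.null(cfg$gof$position)) cfg$gof$position <- "mean"
  if (is.null(cfg$figures)) cfg$figures <- TRUE
  if (is.null(cfg$log_level)) cfg$log_level <- "info"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

attr_model_rhs <- function(binary, mixing) {
  structural <- if (binary) "edges + mutual + transitive + cyclical"
                else "sum + transitive + cyclical"
  matches <- paste(
    "nodematch(\"age_class\", \"adult\") + nodematch(\"age_class\", \"juvenile\") +",
    "nodematch(\"age_class\", \"subadult\") + nodematch(\"sex\", \"female\") +",
    "nodematch(\"sex\", \"male\")")
  mixing_terms <- if (mixing == "nodemix")
    paste("nodemix(\"sex\", \"male\", \"female\") +",
          "nodemix(\"age_class\", \"juvenile\", \"adult\") +",
          "nodemix(\"age_class\", \"subadult\", \"adult\")")
  else "sender(\"is_male\") + sender(\"is_juvenile\") + sender(\"is_subadult\")"
  stats::formula(paste("~", structural, "+", matches, "+", mixing_terms))
}

plog <- function(cfg, stage, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message(sprintf("[packdom %s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes, from one configuration: data loading or generation;
#' construction of the directed binary, directed weighted and
#' undirected weighted networks for each behaviour; I&SI ranking from
#' submissive interactions; the binary and count attribute ERGMs for
#' all behaviours (models of interaction probability and frequency);
#' the directed and undirected rank models for the non-submissive
#' behaviours; a simulated ensemble from each directed rank model; the
#' goodness-of-fit surfaces and instability contrasts; and all exports,
#' with a run manifest (config hash, seed, versions). Identical config
#' and seed reproduce identical outputs. A stage failure is logged
#' with its stage name and re-thrown; outputs of completed stages are
#' preserved.
#'
#' @param config a [pipeline_config()], or a path readable by
#'   [read_config()]
#' @param dry_run validate the config and print the execution plan
#'   without computing
#' @return (invisibly) a list of the principal result objects and
#'   output paths
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  plan <- c("load_or_generate", "networks", "ranking",
            "attribute_models", "rank_models", "gof", "export")
  if (dry_run) {
    cat("packdom pipeline plan (dry run):\n")
    cat(paste0("  ", seq_along(plan), ". ", plan, collapse = "\n"), "\n")
    cat(sprintf("  seed %d, outdir '%s', ensemble %d networks\n",
                cfg$seed, cfg$outdir, cfg$sim$n_networks))
    return(invisible(plan))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = cfg)
  stage <- function(name, expr) {
    plog(cfg, name, "starting")
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  out$data <- stage("load_or_generate", {
    if (!is.null(cfg$input)) {
      read_interactions(cfg$input$log, cfg$input$attrs)
    } else {
      comp <- do.call(pack_composition, as.list(cfg$generator$composition %||% list()))
      prm <- do.call(pack_params, c(as.list(cfg$generator$params %||% list()),
                                    list(seed = cfg$seed)))
      pack <- make_pack(comp, seed = cfg$seed)
      log <- simulate_interactions(pack, prm)
      write_pack(pack, log, file.path(cfg$outdir, "synthetic"))
      list(log = log, attrs = pack$attrs, truth = pack$truth)
    }
  })

  out$networks <- stage("networks", {
    nets <- list()
    for (beh in BEHAVIOURS) {
      nets[[beh]] <- list(
        binary = build_network(out$data$log, beh, weighted = FALSE,
                               attrs = out$data$attrs),
        directed = build_network(out$data$log, beh, attrs = out$data$attrs),
        undirected = build_network(out$data$log, beh, directed = FALSE,
                                   attrs = out$data$attrs))
      for (form in names(nets[[beh]]))
        write_network(nets[[beh]][[form]],
                      file.path(cfg$outdir, sprintf("net_%s_%s.graphml", beh, form)))
    }
    nets
  })

  out$ranking <- stage("ranking", {
    rk <- isi_rank(wins_matrix(out$data$log, out$data$attrs),
                   seed = cfg$seed + 2L)
    write_ranks(rk, file.path(cfg$outdir, "ranks.csv"), out$data$attrs)
    rk
  })

  out$attribute_models <- stage("attribute_models", {
    fits <- list()
    for (beh in BEHAVIOURS) {
      for (binary in c(TRUE, FALSE)) {
        key <- sprintf("%s_%s", beh, if (binary) "probability" else "frequency")
        net <- if (binary) out$networks[[beh]]$binary else out$networks[[beh]]$directed
        if (cfg$mixing == "sender") {
          a <- net$attrs
          a$is_male <- as.numeric(a$sex == "male")
          a$is_juvenile <- as.numeric(a$age_class == "juvenile")
          a$is_subadult <- as.numeric(a$age_class == "subadult")
          net <- agonet(net$adj, net$directed, net$weighted, net$behaviour, a)
        }
        ctl <- cfg$control; ctl$seed <- cfg$seed + 100L + length(fits)
        f <- stats::formula(paste("net ~",
          deparse1(attr_model_rhs(binary, cfg$mixing)[[2]])))
        environment(f) <- environment()
        fits[[key]] <- packergm(f, response = if (binary) "binary" else "count",
                                control = ctl)
        write_fit(fits[[key]], file.path(cfg$outdir, sprintf("fit_%s.csv", key)))
        plog(cfg, "attribute_models", key, " done")
      }
    }
    fits
  })

  out$rank_models <- stage("rank_models", {
    fits <- list()
    for (beh in cfg$rank_behaviours) {
      ctl <- cfg$control; ctl$seed <- cfg$seed + 200L + length(fits)
      fits[[paste0(beh, "_directed")]] <-
        fit_directed_rank_model(out$networks[[beh]]$directed, out$ranking,
                                control = ctl)
      ctl$seed <- ctl$seed + 1L
      fits[[paste0(beh, "_undirected")]] <-
        fit_undirected_rank_model(out$networks[[beh]]$undirected, out$ranking,
                                  control = ctl)
      for (key in grep(beh, names(fits), value = TRUE))
        write_fit(fits[[key]], file.path(cfg$outdir, sprintf("fit_rank_%s.csv", key)))
      tab <- rank_effects_table(fits[[paste0(beh, "_undirected")]])
      write.csv(tab, file.path(cfg$outdir, sprintf("rank_effects_%s.csv", beh)),
                row.names = FALSE)
      if (isTRUE(cfg$figures)) {
        grDevices::png(file.path(cfg$outdir, sprintf("rank_effects_%s.png", beh)),
                       width = 700, height = 400)
        plot_rank_effects(fits[[paste0(beh, "_undirected")]])
        grDevices::dev.off()
      }
    }
    fits
  })

  out$gof <- stage("gof", {
    surfaces <- list()
    for (beh in cfg$rank_behaviours) {
      fit <- out$rank_models[[paste0(beh, "_directed")]]
      ctl <- cfg$sim; ctl$seed <- cfg$seed + 300L + length(surfaces)
      sims <- simulate_networks(fit$model, coef(fit), control = ctl)
      surf <- gof_surface(out$networks[[beh]]$directed, sims, out$ranking,
                          position = cfg$gof$position)
      n <- length(out$ranking$order)
      band <- central_band(n, cfg$gof$central_frac)
      inst <- instability_summary(surf, band, c(2, cfg$gof$k_max),
                                  seed = cfg$seed + 400L)
      write_surface(surf, file.path(cfg$outdir, sprintf("gof_%s.csv", beh)))
      jsonlite::write_json(inst, file.path(cfg$outdir,
                                           sprintf("instability_%s.json", beh)),
                           auto_unbox = TRUE, digits = NA)
      if (isTRUE(cfg$figures)) {
        grDevices::png(file.path(cfg$outdir, sprintf("gof_%s.png", beh)),
                       width = 600, height = 500)
        plot(surf)
        grDevices::dev.off()
      }
      surfaces[[beh]] <- list(surface = surf, instability = inst)
    }
    surfaces
  })

  stage("export", {
    cfg_json <- jsonlite::toJSON(cfg[c("seed", "mixing", "gof", "outdir")],
                                 auto_unbox = TRUE)
    tf <- tempfile(); writeLines(cfg_json, tf)
    manifest <- list(
      package = "packdom",
      version = as.character(utils::packageVersion("packdom")),
      r_version = R.version.string,
      seed = cfg$seed,
      config_hash = unname(tools::md5sum(tf)),
      timestamp = format(Sys.time(), tz = "UTC"),
      stages = plan)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE)
  })
  plog(cfg, "done", "outputs in ", cfg$outdir)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
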