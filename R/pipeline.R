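# End-to-end pipeline: read or simulate microdata, validate, compute
# indicators and the index, then the optional evaluation stages
# (reliability, spatial autocorrelation, Theil decomposition, outcome
# regressions), writing CSV/JSON artifacts and a run manifest.

#' Run the full analysis pipeline
#'
#' Stages, in order: load (CSV via `input`/`varmap`, or simulate via
#' `scenario`), household validation, indicator matrix, scaling and
#' aggregation, outcomes; then optionally reliability (lambda-6 over the
#' eleven scores), spatial statistics (needs `centroids`), the Theil
#' decomposition of the index over countries, and stepwise outcome
#' regressions (needs `covariates`). Outputs are deterministic given the
#' configuration and seed.
#'
#' @param config Named list (or path to a YAML/JSON file) with any of:
#'   `input` (persons CSV), `varmap`, `code_maps`, `scenario` (list of
#'   [scenario_config()] argument lists), `centroids` (CSV path),
#'   `covariates` (CSV path), `standardize` (default TRUE), `level`
#'   (`"region"`/`"country"`), `k` (neighbours, default 7), `nperm`
#'   (default 999), `alpha` (default 0.05), `seed` (default 1),
#'   `outcomes` (character vector of covariate columns to regress),
#'   `out_dir` (default `"results"`).
#' @return Invisibly, a list with every stage's objects; artifacts are
#'   written under `out_dir` (`indicators.csv`, `pi.csv`, `outcomes.csv`,
#'   `benchmarks.json`, `manifest.json`, and per-stage files when run).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  cfg <- config
  out_dir <- if (is.null(cfg$out_dir)) "results" else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  centroids <- NULL
  res <- list()

  table <- stage("load", {
    if (!is.null(cfg$scenario)) {
      configs <- lapply(cfg$scenario, function(a) {
        a$seed <- if (is.null(a$seed)) seed else a$seed
        if (!is.null(a$archetype_mix)) {
          a$archetype_mix <- unlist(a$archetype_mix)
        }
        do.call(scenario_config, a)
      })
      gen <- generate_dataset(configs)
      centroids <- gen$centroids
      gen$table
    } else if (!is.null(cfg$input)) {
      read_microdata(cfg$input, cfg$varmap,
                     code_maps = if (is.null(cfg$code_maps))
                       default_code_maps() else
                         merge_code_maps(cfg$code_maps))$table
    } else {
      stop("config must give either 'input' or 'scenario'")
    }
  })
  if (!is.null(cfg$centroids)) {
    centroids <- stage("load", read_centroids(cfg$centroids))
  }

  val <- stage("validate", validate_households(table))
  table <- val$table
  res$validation <- val$report

  standardize <- if (is.null(cfg$standardize)) TRUE else
    isTRUE(cfg$standardize)
  level <- if (is.null(cfg$level)) "region" else cfg$level
  pi_res <- stage("index", compute_pi(table, standardize = standardize,
                                      level = level))
  res$pi <- pi_res
  readr::write_csv(pi_res$scores, file.path(out_dir, "indicators.csv"),
                   progress = FALSE)
  readr::write_csv(pi_res$pi, file.path(out_dir, "pi.csv"),
                   progress = FALSE)
  jsonlite::write_json(pi_res$benchmarks,
                       file.path(out_dir, "benchmarks.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  outcomes <- stage("outcomes", compute_outcomes(table))
  res$outcomes <- outcomes
  readr::write_csv(outcomes, file.path(out_dir, "outcomes.csv"),
                   progress = FALSE)

  # reliability over the eleven scaled scores
  res$reliability <- stage("reliability", {
    items <- tidyr::pivot_wider(
      pi_res$scores[, c("region", "id", "score")],
      names_from = "id", values_from = "score", names_prefix = "ind")
    it <- as.matrix(items[, -1])
    if (sum(stats::complete.cases(it)) >= ncol(it) + 1 &&
        !any(apply(it[stats::complete.cases(it), , drop = FALSE], 2,
                   stats::sd) == 0)) {
      l6 <- guttman_lambda6(it)
      jsonlite::write_json(list(lambda6 = l6$lambda6, n = l6$n),
                           file.path(out_dir, "reliability.json"),
                           auto_unbox = TRUE, digits = NA)
      l6
    } else NULL
  })

  if (!is.null(centroids)) {
    res$spatial <- stage("spatial", {
      k <- if (is.null(cfg$k)) min(7, nrow(pi_res$pi) - 1) else cfg$k
      nperm <- if (is.null(cfg$nperm)) 999 else cfg$nperm
      alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
      w <- knn_weights(centroids[centroids$region %in% pi_res$pi$region, ],
                       k = k)
      v <- pi_res$pi$pi[match(w$region, pi_res$pi$region)]
      gl <- morans_i(v, w, nperm = nperm, seed = seed)
      li <- local_moran(v, w, nperm = nperm, alpha = alpha, seed = seed)
      jsonlite::write_json(gl, file.path(out_dir, "moran_global.json"),
                           auto_unbox = TRUE, digits = NA)
      readr::write_csv(li, file.path(out_dir, "lisa.csv"), progress = FALSE)
      list(global = gl, lisa = li)
    })
  } else if (isTRUE(cfg$require_spatial)) {
    stop("[stage: spatial] no centroids available", call. = FALSE)
  }

  res$theil <- stage("theil", {
    ok <- !is.na(pi_res$pi$pi) & pi_res$pi$pi > 0
    groups <- tibble::as_tibble(table) |>
      dplyr::distinct(.data$region, .data$country)
    g <- groups$country[match(pi_res$pi$region[ok], groups$region)]
    if (sum(ok) >= 2 && dplyr::n_distinct(g) >= 2) {
      th <- theil_decomposition(pi_res$pi$pi[ok], g)
      jsonlite::write_json(th[c("T_total", "T_between", "T_within",
                                "polarization", "pct_between")],
                           file.path(out_dir, "theil.json"),
                           auto_unbox = TRUE, digits = NA)
      th
    } else NULL
  })

  if (!is.null(cfg$covariates)) {
    res$regressions <- stage("regress", {
      cov <- read_covariates(cfg$covariates)
      outs <- if (is.null(cfg$outcomes)) {
        intersect(c("flfp_rel", "eys_ratio", "wtot_ratio", "cgfr", "e0_gap"),
                  names(cov))
      } else cfg$outcomes
      tabs <- lapply(outs, function(o)
        stepwise_decomposition(o, pi_res$pi, cov))
      reg <- dplyr::bind_rows(tabs)
      readr::write_csv(reg, file.path(out_dir, "regressions.csv"),
                       progress = FALSE)
      reg
    })
  }

  manifest <- list(seed = seed, standardize = standardize, level = level,
                   n_persons = nrow(table),
                   n_regions = dplyr::n_distinct(table$region),
                   validation = res$validation,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
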