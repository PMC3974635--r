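#' Configuration of a full surrogate analysis
#'
#' @param n_surrogates Ensemble size per surrogate type (>= 2 so dispersion
#'   and tests are defined).
#' @param surrogate_types Which of `"random"`, `"spatial"`, `"reduced"` to
#'   generate.
#' @param swaps_per_edge Named list overriding the per-type defaults (20
#'   for random/spatial, 1 for reduced).
#' @param max_attempts_factor,reduced_mode Passed to [rewiring_config()].
#' @param metrics Character vector of metric names to evaluate; any of
#'   `"qs_binary"`, `"qs_weighted"`, `"mean_edge_length"`, `"clustering"`,
#'   `"efficiency"`, `"small_world"`, `"modularity"`, `"assortativity"`,
#'   `"s_core"`, `"rich_club"`.
#' @param test `"one_sample_t"` or `"wilcoxon"` (signed-rank against the
#'   source value).
#' @param alternative Test sidedness, default two-sided.
#' @param rich_club_size Club size at which the weighted rich-club density
#'   is reported; defaults to `min(100, max_assessable_club(E))`.
#' @param star_thresholds Decreasing p-value cut-offs for the star
#'   annotation.
#' @param seed Integer base seed; ensemble members derive their own seeds
#'   from it, so the whole analysis is reproducible.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_surrogates = 20,
                            surrogate_types = c("random", "spatial", "reduced"),
                            swaps_per_edge = list(),
                            max_attempts_factor = 1000,
                            reduced_mode = "per_region_strict",
                            metrics = c("qs_binary", "mean_edge_length",
                                        "clustering", "efficiency",
                                        "small_world", "modularity",
                                        "assortativity", "s_core",
                                        "rich_club"),
                            test = c("one_sample_t", "wilcoxon"),
                            alternative = "two.sided",
                            rich_club_size = NULL,
                            star_thresholds = c(0.05, 0.01, 0.001, 0.0001),
                            seed = 1) {
  if (n_surrogates < 2) {
    stop("n_surrogates must be >= 2 for dispersion estimates", call. = FALSE)
  }
  surrogate_types <- match.arg(surrogate_types, several.ok = TRUE)
  test <- match.arg(test)
  structure(list(n_surrogates = n_surrogates,
                 surrogate_types = surrogate_types,
                 swaps_per_edge = swaps_per_edge,
                 max_attempts_factor = max_attempts_factor,
                 reduced_mode = reduced_mode, metrics = metrics, test = test,
                 alternative = alternative, rich_club_size = rich_club_size,
                 star_thresholds = sort(star_thresholds, decreasing = TRUE),
                 seed = seed),
            class = "analysis_config")
}

#' Test a source metric value against its surrogate ensemble
#'
#' One-sample test of the ensemble values against the source value, with a
#' star annotation at the configured thresholds. An ensemble with zero
#' variance cannot be tested and is flagged degenerate instead of erroring.
#'
#' @param source_value Metric value of the source network.
#' @param ensemble_values Metric values of the surrogate ensemble (>= 2).
#' @param test `"one_sample_t"` or `"wilcoxon"` (signed-rank).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param star_thresholds Decreasing p-value cut-offs; the default gives
#'   `*` below 0.05 up to `****` below 0.0001.
#' @return A one-row tibble: statistic, p_value, stars, degenerate flag.
#' @export
significance_annotation <- function(source_value, ensemble_values,
                                    test = c("one_sample_t", "wilcoxon"),
                                    alternative = "two.sided",
                                    star_thresholds = c(0.05, 0.01, 0.001,
                                                        0.0001)) {
  test <- match.arg(test)
  if (length(ensemble_values) < 2) {
    stop("need at least two ensemble values", call. = FALSE)
  }
  if (is.na(source_value) || anyNA(ensemble_values) ||
      stats::sd(ensemble_values) == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          stars = "", degenerate = TRUE))
  }
  ht <- if (test == "one_sample_t") {
    stats::t.test(ensemble_values, mu = source_value,
                  alternative = alternative)
  } else {
    stats::wilcox.test(ensemble_values, mu = source_value,
                       alternative = alternative, exact = FALSE)
  }
  thr <- sort(star_thresholds, decreasing = TRUE)
  stars <- strrep("*", sum(ht$p.value < thr))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 stars = stars, degenerate = FALSE)
}

evaluate_metrics <- function(net, metrics, source = NULL, rc_size = NULL) {
  out <- list()
  need_ce <- any(c("clustering", "efficiency", "small_world") %in% metrics)
  if (need_ce) {
    out$clustering <- weighted_clustering(net)$global
    out$efficiency <- global_efficiency(net)$global
  }
  if ("qs_binary" %in% metrics) {
    out$qs_binary <- if (is.null(source)) 1 else similarity_binary(source, net)
  }
  if ("qs_weighted" %in% metrics) {
    out$qs_weighted <- if (is.null(source)) 1 else similarity_weighted(source, net)
  }
  if ("mean_edge_length" %in% metrics) {
    out$mean_edge_length <- mean(edge_lengths(net))
  }
  if ("modularity" %in% metrics) {
    out$modularity <- spectral_partition(net)$q
  }
  if ("assortativity" %in% metrics) {
    out$assortativity <- degree_assortativity(net)
  }
  if ("s_core" %in% metrics) {
    out$s_core <- core_decomposition(net, "s_core")$core$threshold
  }
  if ("rich_club" %in% metrics) {
    out$rich_club <- rich_club_core(net, rc_size)$phi_w
  }
  out[intersect(c(metrics, "clustering", "efficiency"), names(out))]
}

#' Run the full surrogate analysis of a network
#'
#' Generates the configured surrogate ensembles, evaluates the metric
#' battery on the source network and every member, derives the small-world
#' index of all networks against the random-ensemble means, tests each
#' source value against each ensemble, and assembles a summary table
#' (source value, ensemble mean and standard deviation, test statistic,
#' p-value and star annotation per metric and surrogate type). The whole
#' run is deterministic given `config$seed`.
#'
#' @param net The source [spatial_network()].
#' @param config An [analysis_config()].
#' @param out_dir Optional directory: writes `report.json`, `report.tsv`,
#'   per-member surrogate edge tables with a JSON provenance sidecar under
#'   `ensembles/<type>/`, and `log.txt` with per-stage timings.
#' @return A `wirecost_report`: list with `table` (the summary tibble),
#'   `member_values` (per-member metric values), `ensembles` (per-ensemble
#'   provenance summaries) and `config`.
#' @export
run_analysis <- function(net, config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(net, "spatial_network"), inherits(config, "analysis_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  rc_size <- config$rich_club_size
  if (is.null(rc_size)) {
    rc_size <- min(100, max_assessable_club(nrow(net$edges)))
  }
  metrics <- config$metrics

  say("evaluating source network metrics")
  t0 <- Sys.time()
  src_vals <- evaluate_metrics(net, metrics, source = NULL, rc_size = rc_size)
  say("source metrics done in %.1f s", as.numeric(Sys.time() - t0, "secs"))

  ensembles <- list()
  member_rows <- list()
  for (ty in config$surrogate_types) {
    spe <- config$swaps_per_edge[[ty]]
    cfg <- rewiring_config(ty, swaps_per_edge = spe,
                           max_attempts_factor = config$max_attempts_factor,
                           reduced_mode = config$reduced_mode,
                           seed = config$seed + 1000 *
                             match(ty, c("random", "spatial", "reduced")))
    t0 <- Sys.time()
    ens <- generate_ensemble(net, cfg, config$n_surrogates)
    say("%s ensemble generated in %.1f s (%d saturated members)", ty,
        as.numeric(Sys.time() - t0, "secs"), sum(ens$provenance$saturated))
    ensembles[[ty]] <- ens
    t0 <- Sys.time()
    for (m in seq_along(ens$members)) {
      vals <- evaluate_metrics(ens$members[[m]], metrics, source = net,
                               rc_size = rc_size)
      member_rows[[length(member_rows) + 1]] <-
        tibble::tibble(surrogate_type = ty, member = m,
                       metric = names(vals),
                       value = unlist(vals, use.names = FALSE))
    }
    say("%s member metrics done in %.1f s", ty,
        as.numeric(Sys.time() - t0, "secs"))
  }
  member_values <- dplyr::bind_rows(member_rows)

  # small-world index relative to the random-ensemble means
  if ("small_world" %in% metrics && "random" %in% names(ensembles)) {
    rnd <- member_values[member_values$surrogate_type == "random", ]
    c_rnd <- mean(rnd$value[rnd$metric == "clustering"])
    e_rnd <- mean(rnd$value[rnd$metric == "efficiency"])
    sw_of <- function(cv, ev) small_world_index(cv, ev, c_rnd, e_rnd)
    src_vals$small_world <- sw_of(src_vals$clustering, src_vals$efficiency)
    sw_rows <- member_values |>
      dplyr::filter(.data$metric %in% c("clustering", "efficiency")) |>
      tidyr::pivot_wider(names_from = "metric", values_from = "value") |>
      dplyr::mutate(metric = "small_world",
                    value = sw_of(.data$clustering, .data$efficiency)) |>
      dplyr::select("surrogate_type", "member", "metric", "value")
    member_values <- dplyr::bind_rows(member_values, sw_rows)
  }

  keep <- intersect(metrics, unique(member_values$metric))
  table <- purrr::map_dfr(keep, function(mt) {
    purrr::map_dfr(names(ensembles), function(ty) {
      v <- member_values$value[member_values$metric == mt &
                                 member_values$surrogate_type == ty]
      src <- src_vals[[mt]] %||% NA_real_
      ann <- significance_annotation(src, v, test = config$test,
                                     alternative = config$alternative,
                                     star_thresholds = config$star_thresholds)
      dplyr::bind_cols(
        tibble::tibble(metric = mt, surrogate_type = ty, source_value = src,
                       ensemble_mean = mean(v), ensemble_sd = stats::sd(v),
                       n_members = length(v)),
        ann)
    })
  })

  report <- structure(list(table = table, member_values = member_values,
                           ensembles = purrr::map(ensembles, glance),
                           config = config, log = log_lines),
                      class = "wirecost_report")
  if (!is.null(out_dir)) write_report(report, ensembles, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, ensembles, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(table = report$table,
         ensembles = dplyr::bind_rows(report$ensembles)),
    file.path(out_dir, "report.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA, na = "null")
  readr::write_tsv(report$table, file.path(out_dir, "report.tsv"),
                   progress = FALSE)
  for (ty in names(ensembles)) {
    ens <- ensembles[[ty]]
    dir <- file.path(out_dir, "ensembles", ty)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (m in seq_along(ens$members)) {
      edges <- ens$members[[m]]$edges
      names(edges) <- c("source", "target", "weight")
      readr::write_tsv(edges, file.path(dir, sprintf("member_%02d.tsv", m)),
                       progress = FALSE)
    }
    jsonlite::write_json(ens$provenance, file.path(dir, "provenance.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(report)
}

#' @export
print.wirecost_report <- function(x, ...) {
  cat(sprintf("<wirecost_report: %d metrics x %d surrogate types>\n",
              dplyr::n_distinct(x$table$metric),
              dplyr::n_distinct(x$table$surrogate_type)))
  print(x$table, n = Inf)
  invisible(x)
}

#' Tidy an analysis report
#'
#' @param x A `wirecost_report`.
#' @param ... Unused.
#' @return The summary table tibble (metric, surrogate type, source value,
#'   ensemble mean and sd, test results, stars).
#' @method tidy wirecost_report
#' @export
tidy.wirecost_report <- function(x, ...) x$table

#' One-row-per-ensemble summary of an analysis report
#'
#' @param x A `wirecost_report`.
#' @param ... Unused.
#' @return Tibble of per-ensemble generation summaries.
#' @method glance wirecost_report
#' @export
glance.wirecost_report <- function(x, ...) dplyr::bind_rows(x$ensembles)
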