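# End-to-end orchestration: generate or ingest a cohort, detect peaks,
# summarize animals, run group tests and the GLS contrast, and write
# delimited artifacts plus a run log with the config hash.

#' Assemble a pipeline run configuration
#'
#' Defaults reproduce the study's stated analysis settings: 40 mmHg minimum
#' peak height, 20 mmHg minimum prominence, the 2-hour post-onset analysis
#' window, the ZT3 onset boundary, and the one-sided GLS contrast.
#'
#' @param cohort a [cohort_config()] for synthetic input, or `NULL` when
#'   reading from `manifest`.
#' @param manifest path to a cohort `manifest.csv` (as written by
#'   [generate_cohort()]); ignored when `cohort` is given.
#' @param min_height,min_prominence peak-detection thresholds, mmHg.
#' @param zt_boundary onset-classification boundary, hours ZT.
#' @param gls_tol,gls_max_iter,gls_one_step,gls_two_sided GLS options (see
#'   [fit_gls()] and [one_sided_test()]).
#' @param outdir output directory for run artifacts.
#' @param seed integer; overrides the cohort config's seed when synthetic.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, manifest = NULL,
                       min_height = 40, min_prominence = 20,
                       zt_boundary = 3,
                       gls_tol = 1e-8, gls_max_iter = 100L,
                       gls_one_step = FALSE, gls_two_sided = FALSE,
                       outdir = tempfile("partolab_run_"), seed = NULL) {
  if (is.null(cohort) && is.null(manifest))
    stop("provide either a cohort config or a manifest path")
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_config"))
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
  }
  structure(list(cohort = cohort, manifest = manifest,
                 min_height = min_height, min_prominence = min_prominence,
                 zt_boundary = zt_boundary, gls_tol = gls_tol,
                 gls_max_iter = as.integer(gls_max_iter),
                 gls_one_step = isTRUE(gls_one_step),
                 gls_two_sided = isTRUE(gls_two_sided),
                 outdir = outdir,
                 seed = if (!is.null(seed)) as.integer(seed)
                        else if (!is.null(cohort)) cohort$seed
                        else NA_integer_),
            class = "run_config")
}

# load traces + delivery records either synthetically or from a manifest dir
load_cohort <- function(config) {
  if (!is.null(config$cohort)) {
    roster <- cohort_roster(config$cohort)
    traces <- lapply(roster$animal_index, function(i)
      generate_pressure_trace(config$cohort, i))
    records <- lapply(roster$animal_index, function(i)
      generate_delivery_events(config$cohort, i))
    names(traces) <- names(records) <- roster$animal_id
    list(roster = roster, traces = traces, records = records)
  } else {
    if (!file.exists(config$manifest))
      stop(sprintf("no such manifest: %s", config$manifest))
    mdir <- dirname(config$manifest)
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    need <- c("animal_id", "group", "d_drg", "d_uterus", "trace_file",
              "events_file")
    if (!all(need %in% names(man)))
      stop(sprintf("manifest must have columns %s",
                   paste(need, collapse = ", ")))
    recs <- read_events(file.path(mdir, man$events_file[1]))
    traces <- Map(function(f, id, grp)
      read_trace(file.path(mdir, f), id, grp),
      man$trace_file, man$animal_id, man$group)
    names(traces) <- man$animal_id
    roster <- data.frame(animal_index = seq_len(nrow(man)),
                         man[c("animal_id", "group", "d_drg", "d_uterus")],
                         stringsAsFactors = FALSE)
    list(roster = roster, traces = traces, records = recs[man$animal_id])
  }
}

#' Summarize a cohort into the per-animal analysis table
#'
#' Resamples every trace to 1 Hz, detects peaks at the configured thresholds,
#' windows them to the 2-hour post-onset window, and emits one AnimalSummary
#' row per animal.
#'
#' @param config a [run_config()].
#' @return list with `summaries` (data.frame), `peaks` (per-animal peak
#'   tables), `traces_1hz` (resampled traces), `records`.
#' @export
summarize_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ch <- load_cohort(config)
  if (!nrow(ch$roster)) stop("empty cohort")
  rows <- vector("list", nrow(ch$roster))
  peak_tabs <- vector("list", nrow(ch$roster))
  traces_1hz <- vector("list", nrow(ch$roster))
  for (i in seq_len(nrow(ch$roster))) {
    id <- ch$roster$animal_id[i]
    tr <- resample_1hz(ch$traces[[id]])
    traces_1hz[[i]] <- tr
    pk <- find_peaks(tr, config$min_height, config$min_prominence)
    peak_tabs[[i]] <- pk
    ps <- window_peaks(pk, ch$records[[id]], "post_onset_2h",
                       recording_start = tr$timestamps[1],
                       recording_end = tr$timestamps[length(tr$timestamps)])
    rows[[i]] <- summarize_animal(ps, ch$records[[id]],
                                  d_drg = ch$roster$d_drg[i],
                                  d_uterus = ch$roster$d_uterus[i],
                                  zt_boundary = config$zt_boundary)
  }
  names(peak_tabs) <- names(traces_1hz) <- ch$roster$animal_id
  list(summaries = do.call(rbind, rows), peaks = peak_tabs,
       traces_1hz = traces_1hz, records = ch$records)
}

# group-level test battery on the summary table; control = first group level
cohort_stats <- function(summaries) {
  grp <- factor(summaries$group, levels = unique(summaries$group))
  out <- list()
  add <- function(test, variable, statistic, p, n) {
    out[[length(out) + 1L]] <<- data.frame(
      test = test, variable = variable, statistic = statistic, p_value = p,
      n = n, stringsAsFactors = FALSE)
  }
  by_grp <- function(v) split(summaries[[v]][!is.na(summaries[[v]])],
                              grp[!is.na(summaries[[v]])])
  for (v in c("mean_peak_pressure", "mean_interpup_interval")) {
    gs <- by_grp(v)
    gs <- gs[lengths(gs) > 0]
    if (length(gs) >= 2) {
      kw <- kruskal_wallis(gs)
      add("kruskal_wallis", v, kw$H, kw$p_value, sum(lengths(gs)))
      if (length(gs) >= 2) {
        mw <- mann_whitney(gs[[1]], gs[[length(gs)]])
        add(paste0("mann_whitney_", names(gs)[1], "_vs_",
                   names(gs)[length(gs)]), v, mw$U, mw$p_value,
            length(gs[[1]]) + length(gs[[length(gs)]]))
      }
    }
  }
  ctrl <- grp == levels(grp)[1]
  late <- summaries$onset_after_zt3
  if (!any(is.na(late))) {
    tab <- matrix(c(sum(ctrl & !late), sum(ctrl & late),
                    sum(!ctrl & !late), sum(!ctrl & late)), 2, byrow = TRUE)
    fe <- fisher_exact_2x2(tab)
    add("fisher_exact_onset_after_zt3", "control_vs_knockout",
        fe$odds_ratio, fe$p_value, nrow(summaries))
  }
  do.call(rbind, out)
}

#' Run the full telemetry analysis pipeline
#'
#' Generates or ingests a cohort, detects and windows contraction peaks,
#' summarizes every animal, runs the group-level test battery and the
#' heteroscedastic GLS contrast, and writes all artifacts (per-animal peak
#' tables, the AnimalSummary table, stats and GLS reports, and a run log
#' with package version and config hash) under `config$outdir`.
#' Deterministic for a given config and seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of artifacts: `summaries`, `stats`, `gls_fit`,
#'   `tests`, `peaks`, `traces_1hz`, `records`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "summarize"
  res <- tryCatch(summarize_cohort(config), error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
  summ <- res$summaries

  stage <- "stats"
  stats_tab <- tryCatch(cohort_stats(summ), error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))

  stage <- "gls"
  usable <- summ[!is.na(summ$mean_peak_pressure), , drop = FALSE]
  fit <- tryCatch({
    f <- fit_gls(build_design(usable), tol = config$gls_tol,
                 max_iter = config$gls_max_iter,
                 one_step = config$gls_one_step)
    f
  }, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
  tests <- lapply(c("d_drg", "d_uterus"), function(cf)
    c(coefficient = cf, one_sided_test(fit, cf,
                                       two_sided = config$gls_two_sided)))

  stage <- "write"
  files <- list(
    summaries = file.path(config$outdir, "animal_summaries.csv"),
    stats = file.path(config$outdir, "stats_report.csv"),
    gls = file.path(config$outdir, "gls_report.csv"),
    log = file.path(config$outdir, "run_log.txt"),
    config = file.path(config$outdir, "run_config.yaml")
  )
  write_summary_csv(summ, files$summaries)
  utils::write.csv(format(stats_tab, digits = 10), files$stats,
                   row.names = FALSE, quote = FALSE)
  gls_tab <- data.frame(coefficient = names(fit$beta),
                        estimate = sprintf("%.6f", fit$beta),
                        se = sprintf("%.6f", fit$se),
                        t = sprintf("%.6f", fit$t_stats),
                        p_one_sided = sprintf("%.6g", fit$p_one_sided),
                        df = fit$df, converged = fit$converged,
                        n_iter = fit$n_iter)
  utils::write.csv(gls_tab, files$gls, row.names = FALSE, quote = FALSE)
  serialize_run_config(config, files$config)
  writeLines(c(
    sprintf("partolab %s",
            as.character(utils::packageVersion("partolab"))),
    sprintf("config_hash: %s", unname(tools::md5sum(files$config))),
    sprintf("seed: %s", config$seed),
    sprintf("animals: %d", nrow(summ)),
    sprintf("stages: summarize, stats, gls, write")
  ), files$log)

  per_animal_dir <- file.path(config$outdir, "peaks")
  dir.create(per_animal_dir, showWarnings = FALSE)
  for (id in names(res$peaks)) {
    pk <- res$peaks[[id]]
    con <- file(file.path(per_animal_dir, paste0(id, "_peaks.csv")), "w")
    writeLines("time_s,height_mmHg,prominence_mmHg", con)
    if (nrow(pk))
      writeLines(sprintf("%.3f,%.6f,%.6f", pk$time_s, pk$height,
                         pk$prominence), con)
    close(con)
  }

  invisible(list(summaries = summ, stats = stats_tab, gls_fit = fit,
                 tests = tests, peaks = res$peaks,
                 traces_1hz = res$traces_1hz, records = res$records,
                 files = files, config = config))
}

# fixed-precision summary serialization so identical runs are byte-identical
write_summary_csv <- function(summ, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(summ), collapse = ","), con)
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.6f", x))
    else as.character(x)
  }
  body <- do.call(paste, c(lapply(summ, fmt), sep = ","))
  writeLines(body, con)
}

serialize_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$cohort)) {
    x$cohort <- unclass(x$cohort)
    x$cohort$group_defs <- as.list(x$cohort$group_defs)
  }
  x$outdir <- NULL                      # location-independent hash
  yaml::write_yaml(x, path)
}

#' Produce a human-readable run report with figures
#'
#' Writes `report.txt` (per-group counts, mean peak pressures, inter-pup
#' intervals, onset classification, test battery, GLS contrast) and a PDF
#' with one representative 1 Hz trace per group overlaid with detected peaks,
#' plus a cohort heatmap of intrauterine pressure over the 2-hour post-onset
#' window (animals as rows). Tests that are not applicable (single animal,
#' missing statistics) are marked as such rather than failing.
#'
#' @param artifacts result of [run_pipeline()].
#' @return invisibly, paths to the written report files.
#' @export
make_report <- function(artifacts) {
  summ <- artifacts$summaries
  if (is.null(summ) || !nrow(summ)) stop("no artifacts to report on")
  outdir <- artifacts$config$outdir
  report <- file.path(outdir, "report.txt")
  grp <- factor(summ$group, levels = unique(summ$group))
  lines <- c("partolab run report", strrep("=", 40))
  for (g in levels(grp)) {
    s <- summ[grp == g, , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s: n=%d | mean peak pressure %.1f mmHg | interpup %.1f min | onset>ZT3 %d/%d",
      g, nrow(s), mean(s$mean_peak_pressure, na.rm = TRUE),
      mean(s$mean_interpup_interval, na.rm = TRUE),
      sum(s$onset_after_zt3, na.rm = TRUE), sum(!is.na(s$onset_after_zt3))))
  }
  lines <- c(lines, "", "tests:")
  if (nrow(summ) < 2) {
    lines <- c(lines, "  not applicable (single animal)")
  } else if (!is.null(artifacts$stats)) {
    lines <- c(lines, sprintf("  %s [%s]: stat=%.4g p=%.4g (n=%d)",
                              artifacts$stats$test, artifacts$stats$variable,
                              artifacts$stats$statistic,
                              artifacts$stats$p_value, artifacts$stats$n))
  }
  fit <- artifacts$gls_fit
  if (!is.null(fit)) {
    lines <- c(lines, "", "GLS contrast (one-sided, H1: beta < 0):",
               sprintf("  %s: estimate %.2f mmHg (se %.2f), t=%.3f, p=%.4g, df=%d",
                       names(fit$beta), fit$beta, fit$se, fit$t_stats,
                       fit$p_one_sided, fit$df))
  }
  writeLines(lines, report)

  figs <- file.path(outdir, "report_figures.pdf")
  grDevices::pdf(figs, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  for (g in levels(grp)) {
    id <- summ$animal_id[grp == g][1]
    tr <- artifacts$traces_1hz[[id]]
    pk <- artifacts$peaks[[id]]
    graphics::plot(tr$timestamps / 3600, tr$pressure, type = "l",
                   xlab = "time (h ZT)", ylab = "pressure (mmHg)",
                   main = sprintf("%s (%s)", id, g))
    if (nrow(pk))
      graphics::points(pk$time_s / 3600, pk$height, col = "red", pch = 20)
  }
  # cohort heatmap: pressure over the 2-h post-onset window, animals as rows
  mat <- t(vapply(summ$animal_id, function(id) {
    tr <- artifacts$traces_1hz[[id]]
    rec <- artifacts$records[[id]]
    if (is.na(rec$first_pup_time)) return(rep(NA_real_, 7200))
    onset_s <- rec$first_pup_time * 60
    idx <- findInterval(onset_s + 0:7199, tr$timestamps)
    out <- rep(NA_real_, 7200)
    ok <- idx >= 1 & idx <= length(tr$pressure)
    out[ok] <- tr$pressure[idx[ok]]
    out
  }, numeric(7200)))
  graphics::image(x = (0:7199) / 60, y = seq_len(nrow(mat)), z = t(mat),
                  xlab = "time after labor onset (min)", ylab = "animal",
                  main = "intrauterine pressure, 2-h post-onset window",
                  col = grDevices::hcl.colors(64, "inferno"))
  invisible(list(report = report, figures = figs))
}
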