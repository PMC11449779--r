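#' Configuration for a full pipeline run
#'
#' Bundles the generator configuration with the analysis switches.  The seed
#' in `generator` propagates to every stochastic stage (stage-specific seeds
#' are derived deterministically from it), so re-running the same config
#' reproduces all outputs bit-for-bit.
#'
#' @param generator a [generator_config()].
#' @param n_factors factors to extract in the measurement stage.
#' @param cutoffs proband threshold table for the extremes stage.
#' @param n_boot bootstrap resamples used by the twin stage.
#' @param outcome `"sum_score"` or `"factor_score"` for the coaggregation
#'   stage.
#' @param exclude_severe_id,age_min,age_max sensitivity filters applied
#'   before analysis (see [apply_filters()]).
#' @param out_dir output directory for the report bundle.
#' @return an object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(), n_factors = 3L,
                       cutoffs = default_cutoffs(), n_boot = 200L,
                       outcome = c("sum_score", "factor_score"),
                       exclude_severe_id = FALSE, age_min = NULL,
                       age_max = NULL, out_dir = "pcontinuum_run") {
  outcome <- match.arg(outcome)
  stopifnot(inherits(generator, "generator_config"), n_factors >= 1)
  structure(list(generator = generator, n_factors = as.integer(n_factors),
                 cutoffs = cutoffs, n_boot = as.integer(n_boot),
                 outcome = outcome, exclude_severe_id = exclude_severe_id,
                 age_min = age_min, age_max = age_max, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> measurement -> reliability -> coaggregation ->
#' twin models -> report.  Each stage writes its CSV/JSON outputs under
#' `config$out_dir`; a consolidated Markdown report collects the loading
#' matrix, the reliability curve summary, the coaggregation gradient and the
#' twin/extremes tables.  Timing and session details go to `run.log` only,
#' so the analysis outputs are byte-identical across reruns of the same
#' config.  A stage failure aborts with the stage name; outputs of completed
#' stages are preserved.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the stage results: `data`, `solution`,
#'   `reliability`, `coaggregation`, `id_control`, `ace`, `extremes`,
#'   `continuity`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  cat("", file = logf)
  log_line("pcontinuum ", as.character(utils::packageVersion("pcontinuum")),
           " | R ", as.character(getRversion()))
  log_line("seed = ", config$generator$seed, ", started ", format(t0))
  notices <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_line("stage ", name, " done")
    res
  }
  gen <- config$generator

  dat <- stage("simulate", {
    d <- simulate_families(gen)
    d <- simulate_id_negative_control(gen, d)
    write_family_csv(d, file.path(config$out_dir, "families.csv"))
    d
  })
  dat <- stage("filters", suppressMessages(apply_filters(
    dat, exclude_severe_id = config$exclude_severe_id,
    age_min = config$age_min, age_max = config$age_max)))

  sol <- stage("measurement", {
    tm <- suppressMessages(tetrachoric_matrix(dat))
    s <- extract_and_rotate(tm, config$n_factors)
    utils::write.csv(
      data.frame(condition = rownames(s$Lambda), round(s$Lambda, 4)),
      file.path(config$out_dir, "loadings.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(component = seq_along(s$eigenvalues),
                 eigenvalue = round(s$eigenvalues, 4)),
      file.path(config$out_dir, "eigenvalues.csv"), row.names = FALSE)
    s
  })

  rel <- stage("reliability", {
    r <- conditional_reliability(sol)
    utils::write.csv(round(as.data.frame(r), 6),
                     file.path(config$out_dir, "reliability_curve.csv"),
                     row.names = FALSE)
    r
  })

  has_sibs <- any(dat$relationship == "full_sibling")
  coagg <- idc <- NULL
  if (has_sibs) {
    coagg <- stage("coaggregation", {
      r <- suppressMessages(dummy_regression(
        dat, outcome = config$outcome,
        sol = if (config$outcome == "factor_score") sol else NULL))
      utils::write.csv(r$table, file.path(config$out_dir, "coaggregation.csv"),
                       row.names = FALSE)
      jsonlite::write_json(r$trend,
                           file.path(config$out_dir, "trend.json"),
                           auto_unbox = TRUE, digits = NA)
      r
    })
    idc <- stage("id_negative_control", {
      r <- id_negative_control(dat)
      utils::write.csv(r$table,
                       file.path(config$out_dir, "id_negative_control.csv"),
                       row.names = FALSE)
      r
    })
  } else {
    notices <- c(notices, "no sibling pairs: coaggregation stage skipped")
    log_line("coaggregation skipped (no sibling pairs)")
  }

  has_twins <- any(dat$relationship %in% c("MZ", "DZ"))
  ace <- ext <- cont <- NULL
  if (has_twins) {
    ace <- stage("twin_ace", intraclass_and_ace(
      dat, n_boot = config$n_boot, seed = derive_seed(gen$seed, 11L)))
    ext <- stage("twin_extremes", suppressWarnings(df_extremes(
      dat, config$cutoffs, n_boot = config$n_boot,
      seed = derive_seed(gen$seed, 12L))))
    utils::write.csv(as.data.frame(ext),
                     file.path(config$out_dir, "extremes.csv"),
                     row.names = FALSE)
    cont <- stage("continuity", continuity_report(
      dat, config$cutoffs, n_boot = config$n_boot,
      seed = derive_seed(gen$seed, 13L), ace = ace, ext = ext))
    utils::write.csv(as.data.frame(cont),
                     file.path(config$out_dir, "continuity.csv"),
                     row.names = FALSE)
  } else {
    notices <- c(notices, "no twin pairs: twin stages skipped")
    log_line("twin stages skipped (no twin pairs)")
  }

  stage("report", write_report(config, dat, sol, rel, coagg, idc, ace, ext,
                               cont, notices))
  log_line("finished ", format(Sys.time()), " (",
           round(difftime(Sys.time(), t0, units = "secs"), 1), " s)")
  invisible(list(data = dat, solution = sol, reliability = rel,
                 coaggregation = coagg, id_control = idc, ace = ace,
                 extremes = ext, continuity = cont))
}

write_report <- function(config, dat, sol, rel, coagg, idc, ace, ext, cont,
                         notices) {
  path <- file.path(config$out_dir, "report.md")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  md_table <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 4) else x)
    w("| ", paste(names(df), collapse = " | "), " |")
    w("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    for (i in seq_len(nrow(df)))
      w("| ", paste(unlist(df[i, ]), collapse = " | "), " |")
    w("")
  }
  w("# General psychopathology factor: genetic-continuity analysis")
  w("")
  w("Seed: ", config$generator$seed, "; mode: ",
    config$generator$extreme_mode, "; persons analysed: ", nrow(dat))
  w("")
  for (n in notices) w("> NOTE: ", n)
  w("")
  w("## Measurement model (general + specific loadings)")
  w("")
  md_table(data.frame(condition = rownames(sol$Lambda),
                      round(sol$Lambda, 3)))
  w("First five eigenvalues: ",
    paste(round(utils::head(sol$eigenvalues, 5), 2), collapse = ", "))
  w("")
  w("## Conditional reliability of the sum score")
  w("")
  iv <- reliability_interval(rel)
  w("Reliability >= 0.70 for latent scores in [",
    iv[1], ", ", iv[2], "]; peak R^2 = ", round(max(rel$r2), 3),
    " at theta = ", rel$theta[which.max(rel$r2)], ".")
  w("")
  if (!is.null(coagg)) {
    w("## Sibling coaggregation of the p sum score")
    w("")
    md_table(coagg$table)
    w("Trend: p_linear = ", signif(coagg$trend$p_linear, 3),
      ", lack-of-fit p = ", signif(coagg$trend$p_lackoffit, 3))
    w("")
    w("## Intellectual-disability negative control")
    w("")
    md_table(idc$table)
  }
  if (!is.null(ace)) {
    w("## Classical twin model (", ace$model, ")")
    w("")
    w("r_MZ = ", round(ace$r_mz, 3), ", r_DZ = ", round(ace$r_dz, 3),
      "; a2 = ", round(ace$a2, 3), ", c2 = ", round(ace$c2, 3),
      ", e2 = ", round(ace$e2, 3))
    w("")
    w("## DeFries-Fulker extremes analysis")
    w("")
    md_table(as.data.frame(ext)[, intersect(
      c("label", "n_probands_mz", "n_probands_dz", "t_mz", "t_dz", "h2g",
        "h2g_lower", "h2g_upper", "e2g"), names(ext))])
    w("## Continuity verdict")
    w("")
    md_table(as.data.frame(cont))
    w("**", attr(cont, "verdict"), "**")
  }
  invisible(path)
}
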