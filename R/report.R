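# Report generation: runs the requested analysis stages and writes plain
# CSV/JSON artifacts mirroring the published tables and figures.

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis and write a report
#'
#' Executes the requested stages — base case, one-way sensitivity analysis
#' over every ranged parameter, the two-way compliance grid, the extended
#' threshold searches (platform overhead up to US$2000, therapist time
#' share up to 50\%) and the probabilistic sensitivity analysis — and
#' writes each result as CSV (tables) or JSON (summaries) into
#' \code{out_dir}.  A provenance block (\code{provenance.json}) records the
#' configuration hash, seed and package version; given the same seed and
#' configuration the outputs are byte-identical across runs.
#'
#' @param out_dir output directory (created if missing).
#' @param config parameter configuration passed to [load_parameters()].
#' @param settings a [cea_settings()] object.
#' @param seed master seed for the PSA stage.
#' @param psa_n number of PSA draws.
#' @param stages subset of \code{c("base", "oneway", "twoway", "threshold",
#'   "psa")}.
#' @return A \code{cea_report}: a list with the per-stage results, any
#'   per-stage errors, and the paths of the written files; invisibly.
#' @export
run_report <- function(out_dir, config = NULL, settings = cea_settings(),
                       seed = 1, psa_n = 10000,
                       stages = c("base", "oneway", "twoway", "threshold", "psa")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(config)
  settings <- as_settings(settings)
  model <- cea_model(params, settings)
  files <- character(0)
  results <- list()
  errors <- list()
  run_stage <- function(name, fn) {
    if (!(name %in% stages)) return(invisible(NULL))
    message("stage '", name, "' ...")
    res <- tryCatch(fn(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[name]] <<- res
    invisible(NULL)
  }

  run_stage("base", function() {
    tab <- base_case_table(model)
    files <<- c(files, write_csv_plain(tab, file.path(out_dir, "base_case.csv")))
    for (s in .strategies) {
      tr <- as.data.frame(model$outcomes[[s]]$trace)
      files <<- c(files, write_csv_plain(tr, file.path(out_dir,
                                                       paste0("trace_", s, ".csv"))))
    }
    init <- do.call(rbind, lapply(.strategies, function(s) {
      i <- initial_distribution(s, params, settings)
      data.frame(strategy = s, p_well = i$p_well, p_mild = i$p_mild,
                 p_moderate = i$p_moderate, p_severe = i$p_severe,
                 program_cost = i$program_cost)
    }))
    files <<- c(files, write_csv_plain(init, file.path(out_dir, "initial_distribution.csv")))
    tab
  })

  run_stage("oneway", function() {
    ow <- one_way_sa(model)
    files <<- c(files, write_csv_plain(as.data.frame(ow),
                                       file.path(out_dir, "tornado.csv")))
    ow
  })

  run_stage("twoway", function() {
    tw <- two_way_sa(model)
    files <<- c(files, write_csv_plain(as.data.frame(tw),
                                       file.path(out_dir, "twoway_grid.csv")))
    tw
  })

  run_stage("threshold", function() {
    searches <- list(
      threshold_search(model, "platform_overhead",
                       c(params$platform_overhead, 2000)),
      threshold_search(model, "therapist_time_share_internet",
                       c(params$therapist_time_share_internet, 0.50))
    )
    tab <- do.call(rbind, lapply(searches, function(s)
      data.frame(parameter = s$parameter, bracket_low = s$bracket[1],
                 bracket_high = s$bracket[2], threshold = s$threshold,
                 tol = s$tol)))
    files <<- c(files, write_csv_plain(tab, file.path(out_dir, "thresholds.csv")))
    searches
  })

  run_stage("psa", function() {
    psa <- run_psa(model, n = psa_n, seed = seed)
    files <<- c(files,
                write_csv_plain(psa$draws[c("draw", "d_qaly", "d_cost")],
                                file.path(out_dir, "psa_scatter.csv")),
                write_csv_plain(ceac(psa), file.path(out_dir, "psa_ceac.csv")))
    sm <- summary(psa)
    jsonlite::write_json(unclass(sm), file.path(out_dir, "psa_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <<- c(files, file.path(out_dir, "psa_summary.json"))
    psa
  })

  cfg_path <- file.path(out_dir, "parameters_used.yaml")
  write_parameters(params, cfg_path)
  files <- c(files, cfg_path)
  provenance <- list(
    package = "icbtcea",
    version = as.character(utils::packageVersion("icbtcea")),
    seed = seed,
    psa_n = psa_n,
    stages = stages,
    settings = unclass(settings),
    config_md5 = unname(tools::md5sum(cfg_path))
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(out_dir, "provenance.json"))
  invisible(structure(list(model = model, results = results, errors = errors,
                           files = files, out_dir = out_dir),
                      class = "cea_report"))
}

#' @export
print.cea_report <- function(x, ...) {
  cat("Analysis report in ", x$out_dir, "\n", sep = "")
  cat("  stages: ", paste(names(x$results), collapse = ", "), "\n", sep = "")
  if (length(x$errors))
    cat("  FAILED: ", paste(names(x$errors), collapse = ", "), "\n", sep = "")
  cat("  files:\n")
  for (f in x$files) cat("    ", f, "\n", sep = "")
  invisible(x)
}
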