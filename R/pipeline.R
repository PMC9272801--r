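# End-to-end pipeline and command-line interface:
# load -> medium -> resolve target -> reduce -> search -> refine -> report.

pipeline_options <- function() {
  o <- optparse::make_option
  list(
    o("--model", type = "character", help = "model file (SBML or JSON)"),
    o("--format", type = "character", default = "auto",
      help = "model format: auto|sbml|json [default %default]"),
    o("--target", type = "character", default = NULL,
      help = "target exchange/demand reaction id"),
    o("--metabolite", type = "character", default = NULL,
      help = "target metabolite id (resolved to its unique exchange)"),
    o("--add-demand", action = "store_true", default = FALSE,
      dest = "add_demand",
      help = "append a demand reaction when the metabolite has no exchange"),
    o("--medium", type = "character", default = NULL,
      help = "medium TSV (exchange_id, lb, ub); unlisted uptakes closed"),
    o("--max-kos", type = "integer", default = 5, dest = "max_kos",
      help = "maximum knockouts per design [default %default]"),
    o("--pop", type = "integer", default = 200,
      help = "GA population size [default %default]"),
    o("--time", type = "double", default = 3600,
      help = "search time limit, seconds [default %default]"),
    o("--max-gens", type = "integer", default = 500, dest = "max_gens",
      help = "generation cap [default %default]"),
    o("--stall-gens", type = "integer", default = 50, dest = "stall_gens",
      help = "hypervolume stall window, generations [default %default]"),
    o("--seed", type = "integer", default = 1,
      help = "RNG seed [default %default]"),
    o("--envelope-points", type = "integer", default = 10,
      dest = "envelope_points",
      help = "production-envelope grid intervals [default %default]"),
    o("--tau", type = "double", default = 1e-3,
      help = "relative growth tolerance for guaranteed synthesis"),
    o("--eps-p", type = "double", default = 1e-4, dest = "eps_p",
      help = "product-flux zero threshold"),
    o("--f-min", type = "double", default = 0.1, dest = "f_min",
      help = "growth fraction defining strong coupling"),
    o("--min-growth-frac", type = "double", default = 0.01,
      dest = "min_growth_frac",
      help = "viability threshold as fraction of wild-type growth"),
    o("--gene-assoc-only", action = "store_true", default = FALSE,
      dest = "gene_assoc_only",
      help = "restrict knockouts to gene-associated reactions"),
    o("--exclude-file", type = "character", default = NULL,
      dest = "exclude_file",
      help = "newline-delimited reaction ids to exclude from knockout"),
    o("--out", type = "character", default = "front.csv",
      help = "output CSV path [default %default]"),
    o("--plot", type = "character", default = NULL,
      help = "optional plot path (.png or .svg)"),
    o("--log-level", type = "character", default = "info",
      dest = "log_level", help = "info|quiet [default %default]")
  )
}

#' Run the whole design pipeline
#'
#' Parses CLI-style arguments, then executes: load model, apply medium,
#' resolve target, reduce, NSGA-II search, redundancy refinement, and
#' reporting (CSV, optional plot, provenance JSON next to the CSV).
#' Identical invocations (same files, flags, seed) produce byte-identical
#' CSV output.
#'
#' @param args character vector of command-line arguments, e.g.
#'   `c("--model", "toy.json", "--target", "EXP", "--max-kos", "2")`.
#' @return exit code, invisibly: 0 on success, 2 on usage error.
#' @export
run_pipeline <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(option_list = pipeline_options(),
                                   prog = "gcdesign")
  opt <- tryCatch(optparse::parse_args(parser, args = args),
                  error = function(e) {
                    message("argument error: ", conditionMessage(e))
                    NULL
                  })
  if (is.null(opt)) return(invisible(2L))
  usage_fail <- function(msg) {
    message("usage error: ", msg)
    invisible(2L)
  }
  if (is.null(opt$model)) return(usage_fail("--model is required"))
  if (is.null(opt$target) && is.null(opt$metabolite))
    return(usage_fail("one of --target or --metabolite is required"))
  status <- tryCatch({
    model <- load_model(opt$model, format = opt$format)
    if (!is.null(opt$medium))
      model <- apply_medium(model, read_medium(opt$medium))
    model <- resolve_target(model,
                            if (!is.null(opt$target)) opt$target
                            else opt$metabolite,
                            add_demand = opt$add_demand)
    user_exclude <- if (!is.null(opt$exclude_file))
      readLines(opt$exclude_file, warn = FALSE) else character(0)
    user_exclude <- user_exclude[nzchar(trimws(user_exclude))]
    cfg <- search_config(K_max = opt$max_kos, pop_size = opt$pop,
                         time_limit = opt$time,
                         max_generations = opt$max_gens,
                         stall_generations = opt$stall_gens,
                         seed = opt$seed, tau = opt$tau, eps_p = opt$eps_p,
                         f_min = opt$f_min, n_env = opt$envelope_points,
                         min_growth_frac = opt$min_growth_frac,
                         log_level = opt$log_level)
    space <- build_search_space(model,
                                min_growth_frac = cfg$min_growth_frac,
                                gene_assoc_only = opt$gene_assoc_only,
                                user_exclude = user_exclude)
    archive <- run_search(space$model, space$candidates, cfg)
    archive <- refine_archive(space$model, archive, space$candidates, cfg)
    front <- write_front_csv(archive, space$candidates, opt$out)
    if (cfg$log_level != "quiet") {
      message(sprintf("front_size=%d evaluations=%d csv=%s",
                      nrow(front), archive$n_evaluations, opt$out))
      print_front_console(front)
    }
    if (!is.null(opt$plot)) plot_front(archive, opt$plot)
    write_provenance(opt, cfg, space, archive)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

print_front_console <- function(front) {
  if (!nrow(front)) { message("empty Pareto front"); return(invisible()) }
  txt <- utils::capture.output(print(front, row.names = FALSE))
  for (l in txt) message(l)
}

write_provenance <- function(opt, cfg, space, archive) {
  path <- paste0(tools::file_path_sans_ext(opt$out), "_provenance.json")
  prov <- list(
    package = "gcdesign",
    version = as.character(utils::packageVersion("gcdesign")),
    config = cfg[setdiff(names(cfg), "log_level")],
    model = opt$model,
    seed = opt$seed,
    reduction = list(
      dropped_dead = space$map$dropped,
      lump_groups = space$map$lump_groups,
      n_targets = length(space$candidates$targets),
      excluded = space$candidates$excluded
    ),
    search = list(evaluations = archive$n_evaluations,
                  generations = archive$generations,
                  archive_size = length(archive$designs))
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
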