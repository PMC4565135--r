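# End-to-end pipeline orchestration: simulate (or load) -> per-dataset
# differential expression -> score combination -> signature-length
# progression -> perturbation stability, with all artefacts written as TSV
# and a JSON manifest recording seed, configuration and row counts.

#' Assemble a pipeline run configuration
#'
#' Exactly one of `simulation` or `inputs` must be supplied.
#'
#' @param simulation Named list of [generate_study()] /
#'   [generate_reference_db()] arguments (`study = list(...)`,
#'   `reference = list(...)`), or `TRUE` for all defaults.
#' @param inputs Named list with `expression` (character vector of matrix
#'   TSV paths), `metadata` (matching metadata TSV paths), `reference`
#'   (reference-database TSV path), and optional `stages` (stage filter
#'   applied to every dataset).
#' @param diffexp Named list: `pi0_method` (default `"lfdr"`), `pi0` (fixed
#'   override), `min_abs_log2_fc` (default 1), `log2_input` (default TRUE).
#' @param progression A [progression_config()].
#' @param perturbation Named list: `n_remove` (default 1), `n_perturbations`
#'   (default 100), `mode` (default `"auto"`).
#' @param n_null Monte-Carlo null size (default 1000).
#' @param seed Integer seed; drawn (and recorded) if missing.
#' @param outdir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, inputs = NULL,
                       diffexp = list(), progression = progression_config(),
                       perturbation = list(), n_null = 1000,
                       seed = NULL, outdir = tempfile("mdcmap_run_")) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of 'simulation' or 'inputs' must be given", call. = FALSE)
  }
  if (isTRUE(simulation)) simulation <- list()
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  de_defaults <- list(pi0_method = "lfdr", pi0 = NULL, min_abs_log2_fc = 1,
                      log2_input = TRUE)
  pert_defaults <- list(n_remove = 1, n_perturbations = 100, mode = "auto")
  structure(
    list(simulation = simulation, inputs = inputs,
         diffexp = utils::modifyList(de_defaults, diffexp),
         progression = progression,
         perturbation = utils::modifyList(pert_defaults, perturbation),
         n_null = n_null, seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

.load_study <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    study_args <- sim$study %||% list()
    study_args$seed <- study_args$seed %||% derive_seed(config$seed, 101L)
    study <- do.call(generate_study, study_args)
    universe <- intersect_universes(study$datasets)
    # reference database planted against the combined top genes, so the
    # planted truth is discoverable by the pipeline itself
    des <- lapply(study$datasets, run_diffexp,
                  pi0_method = config$diffexp$pi0_method,
                  pi0 = config$diffexp$pi0)
    combined <- combine_scores(lapply(des, score_dataset,
                                      min_abs_log2_fc = config$diffexp$min_abs_log2_fc))
    ref_args <- sim$reference %||% list()
    ref_args$universe <- universe
    ref_args$seed <- ref_args$seed %||% derive_seed(config$seed, 202L)
    if (is.null(ref_args$signature)) {
      ref_args$signature <- take_top(combined,
                                     min(20L, combined$nonzero_total))
    }
    ref <- do.call(generate_reference_db, ref_args)
    list(datasets = study$datasets, db = ref$db, truth = study$truth,
         ref_truth = ref$truth)
  } else {
    inp <- config$inputs
    if (length(inp$expression) != length(inp$metadata)) {
      stop("'expression' and 'metadata' path lists must match", call. = FALSE)
    }
    datasets <- Map(read_expression, inp$expression, inp$metadata,
                    MoreArgs = list(log2_input = config$diffexp$log2_input))
    if (!is.null(inp$stages)) {
      datasets <- lapply(datasets, filter_by_stage, stages = inp$stages)
    }
    universe <- intersect_universes(datasets)
    datasets <- lapply(datasets, restrict_universe, universe = universe)
    list(datasets = unname(datasets), db = read_reference_db(inp$reference),
         truth = NULL, ref_truth = NULL)
  }
}

#' Run the full pipeline
#'
#' Executes all stages in order and writes, under `config$outdir`:
#' per-dataset differential-expression TSVs, the combined signature TSV,
#' the final query signature, the progression trace, the hit table with
#' perturbation stabilities, and `manifest.json` (package version, seed,
#' configuration echo, per-stage row counts). A rerun with the same
#' configuration and seed reproduces every output.
#'
#' @param config A [run_config()].
#' @param verbose Print per-stage progress.
#' @return Invisibly, a list with the in-memory results (`diffexp`,
#'   `combined`, `progression`, `stability`, `hits`, `manifest`, `outdir`).
#' @export
run_full_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("loading inputs")
  loaded <- .load_study(config)
  if (length(loaded$datasets) == 0L) stop("no datasets loaded", call. = FALSE)
  universe <- intersect_universes(loaded$datasets)
  datasets <- lapply(loaded$datasets, restrict_universe, universe = universe)

  say("differential expression (%d datasets)", length(datasets))
  des <- lapply(datasets, run_diffexp, pi0_method = config$diffexp$pi0_method,
                pi0 = config$diffexp$pi0)
  for (de in des) {
    write_diffexp(de, file.path(config$outdir,
                                paste0("diffexp_", de$dataset_name, ".tsv")))
  }

  say("combining scores")
  combined <- combine_scores(lapply(des, score_dataset,
                                    min_abs_log2_fc = config$diffexp$min_abs_log2_fc))
  write_combined_signature(combined, file.path(config$outdir,
                                               "combined_signature.tsv"))

  say("signature progression")
  state <- run_progression(combined, loaded$db, config$progression,
                           n_null = config$n_null,
                           seed = derive_seed(config$seed, 303L),
                           verbose = verbose)
  write_progression_trace(state, file.path(config$outdir,
                                           "progression_trace.tsv"))
  write_signature(state$signature, file.path(config$outdir,
                                             "final_signature.tsv"))

  hits <- state$final_hits
  stability <- NULL
  if (nrow(hits) > 0L && nrow(state$signature) > 1L) {
    say("perturbation stability (%d hits)", nrow(hits))
    stability <- stability_scores(
      state$signature, loaded$db, hits,
      n_remove = config$perturbation$n_remove,
      n_perturbations = config$perturbation$n_perturbations,
      mode = config$perturbation$mode,
      Efp = config$progression$Efp, n_null = config$n_null,
      seed = derive_seed(config$seed, 404L))
    hits <- add_stability(hits, stability)
  }
  write_connection_results(hits, file.path(config$outdir, "drug_hits.tsv"))

  manifest <- list(
    package = "mdcmap",
    version = as.character(utils::packageVersion("mdcmap")),
    seed = config$seed,
    n_null = config$n_null,
    diffexp = config$diffexp[c("pi0_method", "min_abs_log2_fc")],
    progression = unclass(config$progression),
    perturbation = config$perturbation,
    datasets = lapply(des, function(d)
      list(name = d$dataset_name, N = d$N, M = d$M, pi0 = d$pi0,
           threshold = d$threshold)),
    combined_nonzero = combined$nonzero_total,
    final_m = state$final_m,
    converged = state$converged,
    n_hits = nrow(hits)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", config$outdir)
  invisible(list(diffexp = des, combined = combined, progression = state,
                 stability = stability, hits = hits, truth = loaded$truth,
                 ref_truth = loaded$ref_truth, manifest = manifest,
                 outdir = config$outdir))
}
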