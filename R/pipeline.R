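#' Pipeline run configuration
#'
#' Collects every knob of the full analysis. Exactly one of `input` (path to
#' an aligned FASTA) or `fixture_seed` (simulate the 14-taxon fixture) must
#' be given. Defaults mirror the analysis the package reproduces: model
#' chosen by AIC, 5 search restarts, 1,000 bootstrap pseudoreplicates;
#' validation runs typically scale `n_bootstrap` down.
#'
#' @param input Path to a gapped multi-FASTA alignment, or `NULL`.
#' @param fixture_seed Seed for [simulate_pinniped_fixture()], or `NULL`.
#' @param reference_taxon Intact reference taxon (defaults to
#'   `"domestic_dog"` for the fixture).
#' @param frame_offset Codon position of the first reference column.
#' @param outgroup Character vector of outgroup taxa used for rooting.
#' @param model `"auto"` (AIC selection) or an [hky_gamma_model()].
#' @param n_bootstrap Bootstrap pseudoreplicates (0 disables supports).
#' @param n_restarts Stepwise-addition restarts for the main search (>= 1).
#' @param seed Integer master seed for search and bootstrap.
#' @param output_dir Directory for the result bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, fixture_seed = NULL,
                            reference_taxon = "domestic_dog",
                            frame_offset = 1L,
                            outgroup = c("domestic_dog", "red_fox"),
                            model = "auto", n_bootstrap = 1000L,
                            n_restarts = 5L, seed = 1L,
                            output_dir = tempfile("pseudophy_run")) {
  if (is.null(input) == is.null(fixture_seed)) {
    stop_pseudophy("usage_error",
                   "give exactly one of `input` or `fixture_seed`")
  }
  if (n_bootstrap < 0L) {
    stop_pseudophy("usage_error", "n_bootstrap must be >= 0")
  }
  if (n_restarts < 1L) {
    stop_pseudophy("usage_error", "n_restarts must be >= 1")
  }
  structure(list(input = input, fixture_seed = fixture_seed,
                 reference_taxon = reference_taxon,
                 frame_offset = as.integer(frame_offset),
                 outgroup = outgroup, model = model,
                 n_bootstrap = as.integer(n_bootstrap),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    log(sprintf("stage %s FAILED: %s", stage, conditionMessage(e)))
    stop_pseudophy("stage_error",
                   sprintf("[%s] %s", stage, conditionMessage(e)),
                   stage = stage, parent = e)
  })
  log(sprintf("stage %s done (%.2f s)", stage,
              proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the alignment; scan for inactivating
#' mutations and classify ORFs; encode for likelihood analysis (insertions
#' dropped, deletions/nonsense/N/gaps as missing); choose the substitution
#' model by AIC on a neighbour-joining starting tree (or use the supplied
#' model); heuristic ML tree search; bootstrap supports (when
#' `n_bootstrap > 0`); outgroup rooting; Dollo placement of each mutation and
#' partial ordering of events along lineages. All stage outputs are written
#' to `output_dir` (`report.tsv`, `ml_tree.nwk`, `placements.tsv`,
#' `event_order.tsv`, `alignment.fasta` and `true_tree.nwk` for simulated
#' input, and `run.log`). Reruns with an identical config produce
#' byte-identical result files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a result bundle: `alignment`, `scan`, `matrix`, `fit`,
#'   `ml_tree`, `supports`, `rooted_tree`, `placements`, `event_order`,
#'   `files`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log <- function(msg) writeLines(
    sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg), log_con)
  log(sprintf("seed = %d; restarts = %d; bootstrap = %d", config$seed,
              config$n_restarts, config$n_bootstrap))

  sim <- NULL
  alignment <- run_stage("input", log, {
    if (!is.null(config$input)) {
      read_fasta_alignment(config$input, config$reference_taxon,
                           config$frame_offset)
    } else {
      # the braces evaluate in this function's frame, so plain assignment
      # updates the `sim` defined above
      sim <- simulate_pinniped_fixture(config$fixture_seed)
      log(sprintf("simulated fixture with seed %d", config$fixture_seed))
      sim$alignment
    }
  })

  scan <- run_stage("scan", log, classify_orf(alignment))
  log(sprintf("%d merged mutations; %d taxa disrupted",
              length(scan$mutations),
              sum(scan$orf_status$status == "disrupted")))

  matrix <- run_stage("encode", log,
                      encode_for_ml(alignment, scan$mutations))
  log(sprintf("%d sites retained of %d columns", matrix$n_sites,
              alignment$n_columns))

  fit <- run_stage("model", log, {
    if (inherits(config$model, "hky_gamma_model")) {
      list(model = config$model, type = "user", gamma =
             !is.null(config$model$alpha))
    } else {
      start <- nj_start_tree(matrix)
      select_model(matrix, start)
    }
  })
  log(sprintf("model: %s%s (kappa = %.3f%s)",
              toupper(fit$type), if (fit$gamma) "+G" else "",
              fit$model$kappa,
              if (is.null(fit$model$alpha)) "" else
                sprintf(", alpha = %.3f", fit$model$alpha)))

  ml_tree <- run_stage("search", log,
                       search_ml_tree(matrix, fit$model,
                                      n_restarts = config$n_restarts,
                                      seed = config$seed))
  log(sprintf("ML tree logL = %.4f", attr(ml_tree, "logL")))

  supports <- NULL
  out_tree <- ml_tree
  if (config$n_bootstrap > 0L) {
    bs <- run_stage("bootstrap", log,
                    bootstrap_support(matrix, fit$model, ml_tree,
                                      n_replicates = config$n_bootstrap,
                                      seed = config$seed + 1L))
    supports <- bs$supports
    out_tree <- bs$tree
  }

  rooted <- run_stage("root", log, root_tree(out_tree, config$outgroup))

  placements <- run_stage("map", log, {
    M <- build_event_matrix(scan$mutations, alignment$taxa)
    place_events(rooted, M)
  })
  event_order <- run_stage("order", log, order_events(placements, rooted))

  files <- run_stage("write", log, {
    paths <- list(
      report = file.path(config$output_dir, "report.tsv"),
      tree = file.path(config$output_dir, "ml_tree.nwk"),
      placements = file.path(config$output_dir, "placements.tsv"),
      order = file.path(config$output_dir, "event_order.tsv"))
    write_report(scan$mutations, scan$orf_status, paths$report,
                 placements = placements)
    write_newick(rooted, paths$tree)
    write.table(placements, paths$placements, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(event_order, paths$order, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(sim)) {
      paths$alignment <- file.path(config$output_dir, "alignment.fasta")
      paths$true_tree <- file.path(config$output_dir, "true_tree.nwk")
      write_fasta_alignment(alignment, paths$alignment)
      write_newick(sim$tree, paths$true_tree)
    }
    paths
  })

  invisible(list(alignment = alignment, scan = scan, matrix = matrix,
                 fit = fit, ml_tree = ml_tree, supports = supports,
                 rooted_tree = rooted, placements = placements,
                 event_order = event_order, files = files))
}

# Neighbour-joining starting topology on raw p-distances (missing data
# pairwise-deleted); used only to give model selection a reasonable tree.
nj_start_tree <- function(matrix) {
  chars <- tolower(matrix$states)
  chars[chars == "?"] <- "n"
  dna <- ape::as.DNAbin(chars)
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  tree <- ape::nj(d)
  tree$edge.length <- pmax(tree$edge.length, BL_MIN)
  tree
}
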