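#' Assemble and validate a pipeline configuration
#'
#' One object drives [run_pipeline()]: either a simulation config (the
#' default) or a directory of counts, plus per-stage sections. Validation
#' (file existence, required fields) happens here, before any compute.
#'
#' @param seed Global integer seed (mandatory).
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param simulate A [sim_config()], or NULL when loading counts.
#' @param counts_dir Directory readable by [read_count_matrix()]
#'   (alternative to `simulate`).
#' @param qc List: `thresholds` (a [qc_thresholds()]),
#'   `protein_coding_only`, `doublets` ("truth" to use simulated ground
#'   truth, a character vector of barcodes, or NULL).
#' @param normalize List: `scale_factor`.
#' @param de List: `clusters` (NULL = all), `variable`, `covariates`,
#'   `binary` (is the variable binary), plus DEG thresholds `min_pct`,
#'   `alpha`, `min_lnfc`.
#' @param constellation List: `enabled`, `clusters`, `n_variable_genes`,
#'   `pc_variance_threshold`, `n_repeats`, `threshold`.
#' @param prioritize List: `enabled`, `prior` (a [prior_model()] or NULL),
#'   `strength_path`/`pairs_path` (read when `prior` is NULL),
#'   `source_clusters`, `target_clusters`, `blacklist`, `k`,
#'   `min_detection`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir,
                            simulate = sim_config(),
                            counts_dir = NULL,
                            qc = list(),
                            normalize = list(),
                            de = list(),
                            constellation = list(),
                            prioritize = list()) {
  if (missing(seed)) stop("`seed` is mandatory")
  qc <- utils::modifyList(
    list(thresholds = qc_thresholds(), protein_coding_only = FALSE,
         doublets = "truth"), qc)
  normalize <- utils::modifyList(list(scale_factor = 1e4), normalize)
  de <- utils::modifyList(
    list(clusters = NULL, variable = "diagnosis",
         covariates = character(), binary = TRUE, min_pct = 0.20,
         alpha = 0.05, min_lnfc = 0.1), de)
  constellation <- utils::modifyList(
    list(enabled = FALSE, clusters = NULL, n_variable_genes = 2000,
         pc_variance_threshold = 0.95, n_repeats = 100, threshold = 25),
    constellation)
  prioritize <- utils::modifyList(
    list(enabled = FALSE, prior = NULL, strength_path = NULL,
         pairs_path = NULL, source_clusters = NULL,
         target_clusters = NULL, blacklist = character(), k = 250,
         min_detection = 0.10), prioritize)
  if (is.null(simulate) && is.null(counts_dir)) {
    stop("either `simulate` or `counts_dir` must be given")
  }
  if (!is.null(counts_dir) && !dir.exists(counts_dir)) {
    stop("`counts_dir` does not exist: ", counts_dir)
  }
  if (prioritize$enabled && is.null(prioritize$prior)) {
    if (is.null(prioritize$strength_path) ||
        !file.exists(prioritize$strength_path)) {
      stop("prioritization enabled but no prior model supplied")
    }
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, counts_dir = counts_dir, qc = qc,
                 normalize = normalize, de = de,
                 constellation = constellation, prioritize = prioritize),
            class = "pipeline_config")
}

write_stage_csv <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(x, path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes QC, normalization, marker calling, differential expression,
#' and the optional constellation and ligand-target stages in order,
#' writing every intermediate artifact as CSV under the configured output
#' directory plus a JSON manifest (seed, per-stage row counts, file
#' checksums). Re-running with the same configuration reproduces
#' byte-identical CSVs. A stage failure halts with the stage name; the
#' partial manifest is still written.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), files = list())
  files <- character(0)
  current_stage <- "init"
  finish <- function() {
    manifest$files <<- as.list(tools::md5sum(files))
    names(manifest$files) <<- basename(files)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run <- function(stage, expr) {
    current_stage <<- stage
    tryCatch(expr, error = function(e) {
      finish()
      stop("stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  cm <- run("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_experiment(config$simulate)
      truth <- sim$truth
      sim$counts
    } else {
      read_count_matrix(config$counts_dir)
    }
  })
  manifest$stages$input <- list(genes = nrow(cm$counts),
                                cells = ncol(cm$counts))

  post_qc <- run("qc", {
    fb <- filter_barcodes(cm, config$qc$thresholds)
    x <- fb$counts
    doub <- config$qc$doublets
    if (identical(doub, "truth")) {
      doub <- if (is.null(truth)) character(0) else truth$doublet_cells
    }
    if (length(doub)) {
      x <- suppressWarnings(apply_doublet_labels(x, doub))$counts
    }
    fg <- filter_genes(x, config$qc$thresholds,
                       config$qc$protein_coding_only)
    write_qc_report(fb$report, file.path(config$out_dir,
                                         "qc_barcodes.json"))
    write_qc_report(fg$report, file.path(config$out_dir, "qc_genes.json"))
    files <- c(files, file.path(config$out_dir,
                                c("qc_barcodes.json", "qc_genes.json")))
    fg$counts
  })
  manifest$stages$qc <- list(genes = nrow(post_qc$counts),
                             cells = ncol(post_qc$counts))

  norm <- run("normalize",
              normalize_counts(post_qc, config$normalize$scale_factor))

  de_cfg <- config$de
  de_clusters <- de_cfg$clusters
  if (is.null(de_clusters)) de_clusters <- sort(unique(norm$cells$cluster))
  degs_by_cluster <- list()
  de_tbl <- run("de", {
    purrr::map_dfr(de_clusters, function(cl) {
      res <- run_hurdle_de(norm, cl, de_cfg$variable, de_cfg$covariates)
      degs_by_cluster[[as.character(cl)]] <<-
        select_degs(res, de_cfg$binary, de_cfg$min_pct, de_cfg$alpha,
                    de_cfg$min_lnfc)
      dplyr::mutate(tibble::as_tibble(res), cluster = as.character(cl),
                    .before = 1)
    })
  })
  files <- c(files, write_stage_csv(de_tbl, config$out_dir,
                                    "de_results.csv"))
  deg_tbl <- purrr::map_dfr(names(degs_by_cluster), function(cl) {
    dplyr::mutate(degs_by_cluster[[cl]], cluster = cl, .before = 1)
  })
  files <- c(files, write_stage_csv(deg_tbl, config$out_dir, "degs.csv"))
  manifest$stages$de <- list(tested = nrow(de_tbl), degs = nrow(deg_tbl))

  if (config$constellation$enabled) {
    cc <- config$constellation
    amb <- run("constellation", {
      keep <- if (is.null(cc$clusters)) rep(TRUE, nrow(norm$cells)) else
        norm$cells$cluster %in% cc$clusters
      feats <- suppressWarnings(
        build_features(norm, norm$cells$barcode[keep],
                       cc$n_variable_genes, cc$pc_variance_threshold))
      labels <- stats::setNames(as.character(norm$cells$cluster[keep]),
                                norm$cells$barcode[keep])
      ambiguity_matrix(feats, labels, n_repeats = cc$n_repeats,
                       threshold = cc$threshold, seed = config$seed)
    })
    files <- c(files, write_stage_csv(
      dplyr::select(amb, -"cell_counts"), config$out_dir,
      "ambiguity.csv"))
    manifest$stages$constellation <- list(pairs = nrow(amb))
  }

  if (config$prioritize$enabled) {
    pz <- config$prioritize
    edges <- run("prioritize", {
      prior <- pz$prior
      if (is.null(prior)) {
        prior <- read_prior_model(pz$strength_path, pz$pairs_path)
      }
      src <- as.character(pz$source_clusters)
      tgt <- as.character(pz$target_clusters)
      expressed <- stats::setNames(
        lapply(tgt, function(cl) expressed_genes(norm, cl,
                                                 pz$min_detection)), tgt)
      prioritize_edges(degs_by_cluster[src], degs_by_cluster[tgt], prior,
                       expressed, pz$blacklist, pz$k)
    })
    files <- c(files, write_stage_csv(edges, config$out_dir, "edges.csv"))
    manifest$stages$prioritize <- list(edges = nrow(edges))
  }

  finish()
  invisible(manifest)
}
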