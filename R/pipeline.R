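#' Full pipeline configuration
#'
#' Bundles every stage's configuration plus the ablation mode flags:
#' `no_dec` (drop the self-supervised clustering head), `no_image` (skip
#' histology augmentation) and `no_consensus` (report the single
#' best-likelihood view instead of the consensus merge).
#'
#' @param preprocess a [preprocess_config()]
#' @param augment an [augment_config()]
#' @param augment_enabled use histology augmentation if tiles/image present
#' @param views list of view specs (see [build_views()])
#' @param model a [model_config()]
#' @param n_clusters number of spatial domains (user-supplied, as in
#'   ground-truth-K evaluation practice)
#' @param seed master seed; stage seeds are derived deterministically
#' @param restarts EM restarts for the clusterers
#' @param linkage consensus linkage
#' @param no_dec,no_image,no_consensus ablation switches
#' @param output_dir optional directory for [write_results()]
#' @param verbose stage logging
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            augment = augment_config(),
                            augment_enabled = FALSE,
                            views = default_view_specs(),
                            model = model_config(), n_clusters = 2,
                            seed = 0, restarts = 10, linkage = "average",
                            no_dec = FALSE, no_image = FALSE,
                            no_consensus = FALSE, output_dir = NULL,
                            verbose = FALSE) {
  if (length(views) < 1) mvc_validation_error("need >= 1 view")
  if (n_clusters < 2) mvc_validation_error("n_clusters must be >= 2")
  structure(list(preprocess = preprocess, augment = augment,
                 augment_enabled = augment_enabled, views = views,
                 model = model, n_clusters = as.integer(n_clusters),
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 linkage = linkage, no_dec = isTRUE(no_dec),
                 no_image = isTRUE(no_image),
                 no_consensus = isTRUE(no_consensus),
                 output_dir = output_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

stage <- function(name, cfg, expr) {
  mvc_log(sprintf("stage %s: start", name), verbose = cfg$verbose)
  t0 <- Sys.time()
  res <- withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("mvc_stage_error", class(e)),
                     list(message = sprintf("[stage %s] %s", name,
                                            conditionMessage(e)),
                          call = conditionCall(e), stage = name)))
    }),
    warning = function(w) {
      mvc_log(sprintf("stage %s: warning: %s", name, conditionMessage(w)),
              verbose = cfg$verbose)
      invokeRestart("muffleWarning")
    })
  mvc_log(sprintf("stage %s: done (%.2fs)", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))),
          verbose = cfg$verbose)
  res
}

#' Shared preprocessing + augmentation front end (cacheable)
#' @noRd
prepare_input <- function(ds, cfg) {
  pp <- stage("preprocess", cfg, preprocess_dataset(ds, cfg$preprocess))
  x <- pp$expression
  augmented <- FALSE
  if (cfg$augment_enabled && !cfg$no_image) {
    x <- stage("augment", cfg, {
      tiles <- ds$tiles
      if (is.null(tiles)) tiles <- cut_tiles(ds, cfg$augment$tile_size)
      raw <- extract_cnn_features(tiles)
      ms <- align_features(raw, ncol(x), cfg$augment)
      augmented <- TRUE
      augment_expression(ms, x, cfg$augment$alpha1, cfg$augment$alpha2)
    })
    augmented <- TRUE
  }
  list(dataset = pp, x = x, augmented = augmented,
       hash = hash_object(list(x, pp$gene_ids)))
}

#' Run the complete multi-view consensus pipeline
#'
#' preprocess -> (optional) histology augmentation -> build views -> train
#' one VGAE per view -> cluster each view -> consensus merge -> optional
#' result writing.  Deterministic given `cfg$seed`.
#'
#' @param ds an [st_dataset] of raw counts
#' @param cfg a [pipeline_config()]
#' @param prepared optional precomputed [prepare_input] result (used by the
#'   sweep driver to share preprocessing)
#' @return list with `result` (a `consensus_result`), `embeddings`,
#'   `views`, `metrics` (a `metric_report` if the dataset has truth
#'   labels), `input_hash`
#' @export
run_pipeline <- function(ds, cfg = pipeline_config(), prepared = NULL) {
  if (cfg$augment_enabled && !cfg$no_image && is.null(ds$tiles) &&
      (is.null(ds$image) || is.null(ds$pixel_coords)))
    stop(structure(class = c("mvc_stage_error", "mvc_config_error", "error",
                             "condition"),
                   list(message = "[stage augment] no image/tiles available; disable augmentation",
                        call = NULL, stage = "augment")))
  prep <- prepared %||% prepare_input(ds, cfg)
  views <- stage("views", cfg, build_views(prep$dataset, cfg$views, x = prep$x))
  mcfg <- cfg$model
  if (cfg$no_dec) mcfg$lambda4 <- 0
  embeddings <- vector("list", length(views))
  for (i in seq_along(views)) {
    vcfg <- mcfg
    vcfg$seed <- mcfg$seed + cfg$seed + (i - 1L) * 101L
    g <- normalize_adjacency(views[[i]])
    embeddings[[i]] <- stage(paste0("train_", views[[i]]$view_id), cfg,
                             train_view(prep$x, g, cfg$n_clusters, vcfg,
                                        verbose = cfg$verbose))
  }
  names(embeddings) <- names(views)
  result <- stage("consensus", cfg,
                  run_consensus(embeddings, cfg$n_clusters,
                                seed = cfg$seed, restarts = cfg$restarts,
                                use_consensus = !cfg$no_consensus,
                                linkage = cfg$linkage))
  metrics <- NULL
  if (!is.null(ds$truth_labels))
    metrics <- stage("metrics", cfg,
                     metric_report(ds$truth_labels, result$final_labels))
  if (!is.null(cfg$output_dir))
    stage("write", cfg,
          write_results(prep$dataset, result, cfg$output_dir,
                        embeddings = embeddings))
  list(result = result, embeddings = embeddings, views = views,
       metrics = metrics, input_hash = prep$hash)
}

#' Run the pipeline over several view subsets, sharing preprocessing
#'
#' One pipeline run per subset with a deterministic per-row seed
#' (`seed + row index - 1`); preprocessing and augmentation are computed
#' once and reused (the shared-input hash is recorded per row).
#'
#' @param ds an [st_dataset] with truth labels
#' @param cfg a [pipeline_config()] (its `views` field is ignored)
#' @param view_subsets list of view-spec lists
#' @return data.frame with one metrics row per subset
#' @export
run_view_sweep <- function(ds, cfg, view_subsets) {
  if (is.null(ds$truth_labels))
    mvc_validation_error("view sweep needs truth labels")
  prep <- prepare_input(ds, cfg)
  rows <- lapply(seq_along(view_subsets), function(i) {
    cfg_i <- cfg
    cfg_i$views <- view_subsets[[i]]
    cfg_i$seed <- cfg$seed + i - 1L
    out <- run_pipeline(ds, cfg_i, prepared = prep)
    data.frame(subset = paste(vapply(view_subsets[[i]], view_spec_id,
                                     character(1)), collapse = "+"),
               seed = cfg_i$seed, ari = out$metrics$ari,
               nmi = out$metrics$nmi, hs = out$metrics$hs,
               purity = out$metrics$purity, input_hash = out$input_hash,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
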