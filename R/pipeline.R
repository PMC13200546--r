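#' Run the full fusion pipeline
#'
#' End-to-end orchestration: gene sets + descriptions in, clustered
#' super-PAGs with summaries out. Stages, in order: read inputs; build the
#' m-type overlap network; score clusterability (CDI) and warn (or abort,
#' if `cdi_hard_gate`) when the network looks unclusterable; embed the
#' graph by random walks; encode and PCA-align the descriptions; fuse at
#' `alpha`; select k by consensus; cluster the fused space; summarize each
#' cluster. All seeds derive from `seed`, so a rerun with the same
#' configuration reproduces every output file byte for byte.
#'
#' @param config Configuration list or path to a YAML file. Recognized
#'   fields: `gmt` (path) or `collection`; `descriptions` (path or named
#'   vector; defaults to the collection's own); `out_dir` (optional run
#'   directory; when set, labels / summaries / parameters / log files are
#'   written); `alpha` (default 0.8), `fusion_mode` (`"blend"`),
#'   `dim` (graph dimension, default 64), `walk` (overrides for
#'   [walk_config()]), `p_cutoff` (0.05), `min_overlap` (1), `k` (fixed
#'   cluster count; otherwise consensus over `k_range`, default 2:6),
#'   `final_method` (default `"kmeans"`), `cdi_model` (a fitted
#'   [train_cdi()] model, a path prefix, or NULL to train a compact
#'   default sweep), `cdi_threshold` (0.5), `cdi_hard_gate` (FALSE),
#'   `consensus` (overrides for [consensus_profile()]), `seed` (1).
#' @return List with `cdi`, `selected_k`, `clustering`, `summaries`,
#'   `profile`, `network`, `config`, and `files` (paths written, if any).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  seed <- cfg$seed %||% 1
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[pagfusion] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  collection <- if (!is.null(cfg$collection)) cfg$collection else {
    if (is.null(cfg$gmt)) stop("config needs `gmt` or `collection`", call. = FALSE)
    read_gmt(cfg$gmt)
  }
  descriptions <- cfg$descriptions %||% collection_descriptions(collection)
  if (is.character(descriptions) && length(descriptions) == 1 &&
      file.exists(descriptions)) {
    descriptions <- read_descriptions(descriptions)
  }
  ids <- pag_ids(collection)
  texts <- descriptions[ids]
  texts[is.na(texts)] <- ""
  names(texts) <- ids
  say("collection: %d PAGs, universe %d genes", length(ids),
      length(collection$universe))

  net <- build_mtype_network(collection, p_cutoff = cfg$p_cutoff %||% 0.05,
                             min_overlap = cfg$min_overlap %||% 1)
  say("m-type network: %d edges", nrow(net$edges))

  cdi_model <- cfg$cdi_model
  if (is.character(cdi_model)) cdi_model <- read_cdi_model(cdi_model)
  if (is.null(cdi_model)) {
    say("training compact CDI model (no model supplied)")
    ts <- build_training_set(replicates = 3, n_nodes = 120,
                             seed = derive_seed(seed, "cdi-sweep"))
    cdi_model <- train_cdi(ts, model_kinds = "random_forest",
                           split_seed = derive_seed(seed, "cdi-split"))
  }
  cdi <- cdi_score(cdi_model, net)
  say("CDI = %.3f", cdi)
  if (cdi < (cfg$cdi_threshold %||% 0.5)) {
    if (isTRUE(cfg$cdi_hard_gate)) {
      stop(sprintf("CDI %.3f below threshold %.2f: network judged unclusterable",
                   cdi, cfg$cdi_threshold %||% 0.5), call. = FALSE)
    }
    warning(sprintf(paste0("CDI %.3f below threshold %.2f: the PAG network ",
                           "shows weak cluster structure; results may not be ",
                           "meaningful"), cdi, cfg$cdi_threshold %||% 0.5),
            call. = FALSE)
    say("WARNING: low CDI (%.3f)", cdi)
  }

  walk_args <- cfg$walk %||% list()
  walk_args$dim <- walk_args$dim %||% (cfg$dim %||% 64)
  walk_args$seed <- derive_seed(seed, "embed")
  wcfg <- do.call(walk_config, walk_args)
  d_g <- embed_graph(net, wcfg)
  say("graph embedding: %d x %d", nrow(d_g$vectors), d_g$dim)

  d_s_raw <- encode_descriptions(texts, cfg$encoder %||% hash_text_encoder())
  target <- min(wcfg$dim, length(ids) - 1, d_s_raw$dim)
  d_s <- suppressWarnings(pca_align(d_s_raw, target))
  if (target < wcfg$dim) {
    d_s <- embedding_matrix(cbind(d_s$vectors,
                                  matrix(0, length(ids), wcfg$dim - target)),
                            ids, "semantic", TRUE)
  }
  say("semantic embedding: %d -> %d dims (%.0f%% variance retained)",
      d_s_raw$dim, target, 100 * (attr(d_s, "retained_variance") %||% 1))

  alpha <- cfg$alpha %||% 0.8
  fused <- fuse(subset_embedding(d_g, ids), d_s, alpha = alpha,
                mode = cfg$fusion_mode %||% "blend")
  say("fused at alpha = %.2f", alpha)

  profile <- NULL
  if (!is.null(cfg$k)) {
    selected_k <- as.integer(cfg$k)
    say("fixed k = %d", selected_k)
  } else {
    cons_args <- cfg$consensus %||% list()
    cons_args$data <- fused
    cons_args$k_range <- cons_args$k_range %||% (cfg$k_range %||% 2:6)
    cons_args$seed <- derive_seed(seed, "consensus")
    profile <- do.call(consensus_profile, cons_args)
    selected_k <- profile$selected_k
    say("consensus selected k = %d%s", selected_k,
        if (profile$no_structure) " (no stable structure)" else "")
  }

  clustering <- cluster_pags(fused, method = cfg$final_method %||% "kmeans",
                             k = selected_k,
                             seed = derive_seed(seed, "final-cluster"))
  say("final clustering: %d cluster(s)", clustering$k_effective)

  summaries <- summarize_clusters(clustering, texts,
                                  summarizer = cfg$summarizer %||% extractive_summarizer)
  say("summaries: %d cluster(s)", nrow(summaries))

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- function(name) file.path(cfg$out_dir, name)
    write_labels_tsv(clustering, f("labels.tsv"))
    utils::write.table(summaries, f("summaries.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      cdi = cdi, selected_k = selected_k, alpha = alpha,
      n_pags = length(ids), n_edges = nrow(net$edges),
      seed = seed, walk = unclass(wcfg),
      p_cutoff = cfg$p_cutoff %||% 0.05,
      min_overlap = cfg$min_overlap %||% 1),
      f("run.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, f("log.txt"))
    files <- c(labels = f("labels.tsv"), summaries = f("summaries.tsv"),
               run = f("run.json"), log = f("log.txt"))
  }

  list(cdi = cdi, selected_k = selected_k, clustering = clustering,
       summaries = summaries, profile = profile, network = net,
       embeddings = list(graph = d_g, semantic = d_s, fused = fused),
       config = cfg, files = files)
}
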