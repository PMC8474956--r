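# End-to-end experiment runner: matrix/world -> selection -> pre-train ->
# fine-tune -> evaluate, with a manifest sufficient to re-run
# bit-compatibly.

config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

required_field <- function(config, path) {
  node <- config
  for (p in strsplit(path, "\\.")[[1]]) {
    node <- node[[p]]
    if (is.null(node)) stop("experiment config: missing field '", path, "'")
  }
  node
}

#' Default experiment configuration
#'
#' @return named list of defaults that [run_experiment()] merges under the
#'   user configuration.
#' @export
experiment_defaults <- function() {
  list(strategy = "same_bm", k = 5L, include_target = FALSE,
       architecture = "basset_like",
       multi_n = NULL, single_n = NULL,
       transfer_mode = "all_but_output", freeze = "none",
       learning_rate = 0.003, finetune_learning_rate = 0.0003,
       batch_size = 100L, max_epochs = 30L, patience = 5L,
       seeds = 1:5)
}

#' Run a transfer-learning experiment from a configuration
#'
#' The configuration (a YAML file path or a named list) must provide a
#' synthetic world (`world:` holding [world_config()] fields) or matrix
#' archive paths plus sequences, a `target_tf`, and an `out_dir`; all
#' other fields default to [experiment_defaults()]. The runner selects the
#' pre-training TF set by the configured strategy, builds disjoint
#' pre-training and fine-tuning datasets, pre-trains one multi-task model,
#' and for each seed fine-tunes a transferred model and trains a
#' from-scratch baseline, writing `performance.tsv`, model checkpoints,
#' and `manifest.json` (config hash + seeds) to the results directory.
#'
#' @param config path to a YAML file or a named list.
#' @return the performance data.frame, invisibly; results on disk.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(experiment_defaults(), config)
  target <- required_field(cfg, "target_tf")
  out_dir <- required_field(cfg, "out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$world)) {
    wc <- do.call(world_config, cfg$world)
    world <- generate_world(wc)
    bm_sparse <- world$matrices$sparse
    bm_less <- world$matrices$less_sparse
    seqs <- world$sequences
    bm_table <- world$binding_modes
  } else {
    bm_sparse <- read_binding_matrix(required_field(cfg, "sparse_matrix"))
    bm_less <- read_binding_matrix(required_field(cfg, "less_sparse_matrix"))
    fa <- Biostrings::readDNAStringSet(required_field(cfg, "sequences_fasta"))
    seqs <- setNames(as.character(fa), names(fa))
    bm_table <- read_binding_modes(required_field(cfg, "binding_modes"))
  }

  sel <- switch(cfg$strategy,
    same_bm = select_same_bm(target, rownames(bm_sparse$values), bm_table,
                             k = cfg$k, include_target = cfg$include_target,
                             seed = cfg$seeds[1]),
    cofactor = select_cofactors(target, bm_sparse, bm_table, k = cfg$k,
                                include_target = cfg$include_target),
    noncofactor_same_bm = select_noncofactors_same_bm(
      target, bm_sparse, bm_table, k = cfg$k,
      include_target = cfg$include_target),
    random_diff_bm = select_random_diff_bm(
      target, rownames(bm_sparse$values), bm_table, k = cfg$k,
      include_target = cfg$include_target, seed = cfg$seeds[1]),
    stop("experiment config: unknown strategy '", cfg$strategy, "'"))

  # fine-tuning dataset first, so pre-training can exclude its regions
  st <- extract_single_task(bm_sparse, target, seqs)
  unb <- gc_matched_downsample(st$bound, st$unbound,
                               seed = derive_seed(cfg$seeds[1], 1))
  single <- rbind(cbind(st$bound, label = 1L), cbind(unb, label = 0L))
  if (!is.null(cfg$single_n))
    single <- fix_dataset_size(single, cfg$single_n,
                               seed = derive_seed(cfg$seeds[1], 2))
  multi <- extract_multi_task(bm_less, sel$members, seqs,
                              exclude_regions = single$region_id)
  if (!is.null(cfg$multi_n))
    multi <- fix_dataset_size(multi, cfg$multi_n,
                              seed = derive_seed(cfg$seeds[1], 3))

  pre_cfg <- train_config(learning_rate = cfg$learning_rate,
                          batch_size = cfg$batch_size,
                          max_epochs = cfg$max_epochs,
                          patience = cfg$patience, seed = cfg$seeds[1])
  mspec <- model_spec(cfg$architecture, n_outputs = length(sel$members),
                      seed = cfg$seeds[1])
  msplit <- split_dataset(multi, seed = cfg$seeds[1])
  multi_model <- pretrain_multi(mspec, msplit, pre_cfg)
  save_model(multi_model, file.path(out_dir, "multi_model"),
             provenance = list(stage = "pretrain", tfs = sel$members))

  records <- list()
  for (seed in cfg$seeds) {
    ssplit <- split_dataset(single, seed = seed)
    ft_cfg <- train_config(learning_rate = cfg$finetune_learning_rate,
                           batch_size = cfg$batch_size,
                           max_epochs = cfg$max_epochs,
                           patience = cfg$patience, seed = seed)
    tl0 <- transfer_weights(multi_model,
                            model_spec(cfg$architecture, n_outputs = 1L,
                                       seed = seed),
                            mode = cfg$transfer_mode)
    tl <- finetune(tl0, ssplit, ft_cfg, freeze = cfg$freeze,
                   pretrain_regions = attr(multi_model, "train_regions"))
    sc_cfg <- train_config(learning_rate = cfg$learning_rate,
                           batch_size = cfg$batch_size,
                           max_epochs = cfg$max_epochs,
                           patience = cfg$patience, seed = seed)
    scratch <- train_model(build_model(model_spec(cfg$architecture,
                                                  n_outputs = 1L,
                                                  seed = seed)),
                           ssplit, sc_cfg)
    records <- c(records, list(
      list(tf = target, condition = "tl", seed = seed,
           aucpr = evaluate_model(tl, ssplit$test)),
      list(tf = target, condition = "scratch", seed = seed,
           aucpr = evaluate_model(scratch, ssplit$test))))
  }
  perf <- performance_table(records)
  utils::write.table(perf, file.path(out_dir, "performance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "world")],
         world = cfg$world, config_hash = config_hash(cfg),
         pretrain_set = sel$members, strategy = sel$strategy,
         seeds = cfg$seeds, n_multi_regions = nrow(multi),
         n_single_regions = nrow(single)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(perf)
}
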