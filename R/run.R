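# Configuration-driven entry points: reproducible training/evaluation runs
# with logging, checkpoints and a manifest.  Thin Rscript wrappers around
# these functions live under inst/scripts/.

#' @importFrom stats setNames
#' @importFrom utils packageVersion
NULL

.task_registry <- list(
  xor = list(
    network = function(cfg) build_xor_network(),
    dataset = function(cfg) make_xor_dataset(),
    schedule = function(cfg) training_schedule(
      schedule_stage(steps = cfg$steps %||% 32L,
                     spikes = cfg$spikes %||% 1024L,
                     gamma = cfg$gamma %||% 0.025))),
  parity_split = list(
    network = function(cfg) build_parity_network(split = TRUE),
    dataset = function(cfg) make_parity_dataset(split = TRUE),
    schedule = function(cfg) .parity_schedule(cfg)),
  parity_unsplit = list(
    network = function(cfg) build_parity_network(split = FALSE),
    dataset = function(cfg) make_parity_dataset(split = FALSE),
    schedule = function(cfg) .parity_schedule(cfg)),
  toy_conv = list(
    network = function(cfg) build_toy_conv_network(),
    dataset = function(cfg) make_toy_conv_task(
      n_per_class = cfg$n_per_class %||% 10L,
      noise = cfg$noise %||% 0),
    schedule = function(cfg) training_schedule(
      schedule_stage(steps = cfg$steps %||% 60L,
                     spikes = cfg$spikes %||% 200L,
                     gamma = cfg$gamma %||% 0.05))))

`%||%` <- function(a, b) if (is.null(a)) b else a

# four-stage spike/gamma protocol of the parity task: 7000 steps per stage,
# spikes halving 1024 -> 128 across stages, gamma halving within each stage
.parity_schedule <- function(cfg) {
  steps <- cfg$steps %||% 7000L
  stages <- cfg$stages %||% c("A", "B", "C", "D")
  spikes <- c(A = 1024L, B = 512L, C = 256L, D = 128L)
  do.call(training_schedule, lapply(stages, function(s) {
    schedule_stage(steps = steps, spikes = spikes[[s]],
                   gamma = gamma_halving(cfg$gamma0 %||% 0.03,
                                         cfg$gamma_every %||% 1000L),
                   name = s)
  }))
}

#' Save a weight checkpoint
#'
#' Writes all weight groups plus metadata (shapes, trainability, seed,
#' stage) to a single serialized container.
#'
#' @param net An `sbs_network`.
#' @param path Output file.
#' @param meta Optional named list of metadata.
#' @return `path`, invisibly.
#' @export
save_weights <- function(net, path, meta = list()) {
  saveRDS(list(weights = net$weights, trainable = net$trainable,
               shapes = lapply(net$weights, dim), meta = meta), path)
  invisible(path)
}

#' Load a weight checkpoint into a network
#'
#' @param net An `sbs_network` with matching architecture.
#' @param path Checkpoint written by [save_weights()].
#' @return The network with the stored weights.
#' @export
load_weights <- function(net, path) {
  ck <- readRDS(path)
  for (g in names(net$weights)) {
    if (is.null(ck$weights[[g]])) stop("checkpoint misses group: ", g)
    if (!all(dim(ck$weights[[g]]) == dim(net$weights[[g]]))) {
      stop("checkpoint shape mismatch in group: ", g)
    }
    net$weights[[g]] <- ck$weights[[g]]
  }
  net
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$task) || !config$task %in% names(.task_registry)) {
    stop("config must name a task: ",
         paste(names(.task_registry), collapse = ", "))
  }
  config
}

#' Run a configured training job
#'
#' Builds the configured task and network, seeds the RNG, trains with
#' [train_simple()], and writes a line-delimited JSON training log, a final
#' weight checkpoint and a manifest into the output directory (created if
#' missing).
#'
#' @param config Path to a YAML config or an equivalent named list.
#'   Fields: `task` (one of `xor`, `parity_split`, `parity_unsplit`,
#'   `toy_conv`), `seed`, `out`, optional `steps`, `spikes`, `gamma`,
#'   `retarded`, and task-specific fields.
#' @param seed Overrides `config$seed`.
#' @param out Overrides `config$out` (output directory).
#' @return Invisibly, list with `net`, `log` and the output paths.
#' @export
run_train <- function(config, seed = NULL, out = NULL) {
  cfg <- .load_config(config)
  seed <- seed %||% cfg$seed %||% 1L
  out <- out %||% cfg$out %||% stop("config must give an output directory")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  task <- .task_registry[[cfg$task]]

  set.seed(seed)
  net <- task$network(cfg)
  dataset <- task$dataset(cfg)
  schedule <- task$schedule(cfg)
  fit <- train_simple(net, dataset, schedule,
                      retarded = cfg$retarded %||% TRUE)

  log_path <- file.path(out, "train_log.jsonl")
  con <- file(log_path, "w")
  for (i in seq_len(nrow(fit$log))) {
    writeLines(jsonlite::toJSON(as.list(fit$log[i, ]), auto_unbox = TRUE),
               con)
  }
  close(con)
  wt_path <- file.path(out, "weights.rds")
  save_weights(fit$net, wt_path, meta = list(task = cfg$task, seed = seed))
  manifest <- list(task = cfg$task, seed = seed,
                   config = cfg[setdiff(names(cfg), c("out"))],
                   package = "sbsnet",
                   version = as.character(packageVersion("sbsnet")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(net = fit$net, log = fit$log,
                 paths = list(log = log_path, weights = wt_path)))
}

#' Evaluate a trained network
#'
#' Loads a weight checkpoint into the configured task's network and
#' measures the classification error at a given spike budget.
#'
#' @param config Path to a YAML config or a named list (needs `task`).
#' @param weights Path to a checkpoint from [save_weights()], or `NULL` to
#'   evaluate the freshly initialized network.
#' @param spikes Spikes per pattern (default 1024).
#' @param seed RNG seed for the evaluation simulations.
#' @return List with `error`, `predicted` and `truth`.
#' @export
run_eval <- function(config, weights = NULL, spikes = 1024L, seed = 1L) {
  cfg <- .load_config(config)
  task <- .task_registry[[cfg$task]]
  set.seed(seed)
  net <- task$network(cfg)
  dataset <- task$dataset(cfg)
  if (!is.null(weights)) net <- load_weights(net, weights)
  evaluate_network(net, dataset, spikes = spikes)
}
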