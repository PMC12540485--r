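# End-to-end orchestration: simulate (optional) -> cluster -> emotions ->
# graph -> embed -> train -> evaluate, with one config, one seed fanned out
# to per-stage seeds, and every artifact written under a run directory.

#' Default pipeline configuration
#'
#' Nested list with one section per stage. Amend fields and pass to
#' [run_pipeline()]; the same structure is accepted from a YAML file via
#' [read_pipeline_config()]. Stage problem sizes are desk-scale defaults;
#' see the package vignette for what each parameter means.
#'
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_areas = 20L, n_users = 200L, area_sigma = 150,
                    seq_len_range = c(10L, 51L), stickiness = 0.8,
                    quadrant_mix = c(0.45, 0.127, 0.139, 0.284),
                    gap_lognormal = c(log(24), 1.2), boundary_noise = 0),
    cluster = list(n_areas = 20L, bandwidth = 500, noise_quantile = 0.01),
    emotions = list(mean = FALSE),
    graph = list(alpha = 10),
    embed = list(dim = 64L, order = "both", n_samples = 1e5,
                 n_negative = 5L, lr = 0.025, batch_size = 128L),
    train = list(epochs = 25L, batch_size = 128L, lr = 1e-3, n_heads = 4L,
                 lstm_hidden = 64L, fc_hidden = 256L, dropout = 0.2,
                 max_seq_len = 20L, val_fraction = 0.2, use_attention = TRUE,
                 joint_head = TRUE, weight_decay = 0, n_models = 2L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- default_pipeline_config()
  merge2 <- function(d, u) {
    for (k in names(u))
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]])) merge2(d[[k]], u[[k]]) else u[[k]]
    d
  }
  cfg <- merge2(def, user)
  if (!is.null(user$input) && is.null(user$simulate)) cfg$simulate <- NULL
  cfg
}

#' Run the full location-emotion pipeline
#'
#' Executes simulate (when no `input` CSV is configured), stay-area
#' clustering, emotion labelling, interaction-graph construction, vertex
#' embedding, predictor training and evaluation. Every stage receives a
#' seed derived deterministically from the global seed, so a rerun with the
#' same config and seed reproduces `metrics.json` exactly. All stage
#' artifacts are written under `out_dir`.
#'
#' @param config Config list (see [default_pipeline_config()]); may contain
#'   `input` (a check-in CSV path) instead of a `simulate` section.
#' @param out_dir Run directory (created if missing).
#' @param seed Overrides `config$seed` when given.
#' @return Invisible list: `metrics`, `model`, `world` (when simulated),
#'   `graph`, `embedding`, `areas`, plus file paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("emotraj_run_"), seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) .stopf("config must carry a seed")
  if (is.null(config$input) && is.null(config$simulate))
    .stopf("config needs either an 'input' CSV or a 'simulate' section")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_hash <- .hash_string(as.character(cfg_json))
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(force(expr), error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    logf("stage %-9s done in %.1fs", name, proc.time()[3] - t0)
    out
  }
  writeLines(as.character(cfg_json), file.path(out_dir, "config.json"))
  logf("run config hash %s seed %d", cfg_hash, config$seed)

  world <- NULL
  if (is.null(config$input)) {
    world <- stage("simulate", {
      sw <- config$simulate
      do.call(simulate_world, c(sw, list(seed = .derive_seed(config$seed, "world"))))
    })
    sim <- stage("users", simulate_users(world, seed = .derive_seed(config$seed, "users")))
    checkins <- sim$checkins
    write_checkins(checkins, file.path(out_dir, "checkins.csv"))
    utils::write.table(sim$truth, file.path(out_dir, "truth_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    checkins <- stage("read", read_checkins(config$input))
    sim <- NULL
  }

  clu <- stage("cluster", cluster_stay_areas(
    checkins, n_areas = config$cluster$n_areas,
    bandwidth = config$cluster$bandwidth,
    noise_quantile = config$cluster$noise_quantile))
  write_stay_areas(clu$areas, file.path(out_dir, "areas.geojson"))
  utils::write.table(
    data.frame(checkin_index = seq_along(clu$assignments) - 1L,
               area_id = ifelse(is.na(clu$assignments), -1L, clu$assignments)),
    file.path(out_dir, "assignments.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  checkins <- stage("emotions", label_checkins(checkins, mean = isTRUE(config$emotions$mean)))
  utils::write.table(
    data.frame(checkin_index = seq_len(nrow(checkins)) - 1L,
               x = checkins$x, y = checkins$y, quadrant = checkins$quadrant),
    file.path(out_dir, "labeled.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  trajs <- stage("graph", build_trajectories(checkins, clu$assignments))
  graph <- build_graph(trajs, alpha = config$graph$alpha)
  write_edge_list(graph, file.path(out_dir, "edges.tsv"))

  emb <- stage("embed", line_embed(
    graph, dim = config$embed$dim, order = config$embed$order,
    n_samples = config$embed$n_samples, n_negative = config$embed$n_negative,
    lr = config$embed$lr, batch_size = config$embed$batch_size,
    seed = .derive_seed(config$seed, "embed")))
  write_embedding(emb, file.path(out_dir, "embedding.tsv"))

  tc <- config$train
  samples <- make_training_samples(trajs, emb, max_len = tc$max_seq_len)
  users <- vapply(samples, `[[`, "", "user_id")
  set.seed(.derive_seed(config$seed, "split"))
  uids <- unique(users)
  # held-out test users, plus a small train-side selection split that picks
  # the best epoch (never touches the test users)
  val_u <- sample(uids, max(1L, round((tc$val_fraction %||% 0.2) * length(uids))))
  rest <- setdiff(uids, val_u)
  sel_u <- sample(rest, max(1L, round(0.1 * length(rest))))
  is_val <- users %in% val_u
  is_sel <- users %in% sel_u
  n_models <- tc$n_models %||% 1L
  models <- stage("train", lapply(seq_len(n_models), function(k)
    fit_emotion_model(
      samples[!is_val & !is_sel], epochs = tc$epochs,
      batch_size = tc$batch_size, lr = tc$lr, n_heads = tc$n_heads,
      lstm_hidden = tc$lstm_hidden, fc_hidden = tc$fc_hidden,
      dropout = tc$dropout, max_seq_len = tc$max_seq_len,
      val_samples = samples[is_sel],
      use_attention = isTRUE(tc$use_attention),
      joint_head = isTRUE(tc$joint_head),
      weight_decay = tc$weight_decay %||% 0, keep_best = TRUE,
      seed = .derive_seed(config$seed, paste0("train", k)))))
  model <- models[[1L]]
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  metrics <- stage("evaluate", evaluate_model(models, samples[is_val]))
  metrics$n_parameters <- model$n_parameters
  metrics$n_train <- sum(!is_val)
  metrics$config_hash <- cfg_hash
  metrics$seed <- config$seed
  if (!is.null(world)) {
    metrics$bayes_rate <- bayes_rate(world)
    if (!is.null(sim)) {
      truth_lab <- sim$truth$area_id
      assigned <- clu$assignments
      metrics$clustering_ari <- .adjusted_rand(
        ifelse(is.na(assigned), -1L, assigned), truth_lab)
    }
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  logf("joint accuracy %.4f", metrics$joint_accuracy)
  invisible(list(metrics = metrics, model = model, models = models, world = world,
                 graph = graph, embedding = emb, areas = clu$areas,
                 assignments = clu$assignments, samples = samples,
                 is_val = is_val, out_dir = out_dir))
}

# Adjusted Rand index between two labelings (chance-corrected pair
# agreement); kept internal, used to score stay-area recovery.
.adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  ((sij - exp_idx) / (0.5 * (si + sj) - exp_idx))
}
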