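#' Desk-scale end-to-end training study
#'
#' The package's standard small-compute experiment: generate seeded
#' synthetic pen scenes at the tiny preset's 160 px input, estimate anchors
#' from the training labels, train the requested ablation arms from scratch
#' on one CPU core, and evaluate each on a held-out set. This is the
#' experiment the package's acceptance checks and reproduction script run;
#' with the defaults (100 training scenes, 20 test scenes, 30 epochs) one
#' arm trains in a few minutes.
#'
#' @param seed Master seed for scene generation, anchor estimation,
#'   initialization and training order.
#' @param n_train,n_test Scenes per split; defaults 100 and 20.
#' @param epochs Training epochs per arm; default 30.
#' @param arms Ablation arms to train; default `c("sa_fc", "plain")`.
#' @param image_size Scene/network input side; default 160 (the tiny preset).
#' @param verbose Print per-epoch loss lines.
#' @return List with `reports` (a `metrics_report` per arm), `history`
#'   (per-arm loss history), `anchors`, and `comparison` (the cross-arm
#'   table when more than one arm ran).
#' @export
run_smoke_study <- function(seed = 0L, n_train = 100, n_test = 20,
                            epochs = 30, arms = c("sa_fc", "plain"),
                            image_size = 160, verbose = FALSE) {
  sc <- scene_config(image_size = image_size)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  scene_seeds <- sample.int(2^31 - 2, n_train + n_test)
  train_s <- lapply(scene_seeds[seq_len(n_train)],
                    function(s) render_scene(sc, s))
  test_s <- lapply(scene_seeds[n_train + seq_len(n_test)],
                   function(s) render_scene(sc, s))

  wh <- do.call(rbind, lapply(train_s, function(s)
    cbind(s$boxes$w * image_size, s$boxes$h * image_size)))
  anchors <- kmeans_anchors(wh, k = 3, scales = 3, seed = seed)
  cfg <- tiny_config(anchors = anchors)

  reports <- list(); history <- list()
  for (arm in arms) {
    rc <- run_config(epochs = epochs, batch_size = 1, lr = 0.01, arm = arm,
                     augment = FALSE, warmup_epochs = 3,
                     seed = seed %% 2147480000L)
    fit <- train_detector(rc, train_s, cfg, verbose = verbose)
    reports[[arm]] <- evaluate_model(fit$model, test_s)
    history[[arm]] <- fit$history
  }
  out <- list(reports = reports, history = history, anchors = anchors,
              n_train = n_train, n_test = n_test, epochs = epochs)
  if (length(arms) > 1)
    out$comparison <- comparison_table(reports, baseline = utils::tail(arms, 1))
  out
}
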