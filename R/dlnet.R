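#' Architecture specification of the compact 3-D convolutional classifier
#'
#' Each of `n_blocks` blocks applies `convs_per_block` repetitions of
#' [3x3x3 convolution (stride 1, same padding) -> batch norm -> ReLU]
#' followed by 2x2x2 max pooling; the filter count at block *b* is
#' `min(base_filters * 2^(b-1), max_filters)` (16, 32, 64, 128 by default).
#' A 1x1x1 convolution with `head_channels` channels plus ReLU summarises
#' the channel features in place of stacked fully connected layers, and a
#' single-unit dense layer with sigmoid activation produces the impairment
#' probability.
#'
#' @param input_edge Cubic input edge in voxels; must be divisible by
#'   `2^n_blocks` (default 96; the phantom experiments use 32).
#' @param n_blocks Number of conv+pool blocks.
#' @param base_filters,max_filters Filter schedule bounds.
#' @param convs_per_block Convolutions per block.
#' @param head_channels Channels of the 1x1x1 head (0 ablates the head and
#'   connects the dense layer directly to the last pooled feature map).
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input_edge = 96L, n_blocks = 4L, base_filters = 16L,
                         max_filters = 128L, convs_per_block = 1L,
                         head_channels = 64L) {
  input_edge <- as.integer(input_edge)
  n_blocks <- as.integer(n_blocks)
  if (input_edge %% (2^n_blocks) != 0L) {
    stop_petriage(sprintf("input_edge %d is not divisible by 2^%d.", input_edge, n_blocks),
                  "petriage_spec_error")
  }
  if (convs_per_block < 1L) {
    stop_petriage("`convs_per_block` must be >= 1.", "petriage_spec_error")
  }
  filters <- pmin(base_filters * 2^(seq_len(n_blocks) - 1), max_filters)
  final_edge <- input_edge / 2^n_blocks
  h <- as.integer(head_channels)
  structure(
    list(input_edge = input_edge, n_blocks = n_blocks,
         base_filters = as.integer(base_filters),
         max_filters = as.integer(max_filters),
         convs_per_block = as.integer(convs_per_block),
         head_channels = h,
         filters = as.integer(filters),
         final_edge = as.integer(final_edge),
         feat_len = as.integer(final_edge^3 * (if (h > 0) h else filters[n_blocks]))),
    class = "network_spec"
  )
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.001, binary cross-entropy, mini-batch size 4, early stopping when the
#' best *training* loss has not improved by at least `early_stop_min_delta`
#' for `early_stop_patience` consecutive epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param early_stop_min_delta Minimum loss improvement that resets the
#'   early-stopping counter.
#' @param early_stop_patience Epochs without such an improvement before
#'   stopping.
#' @param max_epochs Hard epoch cap.
#' @param seed Seed driving weight initialisation and shuffling.
#' @param decision_threshold Probability cut for the impaired label
#'   (`>=` convention).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 4L,
                         early_stop_min_delta = 0.01, early_stop_patience = 10L,
                         max_epochs = 100L, seed = 1L,
                         decision_threshold = 0.5) {
  for (nm in c("learning_rate", "batch_size", "early_stop_min_delta",
               "early_stop_patience", "max_epochs")) {
    assert_scalar_number(get(nm), nm, min = .Machine$double.eps)
  }
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop_petriage("`decision_threshold` must lie strictly in (0, 1).",
                  "petriage_parameter_error")
  }
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         early_stop_min_delta = early_stop_min_delta,
         early_stop_patience = as.integer(early_stop_patience),
         max_epochs = as.integer(max_epochs), seed = as.integer(seed),
         decision_threshold = decision_threshold),
    class = "train_config"
  )
}

.network_geometry <- function(spec) {
  edges <- spec$input_edge / 2^(seq_len(spec$n_blocks) - 1)
  list(
    n_blocks = spec$n_blocks,
    convs_per_block = spec$convs_per_block,
    head_channels = spec$head_channels,
    feat_len = spec$feat_len,
    filters = spec$filters,
    edges = as.integer(edges)
  )
}

# Flat parameter list (see src/cnn.cpp for the layout contract).
.init_params <- function(spec, seed) {
  with_seed(seed, {
    params <- list()
    stats <- list()
    cin <- 1L
    for (b in seq_len(spec$n_blocks)) {
      f <- spec$filters[b]
      for (j in seq_len(spec$convs_per_block)) {
        fan_in <- 27L * cin
        params[[sprintf("W%d_%d", b, j)]] <-
          matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f)
        params[[sprintf("b%d_%d", b, j)]] <- matrix(0, 1, f)
        params[[sprintf("gamma%d_%d", b, j)]] <- matrix(1, 1, f)
        params[[sprintf("beta%d_%d", b, j)]] <- matrix(0, 1, f)
        stats[[sprintf("rm%d_%d", b, j)]] <- matrix(0, 1, f)
        stats[[sprintf("rv%d_%d", b, j)]] <- matrix(1, 1, f)
        cin <- f
      }
    }
    if (spec$head_channels > 0) {
      params[["W_head"]] <- matrix(
        stats::rnorm(cin * spec$head_channels, 0, sqrt(2 / cin)), cin, spec$head_channels
      )
      params[["b_head"]] <- matrix(0, 1, spec$head_channels)
    }
    params[["w_dense"]] <- matrix(
      stats::rnorm(spec$feat_len, 0, sqrt(1 / spec$feat_len)), spec$feat_len, 1
    )
    params[["b_dense"]] <- matrix(0, 1, 1)
    list(params = params, run_stats = stats)
  })
}

#' Build an (untrained) network handle
#'
#' Instantiates the layer geometry and seed-deterministic He-initialised
#' weights. The handle is a plain R object; [nn_train()] fits it,
#' [nn_predict()] applies it.
#'
#' @param spec A [network_spec()].
#' @param seed Seed for the initial weights (re-drawn from the training
#'   configuration's seed inside [nn_train()]).
#' @return Object of class `cnn_model`.
#' @export
build_network <- function(spec = network_spec(), seed = 0L) {
  init <- .init_params(spec, seed)
  structure(
    list(spec = spec, geometry = .network_geometry(spec),
         params = init$params, run_stats = init$run_stats,
         trained = FALSE, history = NULL, config = NULL),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %d^3, %d blocks (filters %s), head %d, %s, %s parameters\n",
              x$spec$input_edge, x$spec$n_blocks,
              paste(x$spec$filters, collapse = "/"), x$spec$head_channels,
              if (x$trained) "trained" else "untrained",
              format(count_parameters(x$spec), big.mark = ",")))
  invisible(x)
}

#' Closed-form trainable parameter count
#'
#' Per 3x3x3 convolution `F_out * (27 * F_in + 1)` weights-plus-bias and
#' `2 * F_out` trainable batch-norm parameters; `H * (F_last + 1)` for the
#' 1x1x1 head; `final_edge^3 * H + 1` for the dense output.
#'
#' @param spec A [network_spec()].
#' @return Integer count (with a per-layer breakdown in attribute
#'   `"breakdown"`).
#' @export
count_parameters <- function(spec) {
  rows <- list()
  cin <- 1L
  for (b in seq_len(spec$n_blocks)) {
    f <- spec$filters[b]
    for (j in seq_len(spec$convs_per_block)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = sprintf("conv%d_%d", b, j), params = f * (27 * cin + 1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = sprintf("bn%d_%d", b, j), params = 2 * f)
      cin <- f
    }
  }
  if (spec$head_channels > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = "head", params = spec$head_channels * (cin + 1))
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(layer = "dense", params = spec$feat_len + 1)
  breakdown <- dplyr::bind_rows(rows)
  structure(sum(breakdown$params), breakdown = breakdown)
}

# Trainable parameters actually held by a model handle.
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Early-stopping rule on a loss history
#'
#' Returns the 1-based epoch at which training stops: the first epoch where
#' the best loss so far has failed to improve by at least `min_delta` for
#' `patience` consecutive epochs (NA if the rule never fires).
#'
#' @param losses Numeric vector of per-epoch training losses.
#' @param min_delta,patience Early-stopping parameters.
#' @export
early_stop_epoch <- function(losses, min_delta = 0.01, patience = 10L) {
  best <- Inf
  stall <- 0L
  for (i in seq_along(losses)) {
    if (losses[i] <= best - min_delta || !is.finite(best)) {
      best <- losses[i]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) return(i)
    }
  }
  NA_integer_
}

# Coerce supported volume inputs to a voxel-by-sample double matrix.
.volumes_to_matrix <- function(volumes, input_edge) {
  V <- as.integer(input_edge)^3
  if (is.matrix(volumes)) {
    x <- volumes
  } else if (is.list(volumes)) {
    cols <- lapply(volumes, function(v) {
      d <- if (inherits(v, "brain_volume")) v$data else v
      if (length(d) != V) {
        stop_petriage(
          sprintf("volume has %d voxels but the network expects %d (%d^3).",
                  length(d), V, input_edge),
          "petriage_input_error"
        )
      }
      as.numeric(d)
    })
    x <- matrix(unlist(cols), nrow = V)
  } else {
    stop_petriage("`volumes` must be a list of volumes or a voxel-by-sample matrix.",
                  "petriage_input_error")
  }
  if (nrow(x) != V) {
    stop_petriage(sprintf("volumes have %d voxels but the network expects %d (%d^3).",
                          nrow(x), V, input_edge),
                  "petriage_input_error")
  }
  x
}

.coerce_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "impaired")
  } else {
    as.integer(labels)
  }
}

#' Train the classifier on labelled volumes
#'
#' Mini-batch Adam on binary cross-entropy; all randomness (weight
#' initialisation and per-epoch shuffling) derives from `config$seed`.
#' Training stops at `max_epochs` or by the early-stopping rule on the
#' training loss. A validation set, when given, is only monitored (its loss
#' is recorded per epoch), never used for stopping.
#'
#' @param model A [build_network()] handle.
#' @param volumes List of [brain_volume()]/arrays, or a voxel-by-sample
#'   matrix.
#' @param labels Binary labels (1/`"impaired"` = positive).
#' @param config A [train_config()].
#' @param validation Optional list `list(volumes =, labels =)` to monitor.
#' @return The trained model, with `history` (tibble of per-epoch losses).
#' @export
nn_train <- function(model, volumes, labels, config = train_config(),
                     validation = NULL) {
  x <- .volumes_to_matrix(volumes, model$spec$input_edge)
  y <- .coerce_labels(labels)
  if (length(y) != ncol(x)) {
    stop_petriage("labels and volumes lengths differ.", "petriage_input_error")
  }
  if (length(unique(y)) < 2L) {
    stop_petriage("training requires both classes present.", "petriage_training_error")
  }
  xv <- NULL; yv <- NULL
  if (!is.null(validation)) {
    xv <- .volumes_to_matrix(validation$volumes, model$spec$input_edge)
    yv <- .coerce_labels(validation$labels)
  }

  init <- .init_params(model$spec, config$seed)
  params <- init$params
  run_stats <- init$run_stats
  adam_m <- lapply(params, function(p) array(0, dim(p)))
  adam_v <- lapply(params, function(p) array(0, dim(p)))
  geom <- model$geometry
  n <- ncol(x)

  orders <- with_seed(config$seed + 1L, {
    lapply(seq_len(config$max_epochs), function(e) sample.int(n))
  })

  losses <- numeric(0)
  val_losses <- numeric(0)
  adam_t <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    st <- cnn_epoch_cpp(params, adam_m, adam_v, run_stats, geom, x, y,
                        orders[[epoch]], config$learning_rate,
                        config$batch_size, adam_t, 0.1)
    params <- st$params; adam_m <- st$adam_m; adam_v <- st$adam_v
    run_stats <- st$run_stats; adam_t <- st$adam_t
    losses <- c(losses, st$loss)
    if (!is.null(xv)) {
      pv <- cnn_infer_cpp(params, run_stats, geom, xv, FALSE, 16L)$prob
      pv <- clip(pv, 1e-7, 1 - 1e-7)
      val_losses <- c(val_losses, -mean(yv * log(pv) + (1 - yv) * log(1 - pv)))
    }
    stop_at <- early_stop_epoch(losses, config$early_stop_min_delta,
                                config$early_stop_patience)
    if (!is.na(stop_at)) break
  }

  model$params <- params
  model$run_stats <- run_stats
  model$trained <- TRUE
  model$config <- config
  model$history <- tibble::tibble(
    epoch = seq_along(losses),
    train_loss = losses,
    val_loss = if (is.null(xv)) NA_real_ else val_losses
  )
  model
}

#' Predict impairment probabilities
#'
#' Evaluation-mode forward pass (batch normalisation uses running
#' statistics), so predictions are order-preserving and independent of how
#' volumes are batched.
#'
#' @param model A `cnn_model` (trained or freshly built).
#' @param volumes Volumes as in [nn_train()].
#' @param batch_size Inference batch size (no effect on values).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
nn_predict <- function(model, volumes, batch_size = 16L) {
  x <- .volumes_to_matrix(volumes, model$spec$input_edge)
  cnn_infer_cpp(model$params, model$run_stats, model$geometry, x, FALSE,
                as.integer(batch_size))$prob
}

#' Extract the last flatten-layer features
#'
#' Per-volume feature vector of length `final_edge^3 * head_channels`,
#' taken immediately before the dense output layer (after the 1x1x1 head
#' and its ReLU).
#'
#' @inheritParams nn_predict
#' @return Matrix, one row per volume.
#' @export
extract_features <- function(model, volumes, batch_size = 16L) {
  x <- .volumes_to_matrix(volumes, model$spec$input_edge)
  t(cnn_infer_cpp(model$params, model$run_stats, model$geometry, x, TRUE,
                  as.integer(batch_size))$features)
}

#' Diagnose uncertain cases with a trained model
#'
#' Applies the trained classifier to the uncertain samples' volumes:
#' label `impaired` iff probability >= `threshold` (boundary inclusive).
#'
#' @param model A *trained* `cnn_model`.
#' @param volumes Volumes of the uncertain samples.
#' @param threshold Decision threshold (default from the training config).
#' @param ids Optional sample identifiers.
#' @return Tibble with `id`, `diagnosis` and `diagnosis_prob`.
#' @export
diagnose_uncertain <- function(model, volumes, threshold = NULL, ids = NULL) {
  if (!isTRUE(model$trained)) {
    stop_petriage("model has not been trained; fit it on certain cases first.",
                  "petriage_state_error")
  }
  threshold <- threshold %||% model$config$decision_threshold %||% 0.5
  prob <- nn_predict(model, volumes)
  ids <- ids %||% names(volumes) %||% sprintf("V%04d", seq_along(prob))
  tibble::tibble(
    id = ids,
    diagnosis = ifelse(prob >= threshold, "impaired", "healthy"),
    diagnosis_prob = prob
  )
}
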