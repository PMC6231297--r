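# The small tri-planar patch CNN.
#
# Architecture (input 32x32x3):
#   conv 5x5 pad 2 (32 maps) -> ReLU -> max pool 3x3/2 -> LRN
#   conv 5x5 pad 2 (32 maps) -> ReLU -> avg pool 3x3/2 -> LRN
#   conv 5x5 pad 2 (64 maps) -> ReLU -> avg pool 3x3/2
#   flatten (64 x 4 x 4 = 1024) -> fully connected (2) -> softmax
# Spatial trace 32 -> 16 -> 8 -> 4. The 1024-long flattened last-pool
# output is the deep feature vector of a patch. Training is mini-batch SGD
# with momentum and weight decay: v <- m*v - eta*(g + lambda*theta),
# theta <- theta + v.

#' CNN configuration
#'
#' Defaults follow the published training recipe: 5x5 kernels with 2-pixel
#' padding, 3x3 stride-2 pooling (max, then average twice), LRN after the
#' first two pooling stages, momentum 0.9, learning rate 0.001, weight
#' decay 0.0001, 30 epochs, mini-batches of 151 patches. The second-stage
#' channel count and the LRN constants are not pinned down by the
#' architecture figure; the classic 32/32/64 small-image stack and
#' conventional LRN defaults are used and exposed here.
#'
#' @param channels Feature maps per conv stage (length 3).
#' @param conv_kernel Conv kernel size (odd; padding `(k-1)/2` keeps the
#'   spatial size).
#' @param pool_kernel,pool_stride Pooling window and stride.
#' @param pool_types Pooling type per stage (`"max"`/`"avg"`).
#' @param lrn_size,lrn_alpha,lrn_beta,lrn_k LRN window (channels) and
#'   constants; applied after pooling stages 1 and 2.
#' @param momentum,learning_rate,weight_decay,epochs,batch_size SGD
#'   hyperparameters.
#' @param input_size,input_channels Patch geometry (32x32, 3 channels).
#' @param seed Seed controlling weight initialization and batch shuffling.
#' @return List of class `cnn_config`; `$feature_dim` gives the flattened
#'   last-pool width (1024 at the defaults).
#' @export
cnn_config <- function(channels = c(32, 32, 64),
                       conv_kernel = 5, pool_kernel = 3, pool_stride = 2,
                       pool_types = c("max", "avg", "avg"),
                       lrn_size = 3, lrn_alpha = 5e-5, lrn_beta = 0.75, lrn_k = 1,
                       momentum = 0.9, learning_rate = 0.001,
                       weight_decay = 1e-4, epochs = 30, batch_size = 151,
                       input_size = 32, input_channels = 3, seed = 1) {
  if (length(channels) != 3 || any(channels < 1))
    stop("channels must give three positive feature-map counts")
  if (conv_kernel %% 2 != 1)
    stop("conv_kernel must be odd so same-padding preserves the spatial size")
  if (batch_size < 1) stop("batch_size must be >= 1")
  sizes <- input_size
  s <- input_size
  for (stage in 1:3) {
    s <- pool_out_size(s, as.integer(pool_kernel), as.integer(pool_stride))
    if (s < 1) stop("pooling trace collapses below 1x1 at stage ", stage)
    sizes <- c(sizes, s)
  }
  cfg <- list(channels = as.integer(channels),
              conv_kernel = as.integer(conv_kernel),
              pool_kernel = as.integer(pool_kernel),
              pool_stride = as.integer(pool_stride),
              pool_types = pool_types,
              lrn_size = as.integer(lrn_size), lrn_alpha = lrn_alpha,
              lrn_beta = lrn_beta, lrn_k = lrn_k,
              momentum = momentum, learning_rate = learning_rate,
              weight_decay = weight_decay, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              input_size = as.integer(input_size),
              input_channels = as.integer(input_channels),
              seed = as.integer(seed),
              spatial_trace = as.integer(sizes),
              feature_dim = as.integer(channels[3] * s * s))
  structure(cfg, class = "cnn_config")
}

#' Build an (untrained) CNN
#'
#' Allocates seed-controlled Gaussian weights (He scaling, sd =
#' sqrt(2/fan-in)) for the three conv stages and the 2-unit classification
#' head.
#'
#' @param cfg A [cnn_config()].
#' @return Object of class `cnn_model` with `$params`, `$config`,
#'   `$feature_dim` and an empty training history.
#' @export
build_cnn <- function(cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  k <- cfg$conv_kernel
  cin <- c(cfg$input_channels, cfg$channels[1], cfg$channels[2])
  set.seed(cfg$seed)
  params <- list()
  for (stage in 1:3) {
    fan_in <- k * k * cin[stage]
    params[[paste0("W", stage)]] <-
      array(stats::rnorm(k * k * cin[stage] * cfg$channels[stage],
                         sd = sqrt(2 / fan_in)),
            c(k, k, cin[stage], cfg$channels[stage]))
    params[[paste0("b", stage)]] <- numeric(cfg$channels[stage])
  }
  params$Wfc <- matrix(stats::rnorm(cfg$feature_dim * 2,
                                    sd = sqrt(2 / cfg$feature_dim)),
                       cfg$feature_dim, 2)
  params$bfc <- numeric(2)
  velocity <- lapply(params, function(p) { p[] <- 0; p })
  structure(list(config = cfg, params = params, velocity = velocity,
                 feature_dim = cfg$feature_dim, trained = FALSE,
                 n_updates = 0L, history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat("<cnn_model>", paste(cfg$channels, collapse = "/"),
      "maps, spatial trace", paste(cfg$spatial_trace, collapse = "->"),
      ", feature_dim", x$feature_dim,
      if (x$trained) sprintf("(trained, %d updates)", x$n_updates)
      else "(untrained)", "\n")
  invisible(x)
}

# Stack a list of patch25d arrays into the layer-input matrix
# ((S*S*B) x channels), spatial index fastest, then sample.
patches_to_input <- function(patches) {
  B <- length(patches)
  if (B == 0) stop("empty patch list")
  S2 <- PATCH_SIZE * PATCH_SIZE
  X <- vapply(patches, as.numeric, numeric(S2 * 3L))
  dim(X) <- c(S2, 3L, B)
  X <- aperm(X, c(1, 3, 2))
  dim(X) <- c(S2 * B, 3L)
  X
}

# Full forward pass. X: ((S*S*B) x input_channels). Returns logits, probs,
# flattened last-pool features, and (optionally) the backprop cache.
cnn_forward <- function(params, cfg, X, B, keep_cache = FALSE) {
  tr <- cfg$spatial_trace
  cache <- if (keep_cache) list() else NULL
  A <- X
  for (stage in 1:3) {
    s_in <- tr[stage]
    cv <- conv_forward(A, s_in, s_in, B,
                       params[[paste0("W", stage)]], params[[paste0("b", stage)]])
    rl <- relu_forward(cv$out)
    pl <- pool_forward(rl$out, s_in, s_in, B, cfg$pool_types[stage],
                       cfg$pool_kernel, cfg$pool_stride)
    A <- pl$out
    ln <- NULL
    if (stage < 3) {
      ln <- lrn_forward(A, cfg$lrn_size, cfg$lrn_alpha, cfg$lrn_beta, cfg$lrn_k)
      A <- ln$out
    }
    if (keep_cache)
      cache[[stage]] <- list(conv = cv$cache, relu = rl$cache,
                             pool = pl$cache, lrn = if (is.null(ln)) NULL else ln$cache)
  }
  S <- tr[4]^2
  feats <- flatten_forward(A, S, B, cfg$channels[3])
  fc <- fc_forward(feats, params$Wfc, params$bfc)
  list(logits = fc$out, probs = softmax_probs(fc$out), feats = feats,
       cache = cache, fc_cache = fc$cache)
}

# Loss + gradients for one mini-batch (labels01 in {0,1}).
cnn_loss_grad <- function(params, cfg, X, labels01, B) {
  fwd <- cnn_forward(params, cfg, X, B, keep_cache = TRUE)
  sm <- softmax_xent(fwd$logits, labels01)
  grads <- list()
  fcb <- fc_backward(sm$dLogits, params$Wfc, fwd$fc_cache)
  grads$Wfc <- fcb$dW; grads$bfc <- fcb$db
  tr <- cfg$spatial_trace
  dA <- flatten_backward(fcb$dF, tr[4]^2, B, cfg$channels[3])
  for (stage in 3:1) {
    st <- fwd$cache[[stage]]
    if (!is.null(st$lrn)) dA <- lrn_backward(dA, st$lrn)
    dA <- pool_backward(dA, st$pool)
    dA <- relu_backward(dA, st$relu)
    cb <- conv_backward(dA, params[[paste0("W", stage)]], st$conv)
    grads[[paste0("W", stage)]] <- cb$dW
    grads[[paste0("b", stage)]] <- cb$db
    dA <- cb$dA
  }
  acc <- mean((fwd$probs[, 2] >= fwd$probs[, 1]) == (labels01 == 1))
  list(loss = sm$loss, grads = grads, accuracy = acc)
}

#' Split patches into mini-batches
#'
#' Random equal-size split used by [train_cnn()]: with `n = 62967` patches
#' and the default batch size 151 this yields 417 mini-batches of 151.
#'
#' @param n Number of patches.
#' @param batch_size Patches per batch (last batch may be smaller when
#'   `batch_size` does not divide `n`).
#' @param seed Integer seed for the shuffle.
#' @return List of integer index vectors partitioning `1:n`.
#' @export
make_minibatches <- function(n, batch_size = 151, seed = 1) {
  if (n < 1) stop("no patches to batch")
  set.seed(seed)
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train the CNN on labeled patches
#'
#' Mini-batch stochastic gradient descent with momentum and weight decay:
#' `v <- momentum*v - lr*(grad + wd*theta)`, `theta <- theta + v`. Patches
#' are reshuffled globally each epoch (seed-controlled), so a given seed
#' reproduces the run exactly. Patch labels are inherited from the
#' subject's group: 1 for the positive class (AD, or MCI converter), 0
#' otherwise.
#'
#' @param model A [build_cnn()] model.
#' @param patches List of `patch25d` arrays.
#' @param labels Numeric/integer vector in \{0, 1\}, one per patch.
#' @param epochs,batch_size Optional overrides of the model's config.
#' @param verbose Print one line per epoch.
#' @return Trained `cnn_model`; `$history` holds per-epoch mean loss and
#'   training-patch accuracy.
#' @export
train_cnn <- function(model, patches, labels, epochs = NULL,
                      batch_size = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(batch_size)) batch_size <- cfg$batch_size
  n <- length(patches)
  if (n == 0) stop("empty training set")
  if (length(labels) != n) stop("one label per patch is required")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) stop("training set contains a single class")
  if (epochs == 0) return(model)

  Xall <- patches_to_input(patches)
  S2 <- cfg$input_size^2
  params <- model$params; velocity <- model$velocity
  m <- cfg$momentum; eta <- cfg$learning_rate; lam <- cfg$weight_decay
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  n_updates <- model$n_updates
  for (ep in seq_len(epochs)) {
    batches <- make_minibatches(n, batch_size, seed = cfg$seed + ep)
    ep_loss <- 0; ep_acc <- 0
    for (idx in batches) {
      B <- length(idx)
      rows <- rep((idx - 1L) * S2, each = S2) + seq_len(S2)
      lg <- cnn_loss_grad(params, cfg, Xall[rows, , drop = FALSE],
                          labels[idx], B)
      for (nm in names(params)) {
        velocity[[nm]] <- m * velocity[[nm]] -
          eta * (lg$grads[[nm]] + lam * params[[nm]])
        params[[nm]] <- params[[nm]] + velocity[[nm]]
      }
      n_updates <- n_updates + 1L
      ep_loss <- ep_loss + lg$loss * B
      ep_acc <- ep_acc + lg$accuracy * B
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n,
                                         accuracy = ep_acc / n))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, train acc %.3f",
                      ep, ep_loss / n, ep_acc / n))
  }
  model$params <- params
  model$velocity <- velocity
  model$trained <- TRUE
  model$n_updates <- n_updates
  model$history <- rbind(model$history, history)
  model
}

#' Extract deep features from patches
#'
#' Runs the forward pass and returns the flattened last-pool output: one
#' row of 1024 features per patch. With 151 patches per image this yields
#' 1024 x 151 = 154624 deep feature values per subject. Extraction from an
#' untrained model is permitted (a message is emitted) since the features
#' are still well defined.
#'
#' @param model A `cnn_model`.
#' @param patches List of `patch25d` arrays.
#' @param chunk_size Patches per forward pass (memory control).
#' @return Numeric matrix (patches x `feature_dim`), row names = the
#'   patches' subject ids.
#' @export
extract_cnn_features <- function(model, patches, chunk_size = 512) {
  stopifnot(inherits(model, "cnn_model"))
  if (length(patches) == 0) stop("empty patch list")
  if (!model$trained)
    message("extracting features from an untrained CNN")
  n <- length(patches)
  out <- matrix(0, n, model$feature_dim)
  S2 <- model$config$input_size^2
  for (start in seq(1, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, n)
    X <- patches_to_input(patches[idx])
    out[idx, ] <- cnn_forward(model$params, model$config, X,
                              length(idx))$feats
  }
  rownames(out) <- vapply(patches, function(p) {
    id <- attr(p, "subject_id"); if (is.null(id)) "" else id
  }, character(1))
  out
}

#' Classify a subject by majority patch vote
#'
#' Each patch gets the argmax of the CNN's softmax; the subject label is
#' the majority of patch decisions, with ties broken toward the positive
#' class (151 patches being odd, ties cannot occur at the default count).
#'
#' @param model A trained `cnn_model`.
#' @param patches The subject's patches (list of `patch25d`).
#' @return Integer label: 1 (positive: AD / converter) or 0.
#' @export
classify_subject_by_patch_vote <- function(model, patches) {
  stopifnot(inherits(model, "cnn_model"))
  if (length(patches) == 0) stop("no patches to vote on")
  X <- patches_to_input(patches)
  probs <- cnn_forward(model$params, model$config, X, length(patches))$probs
  votes <- as.integer(probs[, 2] >= probs[, 1])   # patch tie -> positive
  as.integer(sum(votes) >= length(votes) / 2)     # subject tie -> positive
}
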