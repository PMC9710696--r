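# Feature-extraction CNN, built directly on BLAS matrix products.
#
# Activations are stored as C x (P*B) matrices, block-major: the columns of
# sample b occupy (b-1)*P + 1..P. A stride-1 "same" convolution with filter
# width d is computed as a sum of d shifted matrix products
#   Out = sum_t W[, , t] %*% Xpad[, idx_t],
# which keeps every FLOP inside dgemm. Each of the eight modules is
# convolution -> batch normalization -> rectified linear unit -> max pooling;
# the classifier head is global average pooling + a fully connected layer
# trained with softmax cross-entropy. Style extraction reads the post-ReLU,
# pre-pooling activations and never touches the fully connected layer.

CHECKPOINT_FORMAT <- "stylebin_checkpoint"
CHECKPOINT_VERSION <- 1L

#' Configuration of the feature-extraction CNN
#'
#' Eight modules of (convolution, batch norm, ReLU, max pool) followed by
#' global average pooling and a fully connected classifier. Defaults: 64
#' filters per module, filter widths (8, 4, 4, 4, 4, 4, 4, 4) — the 8 bp
#' first-layer filters act as position-weight-matrix motif detectors — and
#' 2x max pooling per module, which reduces 1024 input positions to 4 before
#' pooling globally.
#'
#' @param n_classes Number of species classes (>= 2).
#' @param n_filters Filters per module; scalar or length-8 vector.
#' @param filter_sizes Filter widths, length-8 vector.
#' @param pool_sizes Max-pooling widths, length-8 vector (1 = no pooling).
#' @param input_length Input window length in bp (default 1024).
#' @param seed Seed for weight initialization.
#' @return An object of class `feature_cnn_config`.
#' @export
feature_cnn_config <- function(n_classes, n_filters = 64L,
                               filter_sizes = c(8L, 4L, 4L, 4L, 4L, 4L, 4L, 4L),
                               pool_sizes = rep(2L, 8L),
                               input_length = 1024L, seed = 1L) {
  stopifnot(n_classes >= 2L, input_length >= 1L)
  n_filters <- rep_len(as.integer(n_filters), 8L)
  filter_sizes <- rep_len(as.integer(filter_sizes), 8L)
  pool_sizes <- rep_len(as.integer(pool_sizes), 8L)
  stopifnot(all(n_filters >= 1L), all(filter_sizes >= 1L),
            all(pool_sizes >= 1L))
  P <- as.integer(input_length)
  spatial <- integer(8L)
  for (l in 1:8) {
    if (P < 1L || P %% pool_sizes[l] != 0L) {
      stop("configuration error: spatial size ", P, " at module ", l,
           " is not divisible by pool size ", pool_sizes[l])
    }
    spatial[l] <- P            # size of the recorded (pre-pool) feature maps
    P <- P %/% pool_sizes[l]
    if (P < 1L) {
      stop("configuration error: spatial size collapses to 0 at module ", l)
    }
  }
  structure(list(n_classes = as.integer(n_classes), n_filters = n_filters,
                 filter_sizes = filter_sizes, pool_sizes = pool_sizes,
                 input_length = as.integer(input_length),
                 map_sizes = spatial, final_spatial = P,
                 seed = as.integer(seed)),
            class = "feature_cnn_config")
}

#' Build an (untrained) feature-extraction CNN
#'
#' He-initialized weights, unit batch-norm scale, zero biases; deterministic
#' given `config$seed`.
#'
#' @param config A [feature_cnn_config()].
#' @return An object of class `feature_cnn`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "feature_cnn_config"))
  with_seed(config$seed, function() {
    layers <- vector("list", 8L)
    C <- 4L
    for (l in 1:8) {
      Fl <- config$n_filters[l]
      d <- config$filter_sizes[l]
      W <- array(rnorm(Fl * C * d, sd = sqrt(2 / (C * d))), dim = c(Fl, C, d))
      layers[[l]] <- list(
        W = W, b = numeric(Fl),
        gamma = rep(1, Fl), beta = numeric(Fl),
        run_mean = numeric(Fl), run_var = rep(1, Fl))
      C <- Fl
    }
    fc <- list(W = matrix(rnorm(config$n_classes * C, sd = sqrt(2 / C)),
                          config$n_classes, C),
               b = numeric(config$n_classes))
    structure(list(config = config, layers = layers, fc = fc,
                   classes = NULL, trained = FALSE),
              class = "feature_cnn")
  })
}

# ---- layer primitives (C++ kernels in src/layers.cpp) ----------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

gap_matrix <- function(P, B) {
  kronecker(diag(B), matrix(1 / P, P, 1L))
}

# ---- forward / backward over the whole network -----------------------------

# X: 4 x (input_length * B) one-hot batch. Returns logits (n_classes x B),
# recorded post-ReLU pre-pool maps, and (if training) caches for backprop.
cnn_forward <- function(model, X, B, training = FALSE,
                        record_layers = integer(0)) {
  cfg <- model$config
  P <- cfg$input_length
  caches <- if (training) vector("list", 8L) else NULL
  maps <- stats::setNames(vector("list", length(record_layers)),
                          as.character(record_layers))
  A <- X
  for (l in 1:8) {
    layer <- model$layers[[l]]
    Z <- conv_fwd_cpp(layer$W, layer$b, A, P, B)
    bn <- bn_relu_fwd_cpp(Z, layer$gamma, layer$beta,
                          layer$run_mean, layer$run_var, BN_EPS, training)
    R <- bn$out
    if (l %in% record_layers) {
      maps[[as.character(l)]] <- array(R, dim = c(nrow(R), P, B))
    }
    s <- cfg$pool_sizes[l]
    if (s > 1L) {
      pl <- pool_fwd_cpp(R, P, B, s)
      A_next <- pl$out
      choice <- pl$choice
    } else {
      A_next <- R
      choice <- NULL
    }
    if (training) {
      caches[[l]] <- list(X = A, bn = bn, R = R, choice = choice, P = P)
    }
    A <- A_next
    P <- P %/% s
  }
  G <- A %*% gap_matrix(P, B)                      # C8 x B pooled features
  logits <- model$fc$W %*% G + model$fc$b
  list(logits = logits, maps = maps, gap = G, caches = caches,
       final_P = P)
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

# Cross-entropy loss and parameter gradients for a one-hot label matrix
# Y (n_classes x B). Returns loss and per-layer gradient list.
cnn_backward <- function(model, fwd, Y, B) {
  cfg <- model$config
  probs <- softmax_cols(fwd$logits)
  loss <- -sum(Y * log(pmax(probs, 1e-12))) / B
  dLogits <- (probs - Y) / B
  gfc <- list(dW = tcrossprod(dLogits, fwd$gap), db = rowSums(dLogits))
  dG <- crossprod(model$fc$W, dLogits)
  dA <- tcrossprod(dG, gap_matrix(fwd$final_P, B))
  grads <- vector("list", 8L)
  for (l in 8:1) {
    cache <- fwd$caches[[l]]
    layer <- model$layers[[l]]
    P <- cache$P
    s <- cfg$pool_sizes[l]
    dR <- if (s > 1L) pool_bwd_cpp(dA, cache$choice, P, B, s) else dA
    bnb <- bn_relu_bwd_cpp(dR, cache$R, cache$bn$xhat, cache$bn$isd,
                           layer$gamma)
    cvb <- conv_bwd_cpp(layer$W, bnb$dZ, cache$X, P, B)
    grads[[l]] <- list(dW = cvb$dW, db = cvb$db,
                       dgamma = bnb$dgamma, dbeta = bnb$dbeta)
    dA <- cvb$dX
  }
  list(loss = loss, grads = grads, fc = gfc)
}

update_running_stats <- function(model, fwd_caches) {
  for (l in 1:8) {
    bn <- fwd_caches[[l]]$bn
    layer <- model$layers[[l]]
    layer$run_mean <- (1 - BN_MOMENTUM) * layer$run_mean + BN_MOMENTUM * bn$mu
    layer$run_var <- (1 - BN_MOMENTUM) * layer$run_var + BN_MOMENTUM * bn$v
    model$layers[[l]] <- layer
  }
  model
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(x) {
    if (is.array(x)) array(0, dim = dim(x)) else numeric(length(x))
  }
  st <- list(t = 0L, layers = lapply(model$layers, function(layer) {
    list(W = list(m = zero_like(layer$W), v = zero_like(layer$W)),
         b = list(m = zero_like(layer$b), v = zero_like(layer$b)),
         gamma = list(m = zero_like(layer$gamma), v = zero_like(layer$gamma)),
         beta = list(m = zero_like(layer$beta), v = zero_like(layer$beta)))
  }))
  st$fc <- list(W = list(m = zero_like(model$fc$W), v = zero_like(model$fc$W)),
                b = list(m = zero_like(model$fc$b), v = zero_like(model$fc$b)))
  st
}

adam_step_one <- function(par, grad, slot, lr, t,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  slot$m <- beta1 * slot$m + (1 - beta1) * grad
  slot$v <- beta2 * slot$v + (1 - beta2) * grad * grad
  mhat <- slot$m / (1 - beta1^t)
  vhat <- slot$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), slot = slot)
}

adam_update <- function(model, state, grads, fc_grads, lr) {
  state$t <- state$t + 1L
  t <- state$t
  for (l in 1:8) {
    layer <- model$layers[[l]]
    sl <- state$layers[[l]]
    for (nm in c("W", "b", "gamma", "beta")) {
      g <- switch(nm, W = grads[[l]]$dW, b = grads[[l]]$db,
                  gamma = grads[[l]]$dgamma, beta = grads[[l]]$dbeta)
      upd <- adam_step_one(layer[[nm]], g, sl[[nm]], lr, t)
      layer[[nm]] <- upd$par
      sl[[nm]] <- upd$slot
    }
    model$layers[[l]] <- layer
    state$layers[[l]] <- sl
  }
  for (nm in c("W", "b")) {
    g <- if (nm == "W") fc_grads$dW else fc_grads$db
    upd <- adam_step_one(model$fc[[nm]], g, state$fc[[nm]], lr, state$t)
    model$fc[[nm]] <- upd$par
    state$fc[[nm]] <- upd$slot
  }
  list(model = model, state = state)
}

# ---- training --------------------------------------------------------------

# Encode a labeled dataset into an integer code matrix (input_length x n,
# right zero-padded) and an integer class vector.
encode_training_data <- function(data, input_length, classes) {
  n <- length(data$sequences)
  codes <- matrix(0L, input_length, n)
  for (i in seq_len(n)) {
    ci <- dna_codes(normalize_dna(data$sequences[[i]]))
    if (length(ci) > input_length) {
      stop("sequence ", names(data$sequences)[i], " is longer (", length(ci),
           " bp) than the model input length (", input_length, " bp)")
    }
    codes[seq_along(ci), i] <- ci
  }
  list(codes = codes, y = match(data$labels, classes))
}

#' Pre-train the feature-extraction CNN on species classification
#'
#' Mini-batch Adam on softmax cross-entropy. A stratified 10% holdout is
#' split off for monitoring; the training log records per-epoch mean
#' training loss and holdout accuracy. With `epochs = 0` the input model is
#' returned unchanged.
#'
#' @param model An (untrained) `feature_cnn` from [build_model()].
#' @param data A `labeled_dataset` with >= 2 classes; sequences at most
#'   `input_length` bp (shorter ones are zero-padded).
#' @param epochs Number of passes over the training split (default 20).
#' @param batch_size Mini-batch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Seed controlling the holdout split and batch shuffling.
#' @param holdout_fraction Fraction per class held out for monitoring.
#' @param verbose Print per-epoch progress to stderr.
#' @return The trained `feature_cnn`; `$training_log` holds a data.frame
#'   (epoch, train_loss, holdout_accuracy) and `$classes` the label set.
#' @export
train_cnn <- function(model, data, epochs = 20L, batch_size = 64L,
                      lr = 1e-3, seed = 1L, holdout_fraction = 0.1,
                      verbose = FALSE) {
  stopifnot(inherits(model, "feature_cnn"), inherits(data, "labeled_dataset"))
  classes <- sort(unique(data$labels))
  if (length(classes) < 2L) {
    stop("training data must contain at least 2 classes, got ",
         length(classes))
  }
  if (length(classes) != model$config$n_classes) {
    stop("dataset has ", length(classes), " classes but the model was ",
         "configured for ", model$config$n_classes)
  }
  if (epochs == 0L) return(model)
  enc <- encode_training_data(data, model$config$input_length, classes)
  n <- ncol(enc$codes)
  with_seed(seed, function() {
    holdout <- unlist(lapply(split(seq_len(n), enc$y), function(idx) {
      k <- max(1L, floor(holdout_fraction * length(idx)))
      sample(idx, k)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(n), holdout)
    state <- adam_init(model)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      holdout_accuracy = numeric(0))
    nc <- model$config$n_classes
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      losses <- numeric(0)
      for (start in seq.int(1L, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        B <- length(idx)
        X <- codes_to_one_hot(enc$codes[, idx, drop = FALSE])
        Y <- matrix(0, nc, B)
        Y[cbind(enc$y[idx], seq_len(B))] <- 1
        fwd <- cnn_forward(model, X, B, training = TRUE)
        model <- update_running_stats(model, fwd$caches)
        bwd <- cnn_backward(model, fwd, Y, B)
        upd <- adam_update(model, state, bwd$grads, bwd$fc, lr)
        model <- upd$model
        state <- upd$state
        losses <- c(losses, bwd$loss)
      }
      acc <- holdout_accuracy(model, enc, holdout, batch_size)
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                   holdout_accuracy = acc))
      if (verbose) {
        message(sprintf("epoch %d: train loss %.4f, holdout accuracy %.3f",
                        ep, mean(losses), acc))
      }
    }
    model$classes <- classes
    model$trained <- TRUE
    model$training_log <- log
    model
  })
}

holdout_accuracy <- function(model, enc, holdout, batch_size) {
  if (!length(holdout)) return(NA_real_)
  correct <- 0L
  for (start in seq.int(1L, length(holdout), by = batch_size)) {
    idx <- holdout[start:min(start + batch_size - 1L, length(holdout))]
    X <- codes_to_one_hot(enc$codes[, idx, drop = FALSE])
    fwd <- cnn_forward(model, X, length(idx), training = FALSE)
    pred <- apply(fwd$logits, 2L, which.max)
    correct <- correct + sum(pred == enc$y[idx])
  }
  correct / length(holdout)
}

#' Extract per-layer feature maps for one window
#'
#' Runs the window through the network in inference mode (batch-norm running
#' statistics) and returns the post-ReLU, pre-pooling activations of every
#' module.
#'
#' @param model A `feature_cnn`.
#' @param window 4 x input_length one-hot matrix.
#' @return Named list `"1"`..`"8"` of Nl x Ml feature-map matrices.
#' @export
extract_feature_maps <- function(model, window) {
  stopifnot(inherits(model, "feature_cnn"))
  if (!is.matrix(window) || nrow(window) != 4L ||
      ncol(window) != model$config$input_length) {
    stop("window must be a 4 x ", model$config$input_length,
         " one-hot matrix, got ", paste(dim(window), collapse = " x "))
  }
  fwd <- cnn_forward(model, window, 1L, training = FALSE, record_layers = 1:8)
  lapply(fwd$maps, function(a) matrix(a, dim(a)[1L], dim(a)[2L]))
}

#' Predict class scores for a batch of windows
#'
#' @param model A `feature_cnn`.
#' @param windows A 4 x (input_length * B) one-hot batch, or a single
#'   4 x input_length window.
#' @return n_classes x B matrix of logits.
#' @export
predict_logits <- function(model, windows) {
  stopifnot(inherits(model, "feature_cnn"))
  L <- model$config$input_length
  stopifnot(is.matrix(windows), nrow(windows) == 4L, ncol(windows) %% L == 0L)
  B <- ncol(windows) %/% L
  cnn_forward(model, windows, B, training = FALSE)$logits
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration alongside all weights and
#' batch-norm running statistics, with a format and version stamp. A round
#' trip reproduces forward outputs bit-identically on the same platform.
#'
#' @param model A `feature_cnn`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "feature_cnn"))
  saveRDS(list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param n_classes Optional expected class count; a mismatch is an error.
#' @export
load_checkpoint <- function(path, n_classes = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupted or unreadable checkpoint: ", path, " (", conditionMessage(e), ")")
  })
  if (!is.list(obj) || !identical(obj$format, CHECKPOINT_FORMAT)) {
    stop("not a stylebin checkpoint: ", path)
  }
  if (!identical(obj$version, CHECKPOINT_VERSION)) {
    stop("checkpoint version mismatch: file has ", obj$version,
         ", this package reads version ", CHECKPOINT_VERSION)
  }
  model <- obj$model
  class(model) <- "feature_cnn"
  class(model$config) <- "feature_cnn_config"
  validate_model(model)
  if (!is.null(n_classes) && model$config$n_classes != n_classes) {
    stop("checkpoint n_classes mismatch: checkpoint has ",
         model$config$n_classes, ", expected ", n_classes)
  }
  model
}

validate_model <- function(model) {
  cfg <- model$config
  C <- 4L
  for (l in 1:8) {
    d <- dim(model$layers[[l]]$W)
    if (!identical(d, c(cfg$n_filters[l], C, cfg$filter_sizes[l]))) {
      stop("weight shape mismatch at module ", l, ": got ",
           paste(d, collapse = " x "), ", expected ",
           paste(c(cfg$n_filters[l], C, cfg$filter_sizes[l]), collapse = " x "))
    }
    C <- cfg$n_filters[l]
  }
  if (!identical(dim(model$fc$W), c(cfg$n_classes, C))) {
    stop("fully connected weight shape mismatch")
  }
  invisible(model)
}

#' @export
print.feature_cnn <- function(x, ...) {
  cfg <- x$config
  cat("Feature-extraction CNN (", if (x$trained) "trained" else "untrained",
      ")\n", sep = "")
  cat("  input: 4 x ", cfg$input_length, " one-hot DNA window\n", sep = "")
  cat("  modules: ", paste(sprintf("%d@%d", cfg$n_filters, cfg$filter_sizes),
                           collapse = " "), "\n", sep = "")
  cat("  classes: ", cfg$n_classes, "\n", sep = "")
  invisible(x)
}
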