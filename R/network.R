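#' Rectified linear unit
#'
#' Activation of every hidden layer: `max(0, z)`, elementwise.
#'
#' @param z numeric vector/matrix of pre-activations.
#' @return same shape as `z`.
#' @export
relu <- function(z) {
  z[z < 0] <- 0
  z
}

#' Numerically stable logistic sigmoid
#'
#' Activation of both output layers: `1 / (1 + exp(-z))`, evaluated via
#' the sign-split form so large `|z|` neither overflows nor underflows to
#' a value outside `[0, 1]`. Satisfies `sigmoid(z) + sigmoid(-z) == 1` to
#' machine precision.
#'
#' @param z numeric vector/matrix.
#' @return values in `[0, 1]`, same shape as `z`.
#' @export
sigmoid <- function(z) {
  out <- z
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Binary cross-entropy averaged over output neurons
#'
#' `-(1/n) * sum(t * log(p) + (1 - t) * log(1 - p))` for predicted
#' probabilities `p` and binary targets `t`. Predictions are clipped to
#' `[eps, 1 - eps]` before the logarithm so a saturated prediction cannot
#' produce an infinite loss; with the default `eps = 1e-12` the loss at a
#' perfect binary fit is ~1e-12 rather than exactly 0.
#'
#' @param predicted probability vector.
#' @param target binary vector of the same length.
#' @param eps clipping bound.
#' @return non-negative scalar.
#' @export
bce_loss <- function(predicted, target, eps = 1e-12) {
  if (length(predicted) != length(target)) {
    stop_format("predicted (%d) and target (%d) lengths differ",
                length(predicted), length(target))
  }
  p <- pmin(pmax(predicted, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# rowwise BCE for an n x d matrix of predictions: per-sample mean over the
# d output neurons
.bce_rows <- function(P, Y, eps = 1e-12) {
  P <- pmin(pmax(P, eps), 1 - eps)
  -rowMeans(Y * log(P) + (1 - Y) * log(1 - P))
}

#' Construct the two-part gait recognition network
#'
#' Architecture: a detection trunk taking the 100-point normalized cycle
#' through six fully connected ReLU hidden layers of 100 units to a
#' 2-neuron sigmoid detection output (normal vs. stroke), and a
#' classification branch taking the trunk's last hidden representation
#' through ten further ReLU hidden layers of 100 units to a 5-neuron
#' sigmoid classification output (stroke, drop foot, circumduction, hip
#' hiking, back knee). `branch_input = "input"` switches the branch to
#' consume the raw cycle instead of the trunk representation.
#'
#' Hidden-layer weights are He-style scaled uniform draws
#' (`U(+-sqrt(6 / fan_in))`, suited to ReLU layers) with zero biases; the
#' two sigmoid output layers start at zero weights so both heads open at
#' probability 0.5 (loss `ln 2`) instead of saturated, which removes the
#' large clipped-log losses an untrained deep trunk otherwise produces.
#' Layer dimensions and total parameter count are asserted at
#' construction.
#'
#' @param n_input input points per cycle (default 100).
#' @param n_hidden units per hidden layer (default 100).
#' @param n_trunk_layers trunk hidden layers (default 6).
#' @param n_cls_layers classification-branch hidden layers (default 10).
#' @param n_det_out,n_cls_out output neurons (defaults 2 and 5).
#' @param branch_input `"trunk"` (default) or `"input"`.
#' @param seed RNG seed for initialization.
#' @return an object of class `gait_network`.
#' @export
init_gait_network <- function(n_input = 100, n_hidden = 100,
                              n_trunk_layers = 6, n_cls_layers = 10,
                              n_det_out = 2, n_cls_out = 5,
                              branch_input = c("trunk", "input"),
                              seed = 0) {
  branch_input <- match.arg(branch_input)
  sizes <- list(n_input = n_input, n_hidden = n_hidden,
                n_trunk_layers = n_trunk_layers,
                n_cls_layers = n_cls_layers,
                n_det_out = n_det_out, n_cls_out = n_cls_out)
  he_layer <- function(d_in, d_out) {
    lim <- sqrt(6 / d_in)
    list(W = matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out),
         b = numeric(d_out))
  }
  zero_layer <- function(d_in, d_out) {
    list(W = matrix(0, d_in, d_out), b = numeric(d_out))
  }
  layers <- local_seed(seed, {
    out <- list()
    d_prev <- n_input
    for (i in seq_len(n_trunk_layers)) {
      out[[sprintf("trunk%d", i)]] <- he_layer(d_prev, n_hidden)
      d_prev <- n_hidden
    }
    out[["det"]] <- zero_layer(n_hidden, n_det_out)
    d_prev <- if (branch_input == "trunk") n_hidden else n_input
    for (i in seq_len(n_cls_layers)) {
      out[[sprintf("cls%d", i)]] <- he_layer(d_prev, n_hidden)
      d_prev <- n_hidden
    }
    out[["cls_out"]] <- zero_layer(n_hidden, n_cls_out)
    out
  })
  net <- structure(list(sizes = sizes, branch_input = branch_input,
                        seed = seed, layers = layers),
                   class = "gait_network")
  stopifnot(n_network_params(net) == .expected_param_count(sizes,
                                                           branch_input))
  net
}

.expected_param_count <- function(s, branch_input) {
  cls_in <- if (branch_input == "trunk") s$n_hidden else s$n_input
  (s$n_input * s$n_hidden + s$n_hidden) +
    (s$n_trunk_layers - 1) * (s$n_hidden^2 + s$n_hidden) +
    (s$n_hidden * s$n_det_out + s$n_det_out) +
    (cls_in * s$n_hidden + s$n_hidden) +
    (s$n_cls_layers - 1) * (s$n_hidden^2 + s$n_hidden) +
    (s$n_hidden * s$n_cls_out + s$n_cls_out)
}

#' Total trainable parameter count of a network
#' @param net a `gait_network`.
#' @return integer count of weights plus biases.
#' @export
n_network_params <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.gait_network <- function(x, ...) {
  s <- x$sizes
  cat(sprintf(
    paste0("<gait_network> %d-point input | trunk %d x %d -> detection %d",
           " | branch (%s) %d x %d -> classification %d | %s parameters\n"),
    s$n_input, s$n_trunk_layers, s$n_hidden, s$n_det_out, x$branch_input,
    s$n_cls_layers, s$n_hidden, s$n_cls_out,
    format(n_network_params(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass of the two-part network
#'
#' Runs a batch of normalized cycles through the trunk and classification
#' branch. In training mode (`dropout_rate > 0` with `training = TRUE`),
#' inverted dropout is applied to the classification branch's hidden
#' activations only: units are kept with probability `1 - dropout_rate`
#' and surviving activations are scaled by `1/keep`, so inference needs no
#' rescaling and uses no masks. Masks are drawn from the current RNG
#' stream unless supplied explicitly (as for gradient checking).
#'
#' @param net a `gait_network`.
#' @param X numeric matrix (n x n_input) or single cycle vector.
#' @param training logical; enables dropout.
#' @param dropout_rate probability of dropping a classification-branch
#'   hidden unit.
#' @param masks optional list of pre-drawn mask matrices (one per
#'   classification hidden layer, entries 0 or `1/keep`).
#' @param keep_cache retain intermediate activations for [backward_pass()].
#' @return list with `det` (n x 2 probabilities), `cls` (n x 5
#'   probabilities), and if requested `cache`.
#' @export
forward_pass <- function(net, X, training = FALSE, dropout_rate = 0,
                         masks = NULL, keep_cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$sizes$n_input) {
    stop_format("input has %d columns, network expects %d",
                ncol(X), net$sizes$n_input)
  }
  if (!all(is.finite(X))) stop_format("network input must be finite")
  n <- nrow(X)
  use_dropout <- training && dropout_rate > 0
  keep <- 1 - dropout_rate
  L <- net$layers
  trunk_Z <- trunk_A <- vector("list", net$sizes$n_trunk_layers)
  A <- X
  for (i in seq_len(net$sizes$n_trunk_layers)) {
    Z <- sweep_add(A %*% L[[sprintf("trunk%d", i)]]$W,
                   L[[sprintf("trunk%d", i)]]$b)
    A <- relu(Z)
    trunk_Z[[i]] <- Z
    trunk_A[[i]] <- A
  }
  det_Z <- sweep_add(A %*% L$det$W, L$det$b)
  det_P <- sigmoid(det_Z)
  cls_in <- if (net$branch_input == "trunk") A else X
  n_cls <- net$sizes$n_cls_layers
  cls_Z <- cls_A <- vector("list", n_cls)
  if (use_dropout && is.null(masks)) {
    masks <- lapply(seq_len(n_cls), function(i) {
      matrix((stats::runif(n * net$sizes$n_hidden) < keep) / keep,
             n, net$sizes$n_hidden)
    })
  }
  A2 <- cls_in
  for (i in seq_len(n_cls)) {
    Z <- sweep_add(A2 %*% L[[sprintf("cls%d", i)]]$W,
                   L[[sprintf("cls%d", i)]]$b)
    A2 <- relu(Z)
    if (!is.null(masks)) A2 <- A2 * masks[[i]]
    cls_Z[[i]] <- Z
    cls_A[[i]] <- A2
  }
  cls_Z_out <- sweep_add(A2 %*% L$cls_out$W, L$cls_out$b)
  cls_P <- sigmoid(cls_Z_out)
  out <- list(det = det_P, cls = cls_P)
  if (keep_cache) {
    out$cache <- list(X = X, trunk_Z = trunk_Z, trunk_A = trunk_A,
                      det_P = det_P, cls_in = cls_in, cls_Z = cls_Z,
                      cls_A = cls_A, cls_P = cls_P, masks = masks)
  }
  out
}

sweep_add <- function(M, b) M + rep(b, each = nrow(M))

#' Joint two-head loss for a batch
#'
#' Per sample: detection binary cross-entropy (mean over the 2 detection
#' neurons) plus, weighted by `cls_weight`, classification binary
#' cross-entropy (mean over the 5 classification neurons); the batch loss
#' is the mean over samples. `cls_weight` implements the optional
#' stroke-only classification loss mode (0 for normal-gait samples).
#'
#' @param net a `gait_network`.
#' @param X input batch.
#' @param Y_det n x 2 binary detection targets.
#' @param Y_cls n x 5 binary classification targets.
#' @param masks optional fixed dropout masks (see [forward_pass()]).
#' @param cls_weight per-sample weight for the classification term
#'   (default 1).
#' @return scalar loss.
#' @export
network_loss <- function(net, X, Y_det, Y_cls, masks = NULL,
                         cls_weight = 1) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  fw <- forward_pass(net, X, training = !is.null(masks), masks = masks)
  w <- rep_len(cls_weight, nrow(X))
  mean(.bce_rows(fw$det, Y_det) + w * .bce_rows(fw$cls, Y_cls))
}

#' Backward pass: exact gradients of the joint loss
#'
#' Computes analytic gradients of [network_loss()] with respect to every
#' weight and bias, for the activations cached by a training-mode
#' [forward_pass()]. The sigmoid + cross-entropy pairing collapses each
#' output delta to `(p - t) / (n_neurons * n_batch)`; classification-head
#' gradients flow through the dropout masks and (for the default trunk
#' branch input) back into the shared trunk.
#'
#' @param net a `gait_network`.
#' @param cache the `cache` element returned by
#'   `forward_pass(..., keep_cache = TRUE)`.
#' @param Y_det,Y_cls binary target matrices.
#' @param cls_weight per-sample classification-loss weight (default 1).
#' @return list of gradients with the same layer structure as
#'   `net$layers`.
#' @export
backward_pass <- function(net, cache, Y_det, Y_cls, cls_weight = 1) {
  L <- net$layers
  n <- nrow(cache$X)
  w <- rep_len(cls_weight, n)
  grads <- list()
  # classification head
  dZ <- (cache$cls_P - Y_cls) * (w / (ncol(Y_cls) * n))
  A_prev <- cache$cls_A[[net$sizes$n_cls_layers]]
  grads$cls_out <- list(W = crossprod(A_prev, dZ), b = colSums(dZ))
  dA <- tcrossprod(dZ, L$cls_out$W)
  for (i in rev(seq_len(net$sizes$n_cls_layers))) {
    if (!is.null(cache$masks)) dA <- dA * cache$masks[[i]]
    dZ <- dA * (cache$cls_Z[[i]] > 0)
    A_prev <- if (i == 1L) cache$cls_in else cache$cls_A[[i - 1L]]
    grads[[sprintf("cls%d", i)]] <- list(W = crossprod(A_prev, dZ),
                                         b = colSums(dZ))
    dA <- tcrossprod(dZ, L[[sprintf("cls%d", i)]]$W)
  }
  d_cls_in <- dA
  # detection head
  dZ <- (cache$det_P - Y_det) / (ncol(Y_det) * n)
  n_trunk <- net$sizes$n_trunk_layers
  grads$det <- list(W = crossprod(cache$trunk_A[[n_trunk]], dZ),
                    b = colSums(dZ))
  dA <- tcrossprod(dZ, L$det$W)
  if (net$branch_input == "trunk") dA <- dA + d_cls_in
  for (i in rev(seq_len(n_trunk))) {
    dZ <- dA * (cache$trunk_Z[[i]] > 0)
    A_prev <- if (i == 1L) cache$X else cache$trunk_A[[i - 1L]]
    grads[[sprintf("trunk%d", i)]] <- list(W = crossprod(A_prev, dZ),
                                           b = colSums(dZ))
    dA <- tcrossprod(dZ, L[[sprintf("trunk%d", i)]]$W)
  }
  grads[names(L)]
}

#' Initialize Adam optimizer state
#'
#' @param net a `gait_network`.
#' @return an `adam_state`: zeroed first/second-moment accumulators
#'   mirroring the layer structure, timestep 0.
#' @export
adam_init <- function(net) {
  zeros <- lapply(net$layers, function(l) {
    list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
  })
  structure(list(m = zeros, v = zeros, t = 0L), class = "adam_state")
}

#' One Adam update step
#'
#' Standard bias-corrected adaptive-moment update applied to every weight
#' and bias: moving averages of the gradient and squared gradient are
#' updated, bias-corrected by `1 - beta^t`, and the parameters moved by
#' `-lr * m_hat / (sqrt(v_hat) + epsilon)`.
#'
#' @param net a `gait_network`.
#' @param grads gradients from [backward_pass()].
#' @param state an `adam_state`.
#' @param lr step size (default 1e-3).
#' @param beta1,beta2 moment decay rates (defaults 0.9, 0.999).
#' @param epsilon numerical stabilizer (default 1e-8).
#' @return list with updated `net` and `state`.
#' @export
adam_step <- function(net, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, epsilon = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[nm]][[p]]
      state$m[[nm]][[p]] <- beta1 * state$m[[nm]][[p]] + (1 - beta1) * g
      state$v[[nm]][[p]] <- beta2 * state$v[[nm]][[p]] + (1 - beta2) * g^2
      net$layers[[nm]][[p]] <- net$layers[[nm]][[p]] -
        lr * (state$m[[nm]][[p]] / bc1) /
          (sqrt(state$v[[nm]][[p]] / bc2) + epsilon)
    }
  }
  list(net = net, state = state)
}

#' Training configuration for the gait network
#'
#' Defaults follow the published protocol: batch size 500, 60 epochs,
#' dropout rate 0.2 on the classification branch's hidden layers, Adam
#' with its published default hyperparameters.
#'
#' @param batch_size samples per weight update.
#' @param epochs passes over the training folds.
#' @param dropout_rate classification-branch dropout probability.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param seed master seed fixing initialization, shuffling and dropout.
#' @param cls_loss_mode `"sg_only"` (default): the classification loss is
#'   restricted to stroke-gait samples, since only those are routed to the
#'   classification part at inference; `"all"`: the classification head
#'   trains on every sample, normal gaits with an all-zero target. The
#'   default avoids the all-zero normal-gait targets back-propagating
#'   through the shared trunk against the detection objective, which
#'   measurably destabilizes detection.
#' @param branch_input passed to [init_gait_network()].
#' @return a `training_config`.
#' @export
training_config <- function(batch_size = 500, epochs = 60,
                            dropout_rate = 0.2, learning_rate = 1e-3,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                            seed = 0,
                            cls_loss_mode = c("sg_only", "all"),
                            branch_input = c("trunk", "input")) {
  cls_loss_mode <- match.arg(cls_loss_mode)
  branch_input <- match.arg(branch_input)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_format("dropout_rate must be in [0, 1), got %g", dropout_rate)
  }
  if (epochs < 1) stop_format("epochs must be >= 1")
  structure(as.list(environment()), class = "training_config")
}

#' Train the two-part network on all folds but one
#'
#' Runs the mini-batch protocol: per epoch, the training-fold cycles are
#' visited once in a seeded shuffled order in batches, each batch's joint
#' loss (detection + classification cross-entropy) is backpropagated, and
#' parameters are updated by Adam. The held-out fold never contributes to
#' any update. The whole trajectory is a deterministic function of
#' (dataset, split, holdout fold, config).
#'
#' @param dataset a [gait_dataset].
#' @param split a `fold_split` from [make_folds()].
#' @param holdout_fold fold id excluded from training.
#' @param config a [training_config()].
#' @return list with `net` (trained `gait_network`), `loss_history`
#'   (mean training loss per epoch), `holdout_fold`, `config`.
#' @export
train_network <- function(dataset, split, holdout_fold,
                          config = training_config()) {
  stopifnot(inherits(split, "fold_split"),
            inherits(config, "training_config"))
  if (!holdout_fold %in% seq_len(split$k)) {
    stop_format("holdout_fold must be in 1..%d", split$k)
  }
  train_idx <- which(split$assignment != holdout_fold)
  if (length(train_idx) == 0L) stop_format("no training samples")
  X <- dataset$cycles[train_idx, , drop = FALSE]
  tg <- target_matrices(dataset)
  Y_det <- tg$detection[train_idx, , drop = FALSE]
  Y_cls <- tg$classification[train_idx, , drop = FALSE]
  cls_w_all <- if (config$cls_loss_mode == "sg_only") {
    as.numeric(dataset$labels$sg[train_idx])
  } else {
    rep(1, length(train_idx))
  }
  n <- nrow(X)
  local_seed(config$seed, {
    net <- init_gait_network(
      n_input = ncol(X),
      branch_input = config$branch_input,
      seed = stats::runif(1, 0, .Machine$integer.max - 1)
    )
    state <- adam_init(net)
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      epoch_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      batch_list <- batches(seq_len(n), config$batch_size,
                            seed = epoch_seed)
      epoch_loss <- 0
      for (b in batch_list) {
        fw <- forward_pass(net, X[b, , drop = FALSE], training = TRUE,
                           dropout_rate = config$dropout_rate,
                           keep_cache = TRUE)
        w <- cls_w_all[b]
        batch_loss <- mean(.bce_rows(fw$det, Y_det[b, , drop = FALSE]) +
                             w * .bce_rows(fw$cls,
                                           Y_cls[b, , drop = FALSE]))
        if (!is.finite(batch_loss)) {
          stop_format("training diverged (non-finite loss) at epoch %d",
                      epoch)
        }
        grads <- backward_pass(net, fw$cache, Y_det[b, , drop = FALSE],
                               Y_cls[b, , drop = FALSE], cls_weight = w)
        upd <- adam_step(net, grads, state, lr = config$learning_rate,
                         beta1 = config$beta1, beta2 = config$beta2,
                         epsilon = config$epsilon)
        net <- upd$net
        state <- upd$state
        epoch_loss <- epoch_loss + batch_loss * length(b)
      }
      loss_history[epoch] <- epoch_loss / n
    }
    list(net = net, loss_history = loss_history,
         holdout_fold = holdout_fold, config = config)
  })
}

#' Predict gait labels for normalized cycles
#'
#' Inference-mode forward pass followed by the gated decision rule: the
#' detection label is the argmax of the two detection probabilities (tie
#' broken to normal gait); only if the detection says stroke are the four
#' abnormality flags read off the classification neurons at the 0.5
#' threshold — a normal-gait decision forces all flags to zero regardless
#' of the classification head.
#'
#' @param net a trained `gait_network`.
#' @param cycles one cycle (vector) or a matrix of cycles (rows).
#' @return list with `labels` (data.frame of the six 0/1 flags),
#'   `detection` (n x 2 probabilities) and `classification` (n x 5
#'   probabilities).
#' @export
predict_gait <- function(net, cycles) {
  fw <- forward_pass(net, cycles, training = FALSE)
  sg <- fw$det[, 2] > fw$det[, 1]
  flags <- (fw$cls[, 2:5, drop = FALSE] > 0.5) & sg
  labels <- data.frame(
    ng = as.integer(!sg), sg = as.integer(sg),
    sgw_df = as.integer(flags[, 1]), sgw_c = as.integer(flags[, 2]),
    sgw_hh = as.integer(flags[, 3]), sgw_bk = as.integer(flags[, 4])
  )
  list(labels = labels, detection = fw$det, classification = fw$cls)
}

#' Save or load trained network parameters
#'
#' The container is a single JSON file: a header with the layer sizes,
#' branch wiring and seed, plus every weight matrix and bias vector at
#' maximum decimal precision (faithful to ~1e-15 relative; the last
#' binary digit of a double may not survive the decimal round trip).
#'
#' @param net a `gait_network`.
#' @param path file path.
#' @return `write_network`: the path, invisibly; `read_network`: a
#'   `gait_network`.
#' @export
write_network <- function(net, path) {
  payload <- list(
    header = list(format = "strokegait-network", version = 1L,
                  sizes = net$sizes, branch_input = net$branch_input,
                  seed = net$seed),
    layers = lapply(net$layers, function(l) {
      list(W = l$W, dim = dim(l$W), b = l$b)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$header$format, "strokegait-network")) {
    stop_format("%s is not a strokegait network file", path)
  }
  layers <- lapply(raw$layers, function(l) {
    list(W = matrix(unlist(l$W), l$dim[1], l$dim[2]), b = as.numeric(l$b))
  })
  structure(list(sizes = as.list(raw$header$sizes),
                 branch_input = raw$header$branch_input,
                 seed = raw$header$seed, layers = layers),
            class = "gait_network")
}
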