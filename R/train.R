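# Binary cross-entropy with logits (numerically stable) and its gradient.
bce_with_logits <- function(logits, labels) {
  n <- length(logits)
  loss <- mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
  grad <- (stats::plogis(logits) - labels) / n
  list(loss = loss, grad = grad)
}

adam_init <- function(state) {
  list(m = zero_like(state), v = zero_like(state), t = 0L)
}

# One Adam step with decoupled-from-bias weight decay: decay is applied to
# matrix-valued leaves (weights, free embeddings) but not to bias vectors,
# layer-norm gains or the scalar beta_dec.
adam_step <- function(state, grads, opt, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (weight_decay > 0) {
    grads <- tree_map2(grads, state, function(g, p)
      if (is.matrix(p)) g + weight_decay * p else g)
  }
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- tree_map2(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  state <- tree_map3(state, opt$m, opt$v, function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(state = state, opt = opt)
}

#' Train the link-prediction model
#'
#' Full-batch optimization of binary cross-entropy on the sigmoid pair
#' scores over the training positives and their fixed 1:1 negatives, with
#' Adam plus weight decay, early stopping on validation AUC and
#' restoration of the best-validation parameters.  Deterministic given
#' `seed` (which governs parameter initialization; the loop itself is
#' deterministic).
#'
#' @param graph the full [hetero_graph()]; the training graph is derived
#'   internally via [build_training_graph()].
#' @param split an `edge_split` from [make_splits()].
#' @param store an [build_instance_store()] built on the *training* graph
#'   covering train and valid pairs; if `NULL` it is built here.
#' @param config an [mda_config()].
#' @param seed initialization seed (default: first of `config$seeds`).
#' @param verbose emit per-epoch progress to stderr.
#' @return List with `state` (best-validation parameters), `log`
#'   (data.frame `epoch`, `loss`, `valid_auc`), `best_epoch`,
#'   `train_graph`, `store`, `config`.
#' @export
train <- function(graph, split, store = NULL, config = mda_config(),
                  seed = NULL, verbose = FALSE) {
  if (nrow(split$pos$train) == 0) stop("empty training split")
  seed <- seed %||% config$seeds[1]
  tg <- build_training_graph(graph, split)
  pr_train <- split_pairs(split, "train")
  pr_valid <- split_pairs(split, "valid")
  if (is.null(store)) {
    store <- build_instance_store(
      tg, pairs = rbind(pr_train[, 1:2], pr_valid[, 1:2]),
      cap = config$cap, seed = seed, target = config$target)
  }
  y_train <- pr_train[, 3]
  des_tr <- build_design(tg, store, pr_train[, 1:2], config)
  has_valid <- nrow(pr_valid) > 0
  if (has_valid) {
    y_valid <- pr_valid[, 3]
    des_va <- build_design(tg, store, pr_valid[, 1:2], config)
  }
  state <- model_init(tg, config, seed)
  opt <- adam_init(state)
  best_auc <- -Inf; best_state <- state; best_epoch <- 0L; wait <- 0L
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    valid_auc = numeric(0))
  for (ep in seq_len(config$epochs)) {
    fw <- model_forward(state, des_tr, config)
    lo <- bce_with_logits(fw$logits, y_train)
    grads <- model_backward(state, des_tr, config, fw, lo$grad)
    st <- adam_step(state, grads, opt, config$lr, config$weight_decay)
    state <- st$state; opt <- st$opt
    va <- NA_real_
    if (has_valid) {
      fv <- model_forward(state, des_va, config, keep_cache = FALSE)
      va <- auc_score(fv$logits, y_valid)
      if (va > best_auc) {
        best_auc <- va; best_state <- state; best_epoch <- ep; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    } else {
      best_state <- state; best_epoch <- ep
    }
    log <- rbind(log, data.frame(epoch = ep, loss = lo$loss, valid_auc = va))
    if (verbose)
      message(sprintf("[seed %d] epoch %3d  loss %.4f  valid AUC %s",
                      seed, ep, lo$loss,
                      ifelse(is.na(va), "-", sprintf("%.4f", va))))
    if (has_valid && wait >= config$patience) break
  }
  list(state = best_state, log = log, best_epoch = best_epoch,
       train_graph = tg, store = store, config = config)
}

#' Evaluate a trained model on labelled pairs
#'
#' @param fit a [train()] result.
#' @param pairs three-column matrix (miRNA index, disease index, label),
#'   e.g. [split_pairs()] output.
#' @return List with the metric set (`auc`, `ap`, `precision`, `recall`,
#'   `f1`, confusion counts), the scored data.frame `scores`, and the
#'   per-pair inter-class weight matrix `beta`.
#' @export
evaluate <- function(fit, pairs) {
  store <- extend_pair_store(fit$store, fit$train_graph,
                             pairs[, 1:2, drop = FALSE])
  sc <- forward_batch(pairs[, 1:2, drop = FALSE], fit$train_graph, store,
                      fit$state, fit$config)
  y <- pairs[, 3]
  prf <- precision_recall_f1(sc$probability, y, fit$config$threshold)
  out <- c(list(auc = auc_score(sc$logit, y),
                ap = ap_score(sc$logit, y)), prf)
  sc$label <- y
  list(metrics = out, scores = sc, beta = attr(sc, "beta"))
}
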