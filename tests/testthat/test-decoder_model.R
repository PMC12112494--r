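# Linear-realizable MLP params: with use_ln = FALSE and slope = 1 the MLP
# computes W_out (W_in x + b_in) + b_out.
lin_mlp <- function(W_in, W_out) {
  list(W_in = W_in, b_in = numeric(nrow(W_in)),
       g = rep(1, nrow(W_in)), b_ln = numeric(nrow(W_in)),
       W_out = W_out, b_out = numeric(nrow(W_out)))
}

test_that("score_pair reduces to the identity configuration", {
  d <- 2
  params <- list(f1 = lin_mlp(diag(d), diag(d)),
                 f2 = lin_mlp(diag(d), diag(d)),
                 f = lin_mlp(diag(d), matrix(1, 1, d)),
                 beta_dec = 0, slope = 1, use_ln = FALSE)
  s <- score_pair("u", "v", c(1, 2), c(3, 4), c(9, 9), params)
  expect_equal(s$logit, 1 * 3 + 2 * 4)   # 11
  params$beta_dec <- 1
  s2 <- score_pair("u", "v", c(1, 2), c(3, 4), c(1, 1), params)
  expect_equal(s2$logit, 13)
  # with beta_dec = 0 the score ignores h_uv entirely
  params$beta_dec <- 0
  withr::with_seed(1, noise <- rnorm(d))
  expect_equal(score_pair("u", "v", c(1, 2), c(3, 4), noise, params)$logit,
               11)
  expect_error(score_pair("u", "v", c(1, 2), c(3, 4), c(1, 2, 3), params),
               "dimension")
  expect_true(s$probability >= 0 && s$probability <= 1)
})

test_that("forward_batch is batch independent and duplicate consistent", {
  g <- pipe_graph(seed = 21)
  split <- make_splits(g, seed = 1)
  tg <- build_training_graph(g, split)
  pairs <- split_pairs(split, "train")[, 1:2]
  cfg <- mda_config(d = 6, d_in = 6, d_k = 3)
  store <- build_instance_store(tg, pairs = pairs, cap = Inf, seed = 1)
  state <- model_init(tg, cfg, seed = 2)
  batch <- forward_batch(pairs, tg, store, state, cfg)
  alone <- forward_batch(pairs[3, , drop = FALSE], tg, store, state, cfg)
  expect_equal(batch$logit[3], alone$logit[1], tolerance = 1e-10)
  dup <- forward_batch(pairs[c(3, 5, 3), ], tg, store, state, cfg)
  expect_equal(dup$logit[1], dup$logit[3], tolerance = 1e-12)
  beta <- attr(batch, "beta")
  expect_equal(dim(beta), c(nrow(pairs), 2L))
  expect_equal(rowSums(beta), rep(1, nrow(pairs)), tolerance = 1e-6)
})

test_that("the full pipeline matches the straight-line single-pair oracle", {
  g <- pipe_graph(seed = 7)   # 30 nodes
  split <- make_splits(g, seed = 1)
  tg <- build_training_graph(g, split)
  pairs <- rbind(split_pairs(split, "train")[, 1:2],
                 split_pairs(split, "test")[, 1:2])
  cfg <- mda_config(d = 5, d_in = 5, d_prime = 5, d_k = 2)
  store <- build_instance_store(tg, pairs = pairs, cap = Inf, seed = 1)
  state <- model_init(tg, cfg, seed = 4)
  got <- forward_batch(pairs, tg, store, state, cfg)
  for (i in c(1, 2, 5, nrow(pairs))) {
    want <- oracle_score(tg, state, cfg,
                         tg$nodes$miRNA[pairs[i, 1]],
                         tg$nodes$disease[pairs[i, 2]])
    expect_equal(got$logit[i], as.numeric(want), tolerance = 1e-5,
                 info = paste("pair", i))
  }
})

test_that("-link ablation equals pinning beta_dec to zero", {
  g <- pipe_graph(seed = 23)
  split <- make_splits(g, seed = 2)
  tg <- build_training_graph(g, split)
  pairs <- split_pairs(split, "train")[, 1:2]
  store <- build_instance_store(tg, pairs = pairs, cap = 16, seed = 1)
  cfg_off <- mda_config(d = 6, d_in = 6, d_k = 3, use_link = FALSE)
  cfg_on <- mda_config(d = 6, d_in = 6, d_k = 3, use_link = TRUE)
  state <- model_init(tg, cfg_on, seed = 5)
  state0 <- state; state0$dec$beta_dec <- 0
  a <- forward_batch(pairs, tg, store, state, cfg_off)
  b <- forward_batch(pairs, tg, store, state0, cfg_on)
  expect_equal(a$logit, b$logit, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences on a toy batch", {
  sg <- mini_bio(seed = 1)
  split <- make_splits(sg$graph, seed = 1)
  tg <- build_training_graph(sg$graph, split)
  pairs <- split_pairs(split, "train")
  cfg <- mda_config(d = 6, d_in = 6, d_k = 3)
  store <- build_instance_store(tg, pairs = pairs[, 1:2], cap = 8, seed = 1)
  des <- hetmda:::build_design(tg, store, pairs[, 1:2], cfg)
  state <- model_init(tg, cfg, seed = 9)
  y <- pairs[, 3]
  fw <- hetmda:::model_forward(state, des, cfg)
  lo <- hetmda:::bce_with_logits(fw$logits, y)
  gr <- hetmda:::model_backward(state, des, cfg, fw, lo$grad)
  lossfn <- function(st)
    hetmda:::bce_with_logits(
      hetmda:::model_forward(st, des, cfg, keep_cache = FALSE)$logits,
      y)$loss
  eps <- 1e-5
  probes <- list(
    list(get = function(s) s$rgcn[[1]]$Wr[["miRNA-mRNA|ab"]],
         set = function(s, v) { s$rgcn[[1]]$Wr[["miRNA-mRNA|ab"]] <- v; s },
         idx = 4),
    list(get = function(s) s$wp_pair[["miRNA-mRNA-disease"]],
         set = function(s, v) { s$wp_pair[["miRNA-mRNA-disease"]] <- v; s },
         idx = 11),
    list(get = function(s) s$inter_p$WK,
         set = function(s, v) { s$inter_p$WK <- v; s },
         idx = 7),
    list(get = function(s) s$dec$f2$W_in,
         set = function(s, v) { s$dec$f2$W_in <- v; s },
         idx = 13),
    list(get = function(s) s$dec$beta_dec,
         set = function(s, v) { s$dec$beta_dec <- v; s },
         idx = 1))
  for (p in probes) {
    v0 <- p$get(state)
    vp <- v0; vp[p$idx] <- vp[p$idx] + eps
    vm <- v0; vm[p$idx] <- vm[p$idx] - eps
    num <- (lossfn(p$set(state, vp)) - lossfn(p$set(state, vm))) / (2 * eps)
    ana <- p$get(gr)[p$idx]
    expect_equal(ana, num, tolerance = 1e-4)
  }
  # every parameter group receives some gradient mass
  expect_gt(hetmda:::tree_sum_sq(gr$proj), 0)
  expect_gt(hetmda:::tree_sum_sq(gr$rgcn), 0)
  expect_gt(hetmda:::tree_sum_sq(gr$wp_node), 0)
  expect_gt(hetmda:::tree_sum_sq(gr$wp_pair), 0)
  expect_gt(hetmda:::tree_sum_sq(gr$inter_m), 0)
  expect_gt(hetmda:::tree_sum_sq(gr$inter_d), 0)
  expect_gt(hetmda:::tree_sum_sq(gr$inter_p), 0)
  expect_gt(hetmda:::tree_sum_sq(gr$dec), 0)
})
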