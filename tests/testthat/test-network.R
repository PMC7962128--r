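test_that("activation functions match their closed forms", {
  expect_identical(relu(-1), 0)
  expect_identical(relu(3), 3)
  expect_identical(relu(0), 0)
  expect_equal(relu(c(-2, 0.5, 7)), c(0, 0.5, 7))

  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(1000), 1)          # no overflow at saturation
  expect_equal(sigmoid(-1000), 0)
  expect_equal(sigmoid(2) + sigmoid(-2), 1, tolerance = 1e-15)
})

test_that("binary cross-entropy matches direct evaluation", {
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-11)
  expect_equal(bce_loss(rep(0.5, 4), c(1, 0, 1, 1)), log(2),
               tolerance = 1e-15)
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -(log(0.9) + log(0.9)) / 2,
               tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), "lengths differ")
})

test_that("network construction asserts the published dimensions", {
  net <- init_gait_network()
  s <- net$sizes
  expect_equal(dim(net$layers$trunk1$W), c(100, 100))
  expect_equal(dim(net$layers$trunk6$W), c(100, 100))
  expect_equal(dim(net$layers$det$W), c(100, 2))
  expect_equal(dim(net$layers$cls10$W), c(100, 100))
  expect_equal(dim(net$layers$cls_out$W), c(100, 5))
  # 6 trunk + 10 classification hidden layers of 100 units plus both heads
  expect_equal(n_network_params(net),
               16 * (100 * 100 + 100) + (100 * 2 + 2) + (100 * 5 + 5))
})

test_that("forward pass is 0.5 at zero weights and deterministic", {
  net <- init_gait_network(seed = 1)
  for (nm in names(net$layers)) {
    net$layers[[nm]]$W[] <- 0
    net$layers[[nm]]$b[] <- 0
  }
  fw <- forward_pass(net, rnorm(100))
  expect_equal(as.numeric(fw$det), c(0.5, 0.5))
  expect_equal(as.numeric(fw$cls), rep(0.5, 5))

  net2 <- init_gait_network(seed = 2)
  x <- rnorm(100, sd = 50)
  expect_identical(forward_pass(net2, x), forward_pass(net2, x))
})

test_that("analytic gradients match central differences on a mini net", {
  net <- randomized_mini_net(seed = 3)
  set.seed(31)
  X <- matrix(rnorm(3 * 8), 3, 8)
  Y_det <- cbind(c(1, 0, 1), c(0, 1, 0))
  Y_cls <- matrix(rbinom(15, 1, 0.5), 3, 5)
  masks <- lapply(1:2, function(i) matrix((runif(18) < 0.8) / 0.8, 3, 6))
  # with dropout masks and a masked-out sample in the classification loss
  worst <- gradient_check_worst(net, X, Y_det, Y_cls, masks = masks,
                                cls_weight = c(1, 1, 0))
  expect_lt(worst, 1e-5)
  # inference path (no masks), all samples weighted
  worst2 <- gradient_check_worst(net, X, Y_det, Y_cls)
  expect_lt(worst2, 1e-5)
})

test_that("gradients respect dropout masks and vanish at a perfect fit", {
  net <- randomized_mini_net(seed = 5)
  set.seed(6)
  x <- rnorm(8)
  # a fully dropped unit in classification layer 1 receives no gradient
  masks <- list(matrix(1 / 0.8, 1, 6), matrix(1 / 0.8, 1, 6))
  masks[[1]][1, 3] <- 0
  fw <- forward_pass(net, x, training = TRUE, masks = masks,
                     keep_cache = TRUE)
  gr <- backward_pass(net, fw$cache, matrix(c(1, 0), 1), matrix(0, 1, 5))
  expect_equal(gr$cls1$W[, 3], rep(0, 6))
  expect_equal(gr$cls1$b[3], 0)

  # saturated perfect fit: all gradients essentially zero
  net2 <- randomized_mini_net(seed = 7)
  net2$layers$det$W[] <- 0; net2$layers$det$b <- c(50, -50)
  net2$layers$cls_out$W[] <- 0; net2$layers$cls_out$b <- rep(-50, 5)
  fw2 <- forward_pass(net2, x, keep_cache = TRUE)
  gr2 <- backward_pass(net2, fw2$cache, matrix(c(1, 0), 1),
                       matrix(0, 1, 5))
  gnorm <- sqrt(sum(unlist(gr2)^2))
  expect_lt(gnorm, 1e-6)
})

test_that("Adam takes a bias-corrected signed first step and is idempotent at zero gradient", {
  net <- randomized_mini_net(seed = 9)
  grads <- lapply(net$layers, function(l) {
    list(W = matrix(rnorm(length(l$W)), nrow(l$W), ncol(l$W)),
         b = rnorm(length(l$b)))
  })
  upd <- adam_step(net, grads, adam_init(net), lr = 1e-3)
  for (nm in names(net$layers)) {
    delta <- upd$net$layers[[nm]]$W - net$layers[[nm]]$W
    expect_equal(delta, -1e-3 * sign(grads[[nm]]$W), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
  expect_equal(upd$state$t, 1L)

  zero_grads <- lapply(net$layers, function(l) {
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))
  })
  upd0 <- adam_step(net, zero_grads, adam_init(net))
  expect_identical(upd0$net$layers, net$layers)
})

test_that("training is deterministic and decreases the loss", {
  ds <- synthesize_cohort(cohort_config(legs = tiny_cohort_legs(25),
                                        seed = 0))
  split <- make_folds(ds, k = 2, seed = 0)
  cfg <- tiny_training_config(epochs = 5, seed = 11)
  a <- train_network(ds, split, 1, cfg)
  b <- train_network(ds, split, 1, cfg)
  expect_identical(a$net$layers, b$net$layers)
  expect_identical(a$loss_history, b$loss_history)
  expect_lt(a$loss_history[5], a$loss_history[1])
})

test_that("a single repeated sample is memorized within the protocol", {
  syn <- synthesize_leg(gait_template(),
                        abnormality_profile(drop_foot = TRUE,
                                            tremor_sd = 15),
                        n_gaits = 3, seed = 1)
  cyc <- normalize_cycle(split_cycles(syn$signal, syn$midswing_indices)[[1]])
  lab <- data.frame(subject = "P", leg = "left", cycle_index = 1:20,
                    ng = 0, sg = 1, sgw_df = 1, sgw_c = 0, sgw_hh = 0,
                    sgw_bk = 0)
  ds <- gait_dataset(matrix(rep(cyc, each = 20), 20, 100), lab)
  split <- structure(list(k = 2L,
                          assignment = rep(c(1L, 2L), 10), seed = 0),
                     class = "fold_split")
  fit <- train_network(ds, split, 2,
                       training_config(batch_size = 10, epochs = 60,
                                       seed = 0))
  tg <- encode_targets(gait_label(ng = 0, sg = 1, sgw_df = 1))
  final_loss <- network_loss(fit$net, cyc, matrix(tg$detection, 1),
                             matrix(tg$classification, 1))
  expect_lt(final_loss, 1e-3)
})

test_that("prediction gates abnormality flags on the detection decision", {
  net <- randomized_mini_net(seed = 13)
  # force detection towards NG and classification heads high
  net$layers$det$W[] <- 0; net$layers$det$b <- c(5, -5)
  net$layers$cls_out$W[] <- 0; net$layers$cls_out$b <- rep(5, 5)
  p_ng <- predict_gait(net, rnorm(8))
  expect_equal(p_ng$labels$ng, 1)
  expect_equal(unlist(p_ng$labels[c("sgw_df", "sgw_c", "sgw_hh",
                                    "sgw_bk")]),
               c(sgw_df = 0, sgw_c = 0, sgw_hh = 0, sgw_bk = 0))

  # detection tie goes to normal gait
  net$layers$det$b <- c(0, 0)
  expect_equal(predict_gait(net, rnorm(8))$labels$ng, 1)

  # stroke decision reads flags off the classification neurons at 0.5
  net$layers$det$b <- c(-5, 5)
  net$layers$cls_out$b <- c(5, 5, -5, 5, -5)
  p_sg <- predict_gait(net, rnorm(8))
  expect_equal(p_sg$labels$sg, 1)
  expect_equal(unlist(p_sg$labels[c("sgw_df", "sgw_c", "sgw_hh",
                                    "sgw_bk")]),
               c(sgw_df = 1, sgw_c = 0, sgw_hh = 1, sgw_bk = 0))
})

test_that("trained networks survive a save/load round trip", {
  net <- init_gait_network(n_input = 12, n_hidden = 5, n_trunk_layers = 2,
                           n_cls_layers = 2, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$layers, net$layers, tolerance = 1e-12)
  x <- rnorm(12)
  expect_equal(forward_pass(back, x), forward_pass(net, x))
})
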