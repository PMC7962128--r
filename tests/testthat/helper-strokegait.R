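# Shared helpers: small cohorts and independent oracles used across tests.

# A miniature cohort (4 legs, tiny gait counts) for fast end-to-end tests.
tiny_cohort_legs <- function(n = 30) {
  data.frame(
    subject = c("P1", "P2", "H1", "H2"),
    leg = c("left", "right", "left", "right"),
    n_gaits = n,
    stroke = c(TRUE, TRUE, FALSE, FALSE),
    sgw_df = c(TRUE, FALSE, FALSE, FALSE),
    sgw_c = c(FALSE, FALSE, FALSE, FALSE),
    sgw_hh = c(FALSE, TRUE, FALSE, FALSE),
    sgw_bk = c(FALSE, FALSE, FALSE, FALSE)
  )
}

tiny_training_config <- function(epochs = 3, ...) {
  training_config(batch_size = 50, epochs = epochs, ...)
}

# Independent linear-interpolation oracle: explicit index arithmetic, no
# call into the package or into approx().
lin_interp_oracle <- function(x, n_out) {
  L <- length(x)
  out <- numeric(n_out)
  for (j in seq_len(n_out)) {
    t <- min((j - 1) * L / n_out, L - 1)
    i0 <- floor(t)
    frac <- t - i0
    out[j] <- (1 - frac) * x[i0 + 1] +
      (if (frac > 0) frac * x[i0 + 2] else 0)
  }
  out
}

# Build a miniature network with random (non-zero) weights everywhere so
# gradient checks also exercise the output layers.
randomized_mini_net <- function(seed = 3) {
  net <- init_gait_network(n_input = 8, n_hidden = 6, n_trunk_layers = 2,
                           n_cls_layers = 2, seed = seed)
  set.seed(seed + 100)
  for (nm in names(net$layers)) {
    net$layers[[nm]]$W[] <- rnorm(length(net$layers[[nm]]$W), 0, 0.5)
    net$layers[[nm]]$b[] <- rnorm(length(net$layers[[nm]]$b), 0, 0.1)
  }
  net
}

# Central-difference gradient check; returns the worst relative error.
gradient_check_worst <- function(net, X, Y_det, Y_cls, masks = NULL,
                                 cls_weight = 1, h = 1e-6) {
  fw <- forward_pass(net, X, training = !is.null(masks), masks = masks,
                     keep_cache = TRUE)
  gr <- backward_pass(net, fw$cache, Y_det, Y_cls, cls_weight = cls_weight)
  worst <- 0
  for (nm in names(net$layers)) {
    for (p in c("W", "b")) {
      g <- gr[[nm]][[p]]
      for (j in seq_along(g)) {
        n2 <- net
        n2$layers[[nm]][[p]][j] <- n2$layers[[nm]][[p]][j] + h
        lp <- network_loss(n2, X, Y_det, Y_cls, masks = masks,
                           cls_weight = cls_weight)
        n2$layers[[nm]][[p]][j] <- n2$layers[[nm]][[p]][j] - 2 * h
        lm <- network_loss(n2, X, Y_det, Y_cls, masks = masks,
                           cls_weight = cls_weight)
        fd <- (lp - lm) / (2 * h)
        worst <- max(worst, abs(fd - g[j]) / max(1e-8, abs(fd) + abs(g[j])))
      }
    }
  }
  worst
}
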