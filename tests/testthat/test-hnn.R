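test_that("network_emit evaluates the MLP exactly", {
  # zero weights: sigma(0) = 0.5
  z <- emission_network(5, 3, W1 = matrix(0, 3, 5), b1 = rep(0, 3),
                        w2 = rep(0, 3), b2 = 0)
  expect_equal(network_emit(z, rep(1, 5)), 0.5)
  # 1 input, 1 hidden: sigma(2 * sigma(1) - 1)
  net <- emission_network(1, 1, W1 = matrix(1, 1, 1), b1 = 0, w2 = 2,
                          b2 = -1)
  expect_equal(network_emit(net, 1), plogis(2 * plogis(1) - 1),
               tolerance = 1e-12)
  expect_equal(network_emit(net, 1), 0.6135163, tolerance = 1e-6)
  # output strictly increasing in the output bias
  outs <- vapply(seq(-1, 1, by = 0.25), function(b2) {
    network_emit(emission_network(1, 1, W1 = matrix(1, 1, 1), b1 = 0,
                                  w2 = 2, b2 = b2), 1)
  }, 0)
  expect_true(all(diff(outs) > 0))
  expect_error(network_emit(net, c(1, 2)), "length")
})

test_that("parameter count and pack/unpack round-trip", {
  set.seed(2)
  net <- emission_network(140, 5)
  expect_length(network_params(net), 140 * 5 + 5 + 5 + 1)
  p <- network_params(net)
  net2 <- network_set_params(net, p)
  expect_identical(network_params(net2), p)
})

test_that("network outputs are clamped into (0, 1)", {
  net <- emission_network(1, 1, W1 = matrix(100, 1, 1), b1 = 0, w2 = 100,
                          b2 = 100)
  expect_lte(network_emit(net, 1), 1 - 1e-6)
  net$w2 <- -100; net$b2 <- -100
  expect_gte(network_emit(net, 1), 1e-6)
})

test_that("constant-output networks factorize the HNN path score", {
  set.seed(19)
  al <- test_alphabet()
  base <- random_tiny_chmm(S = 2, A = 4, n_labels = 1)
  cnet <- emission_network(4 * 3, 1, W1 = matrix(0, 1, 12), b1 = 0,
                           w2 = 0, b2 = plogis(0.3, log.p = FALSE))
  # force output exactly c via zero weights and logit(c) bias
  cnet$b2 <- qlogis(0.3)
  nets <- list(cnet, cnet)
  names(nets) <- base$states
  m <- topology_model(base$states, base$label_map, base$begin, base$trans,
                      emissions = nets, alphabet = al,
                      window = window_spec(1))
  sq <- labeled_sequence("t", "ACGTAC", alphabet = al)
  # transitions sum to 1 from every state: path mass = 1
  expect_equal(forward(m, sq)$loglik, 6 * log(0.3), tolerance = 1e-9)
})

test_that("saturated K=1 networks reproduce CHMM likelihoods and losses", {
  set.seed(23)
  for (rep in 1:10) {
    mc <- random_tiny_chmm()
    nets <- lapply(mc$states,
                   function(s) saturated_table_network(mc$emissions[s, ]))
    names(nets) <- mc$states
    mh <- topology_model(mc$states, mc$label_map, mc$begin, mc$trans,
                         emissions = nets, alphabet = mc$alphabet,
                         window = window_spec(0))
    sq <- random_seq_for(mc, sample(3:8, 1))
    expect_lt(abs(forward(mh, sq)$loglik - forward(mc, sq)$loglik), 1e-4)
    expect_lt(abs(clamped_forward(mh, sq)$loglik -
                    clamped_forward(mc, sq)$loglik), 1e-4)
    expect_lt(abs(cml_loss(mh, sq)$loss - cml_loss(mc, sq)$loss), 2e-4)
  }
})

test_that("HNN trellises match brute-force enumeration with network scores", {
  set.seed(29)
  for (rep in 1:10) {
    m <- random_tiny_hnn(S = sample(2:3, 1), H = 2)
    sq <- random_seq_for(m, sample(2:6, 1))
    E <- emission_scores(m, sq)
    expect_equal(forward(m, sq)$loglik, log(enum_likelihood(m, sq, E = E)),
                 tolerance = 1e-7)
    expect_equal(clamped_forward(m, sq)$loglik,
                 log(enum_likelihood(m, sq, sq$labels, E = E)),
                 tolerance = 1e-7)
  }
})

test_that("error signal vanishes where free and clamped phases coincide", {
  set.seed(31)
  m <- random_tiny_hnn(S = 2)
  m$label_map[] <- "A"  # single label: phases identical
  m$labels <- "A"
  sq <- random_seq_for(m, 5)
  eps <- error_signal(m, sq)
  expect_equal(max(abs(eps)), 0, tolerance = 1e-12)
})

test_that("assembled HNN gradients match central differences of the loss", {
  set.seed(37)
  for (rep in 1:4) {
    m <- random_tiny_hnn(S = sample(2:3, 1), K_left = sample(0:1, 1),
                         H = sample(2:3, 1))
    batch <- replicate(2, random_seq_for(m, sample(3:8, 1)),
                       simplify = FALSE)
    g <- backprop_gradients(m, batch, joint = TRUE)
    ga <- hnntm:::hnn_grad_pack(m, g, TRUE)
    w0 <- hnntm:::hnn_pack(m, TRUE)
    lossfun <- function(w) {
      mm <- hnntm:::hnn_unpack(m, w, TRUE)
      sum(vapply(batch, function(s) cml_loss(mm, s)$loss, 0))
    }
    gn <- numeric_gradient(lossfun, w0)
    expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-4)), 1e-4)
  }
})

test_that("weight decay adds lambda * w to otherwise zero gradients", {
  set.seed(41)
  m <- random_tiny_hnn(S = 2)
  m$label_map[] <- "A"   # zero error signal everywhere
  m$labels <- "A"
  sq <- random_seq_for(m, 4)
  g <- backprop_gradients(m, list(sq), lambda = 0.1, joint = FALSE)
  st <- m$states[1]
  expect_equal(g$networks[[st]]$W1, 0.1 * m$emissions[[st]]$W1,
               tolerance = 1e-10)
  expect_equal(g$networks[[st]]$b2, 0.1 * m$emissions[[st]]$b2,
               tolerance = 1e-10)
})

test_that("batch gradients are additive over sequences", {
  set.seed(43)
  m <- random_tiny_hnn(S = 2)
  s1 <- random_seq_for(m, 5)
  s2 <- random_seq_for(m, 6)
  gb <- backprop_gradients(m, list(s1, s2))
  g1 <- backprop_gradients(m, list(s1))
  g2 <- backprop_gradients(m, list(s2))
  expect_equal(hnntm:::hnn_grad_pack(m, gb, TRUE),
               hnntm:::hnn_grad_pack(m, g1, TRUE) +
                 hnntm:::hnn_grad_pack(m, g2, TRUE), tolerance = 1e-10)
  expect_equal(gb$loss, g1$loss + g2$loss, tolerance = 1e-10)
})

test_that("RPROP follows the sign rules and respects step bounds", {
  st <- rprop_state(1, delta0 = 0.1)
  up1 <- rprop_step(st, 1, 0)      # first step: no history
  expect_equal(up1$w, -0.1)
  up2 <- rprop_step(up1$state, 1, up1$w)  # same sign: step * ea
  expect_equal(up2$state$delta, 0.1 * 1.2)
  expect_equal(up2$w, -0.1 - 0.12)
  up3 <- rprop_step(up2$state, -1, up2$w) # sign flip: step * ed, no move
  expect_equal(up3$state$delta, 0.12 * 0.5)
  expect_equal(up3$w, up2$w)              # iRPROP-: weight held
  # bounds never violated while minimizing a quadratic
  st <- rprop_state(1, delta0 = 0.5, dmax = 1)
  w <- 0
  for (t in 1:200) {
    up <- rprop_step(st, 2 * (w - 3), w)
    w <- up$w; st <- up$state
    expect_true(st$delta >= st$dmin && st$delta <= st$dmax)
  }
})

test_that("RPROP minimizes (w - 3)^2 to 1e-3 within 100 steps", {
  st <- rprop_state(1)
  w <- 0
  for (t in 1:100) {
    up <- rprop_step(st, 2 * (w - 3), w)
    w <- up$w
    st <- up$state
  }
  expect_lt(abs(w - 3), 1e-3)
})

test_that("per-label initialization separates a residue-determined label", {
  # label is a deterministic function of the center residue
  al <- test_alphabet()
  set.seed(47)
  data <- replicate(12, {
    res <- sample(al, 40, replace = TRUE)
    labs <- ifelse(res %in% c("A", "C"), "P", "Q")
    labeled_sequence("d", res, labs, alphabet = al)
  }, simplify = FALSE)
  grammar <- topology_model(
    c("p", "q"), c(p = "P", q = "Q"), c(p = 0.5, q = 0.5),
    matrix(0.5, 2, 2, dimnames = list(c("p", "q"), c("p", "q"))),
    alphabet = al)
  cfg <- train_config(seed = 9, init_epochs = 60)
  m <- init_networks(data, grammar, cfg, hidden = 3,
                     window = window_spec(1))
  W <- do.call(rbind, lapply(data, encode_windows, spec = window_spec(1)))
  labs <- unlist(lapply(data, `[[`, "labels"))
  outP <- hnntm:::network_emit_matrix(m$emissions[["p"]], W)$e
  expect_gt(mean(outP[labs == "P"]), 0.9)
  expect_lt(mean(outP[labs == "Q"]), 0.1)
  # identical config + seed: bitwise identical networks
  m2 <- init_networks(data, grammar, cfg, hidden = 3,
                      window = window_spec(1))
  expect_identical(network_params(m$emissions[["p"]]),
                   network_params(m2$emissions[["p"]]))
  # a label absent from data leaves its network at random init, warns
  grammar3 <- topology_model(
    c("p", "q", "r"), c(p = "P", q = "Q", r = "R"),
    c(p = 0.5, q = 0.5),
    matrix(1 / 3, 3, 3,
           dimnames = list(c("p", "q", "r"), c("p", "q", "r"))),
    alphabet = al)
  expect_warning(
    init_networks(data, grammar3, cfg, hidden = 3,
                  window = window_spec(1)),
    "absent")
})

test_that("joint CML training reduces the loss and early-stops", {
  toy <- toy_topology_model()
  data <- sample_sequences(generator_spec("context", n = 14, seed = 3))
  cfg <- train_config(seed = 3, max_epochs = 25)
  m0 <- init_networks(data, toy, cfg, hidden = 3, window = window_spec(2))
  fit <- train_hnn(m0, data, cfg)
  expect_s3_class(fit, "hnn_fit")
  expect_lte(nrow(fit$log), 25)
  expect_lt(fit$log$train_loss[nrow(fit$log)], fit$log$train_loss[1])
  # returned model is the held-out-minimum snapshot
  expect_equal(fit$best_epoch, fit$log$epoch[which.min(fit$log$holdout_loss)])
  hold_loss <- sum(vapply(fit$holdout, function(j)
    cml_loss(fit$model, data[[j]])$loss, 0))
  expect_equal(hold_loss, min(fit$log$holdout_loss), tolerance = 1e-8)
  # identical seed/config: identical training log
  m0b <- init_networks(data, toy, cfg, hidden = 3, window = window_spec(2))
  fitb <- train_hnn(m0b, data, cfg)
  expect_identical(fit$log, fitb$log)
})

test_that("training refuses grammar-infeasible label sequences", {
  al <- test_alphabet()
  m <- random_tiny_hnn(S = 2)
  bad <- labeled_sequence("bad", "ACGT",
                          c("A", "B", "A", "B"), alphabet = al)
  bad$labels <- c("Z", "Z", "Z", "Z")  # label no state carries
  expect_error(train_hnn(m, list(bad, random_seq_for(m, 5)),
                         train_config(seed = 1)),
               "infeasible.*bad")
})

test_that("HNN model archives round-trip bitwise", {
  set.seed(53)
  m <- random_tiny_hnn(S = 2, H = 3)
  tmp <- withr::local_tempfile(fileext = ".model")
  write_model(m, tmp)
  back <- read_model(tmp)
  for (st in m$states) {
    expect_identical(network_params(back$emissions[[st]]),
                     network_params(m$emissions[[st]]))
  }
  expect_equal(back$trans, m$trans, tolerance = 0)
  # and the file itself is reproducible
  tmp2 <- withr::local_tempfile(fileext = ".model")
  write_model(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})
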