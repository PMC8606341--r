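one_state_model <- function() {
  topology_model("s", c(s = "x"), c(s = 1), matrix(1, 1, 1),
                 emissions = matrix(rep(0.05, 20), 1,
                                    dimnames = list("s", NULL)))
}

test_that("forward matches the closed form for a uniform one-state model", {
  m <- one_state_model()
  sq <- labeled_sequence("t", strrep("A", 10), strrep("x", 10))
  expect_equal(forward(m, sq)$loglik, 10 * log(0.05), tolerance = 1e-12)
  expect_equal(backward(m, sq)$loglik, 10 * log(0.05), tolerance = 1e-12)
  # single state: posterior is identically 1
  expect_equal(state_posteriors(m, sq, "free"),
               matrix(1, 10, 1, dimnames = list(NULL, "s")))
})

test_that("free/clamped forward, backward and posteriors match enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    m <- random_tiny_chmm()
    sq <- random_seq_for(m, L = sample(2:6, 1))
    E <- emission_scores(m, sq)
    f <- forward(m, sq)
    b <- backward(m, sq)
    expect_equal(f$loglik, log(enum_likelihood(m, sq)), tolerance = 1e-9)
    expect_lt(abs(f$loglik - b$loglik), 1e-8)
    cf <- clamped_forward(m, sq)
    cb <- clamped_backward(m, sq)
    expect_equal(cf$loglik, log(enum_likelihood(m, sq, sq$labels)),
                 tolerance = 1e-9)
    expect_lt(abs(cf$loglik - cb$loglik), 1e-8)
    # P(x,y) <= P(x)
    expect_gte(f$loglik - cf$loglik, -1e-9)
    g <- posterior_matrix(f, b)
    expect_equal(rowSums(g), rep(1, length(sq)), tolerance = 1e-9)
    expect_equal(unname(g), enum_state_posteriors(m, sq), tolerance = 1e-8)
    gc <- posterior_matrix(cf, cb)
    expect_equal(unname(gc), enum_state_posteriors(m, sq, sq$labels),
                 tolerance = 1e-8)
    # clamped posterior is zero off the labeled states
    off <- !hnntm:::label_mask(m, sq$labels)
    expect_equal(max(abs(gc[off])), 0)
  }
})

test_that("impossible emissions and labels are flagged, not errors", {
  al <- test_alphabet()
  m <- topology_model(c("a", "b"), c(a = "A", b = "B"), c(a = 1),
                      matrix(c(1, 0, 0, 1), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b"))),
                      emissions = rbind(a = c(0.5, 0.5, 0, 0),
                                        b = c(0, 0, 0.5, 0.5)),
                      alphabet = al)
  # symbol G emits 0 in the only reachable state a
  sq <- labeled_sequence("t", "AG", alphabet = al)
  f <- forward(m, sq)
  expect_false(f$ok)
  expect_identical(f$loglik, -Inf)
  expect_equal(f$blocked_at, 2L)
  # labels demanding the forbidden a -> b transition
  sq2 <- labeled_sequence("t", "AC", c("A", "B"), alphabet = al)
  cf <- clamped_forward(m, sq2)
  expect_false(cf$ok)
  expect_equal(cf$blocked_at, 2L)
  loss <- cml_loss(m, sq2)
  expect_identical(loss$loss, Inf)
  expect_false(loss$ok)
})

test_that("clamped equals free when all states share one label", {
  set.seed(7)
  m <- random_tiny_chmm(n_labels = 1)
  sq <- random_seq_for(m, 5)
  expect_equal(clamped_forward(m, sq)$loglik, forward(m, sq)$loglik,
               tolerance = 1e-12)
  loss <- cml_loss(m, sq)
  expect_equal(loss$loss, 0, tolerance = 1e-10)
})

test_that("cml_loss equals -log P(y|x) from enumeration on tiny models", {
  set.seed(33)
  for (rep in 1:10) {
    m <- random_tiny_chmm()
    sq <- random_seq_for(m, 4)
    loss <- cml_loss(m, sq)
    expect_equal(loss$loss,
                 -log(enum_likelihood(m, sq, sq$labels) /
                        enum_likelihood(m, sq)),
                 tolerance = 1e-9)
  }
})

test_that("one Baum-Welch iteration on a determined path counts frequencies", {
  al <- test_alphabet()
  states <- c("p", "q")
  trans <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                  dimnames = list(states, states))
  m <- topology_model(states, c(p = "P", q = "Q"), c(p = 0.5, q = 0.5),
                      trans,
                      emissions = rbind(p = rep(0.25, 4), q = rep(0.25, 4)),
                      alphabet = al)
  # labels PPQQP pin the unique path p,p,q,q,p
  sq <- labeled_sequence("t", "ACGTA", c("P", "P", "Q", "Q", "P"),
                         alphabet = al)
  fit <- baum_welch_labeled(m, list(sq), max_iter = 1)
  # transitions observed: p->p, p->q, q->q, q->p (one each)
  expect_equal(unname(fit$trans["p", ]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(unname(fit$trans["q", ]), c(0.5, 0.5), tolerance = 1e-9)
  # emissions: state p saw A,C,A; state q saw G,T
  expect_equal(unname(fit$emissions["p", ]), c(2 / 3, 1 / 3, 0, 0),
               tolerance = 1e-8)
  expect_equal(unname(fit$emissions["q", ]), c(0, 0, 0.5, 0.5),
               tolerance = 1e-8)
})

test_that("labeled Baum-Welch increases the joint likelihood monotonically", {
  set.seed(11)
  m <- random_tiny_chmm(S = 3, n_labels = 2)
  data <- replicate(10, random_seq_for(m, sample(4:8, 1)),
                    simplify = FALSE)
  fit <- baum_welch_labeled(m, data, max_iter = 20)
  trace <- attr(fit, "loglik_trace")
  expect_gt(length(trace), 1)
  expect_true(all(diff(trace) > -1e-8))
})

test_that("Baum-Welch recovers generating parameters from sampled data", {
  toy <- toy_topology_model()
  data <- sample_sequences(generator_spec("chmm", n = 150, seed = 42))
  # start EM away from the truth
  start <- toy
  start$trans <- hnntm:::renorm_rows(
    toy$allowed * 1.0, toy$allowed, 1e-10)
  start$emissions[] <- 0.05
  fit <- baum_welch_labeled(start, data)
  expect_lt(max(abs(fit$trans - toy$trans)), 0.02)
  expect_lt(max(abs(fit$emissions - toy$emissions)), 0.02)
})

test_that("transition gradients match central differences and respect zeros", {
  set.seed(55)
  for (rep in 1:5) {
    m <- random_tiny_chmm(S = 3, dense = 0)   # includes structural zeros
    batch <- replicate(3, random_seq_for(m, 5), simplify = FALSE)
    g <- cml_transition_gradients(m, batch)
    expect_equal(unname(g$trans[!m$allowed]),
                 rep(0, sum(!m$allowed)))
    # numeric check through the softmax reparameterization
    zt0 <- log(m$trans[m$allowed])
    zb0 <- log(m$begin[m$begin > 0])
    lossfun <- function(z) {
      mm <- m
      tr <- mm$trans
      tr[mm$allowed] <- exp(z[seq_along(zt0)])
      tr <- tr / rowSums(tr)
      mm$trans <- tr
      eb <- exp(z[length(zt0) + seq_along(zb0)])
      mm$begin[mm$begin > 0] <- eb / sum(eb)
      sum(vapply(batch, function(s) cml_loss(mm, s)$loss, 0))
    }
    gn <- numeric_gradient(lossfun, c(zt0, zb0))
    ga <- c(g$trans[m$allowed], g$begin[m$begin > 0])
    expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-4)), 1e-4)
  }
})

test_that("single-label models have zero CML transition gradient", {
  set.seed(6)
  m <- random_tiny_chmm(n_labels = 1)
  batch <- list(random_seq_for(m, 6))
  g <- cml_transition_gradients(m, batch)
  expect_equal(max(abs(g$trans)), 0, tolerance = 1e-10)
  expect_equal(max(abs(g$begin)), 0, tolerance = 1e-10)
})

test_that("model archives round-trip trained CHMMs exactly", {
  toy <- toy_topology_model()
  tmp <- withr::local_tempfile(fileext = ".model")
  write_model(toy, tmp)
  back <- read_model(tmp)
  expect_identical(back$states, toy$states)
  expect_identical(back$label_map, toy$label_map)
  expect_identical(back$tie, toy$tie)
  expect_equal(back$trans, toy$trans, tolerance = 0)
  expect_equal(unname(back$begin), unname(toy$begin), tolerance = 0)
  expect_equal(unname(back$emissions), unname(toy$emissions), tolerance = 0)
})
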