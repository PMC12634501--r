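test_that("the surrogate pseudo-derivative has the stated shape", {
  expect_equal(surrogate_grad(30, 30), 1)     # maximum at the cutoff
  expect_lt(surrogate_grad(30 + 1e4, 30), 1e-6)
  expect_lt(surrogate_grad(30 - 1e4, 30), 1e-6)
  v <- seq(-80, 140, by = 0.5)
  g <- surrogate_grad(v, 30, slope = 0.8)
  expect_true(all(g > 0))
  expect_equal(v[which.max(g)], 30)
  expect_true(all(diff(g[v < 30]) > 0) && all(diff(g[v > 30]) < 0))
  expect_error(surrogate_grad(0, 30, slope = 0), "slope")
})

test_that("analytic gradients match central finite differences on a toy", {
  cfg <- sgd_config(n_in = 3, n_classes = 2, layer_sizes = 2, steps = 5,
                    w_scale = 2000, seed = 42)
  net <- hetsnn:::sgd_init(cfg)
  set.seed(7)
  X <- lapply(1:5, function(t) matrix(rpois(2 * 3, 0.8), 2, 3))
  labels <- c(0L, 1L)
  lg <- sgd_loss_grad(net, cfg, X, labels, mode = "smooth")
  h <- 1e-5
  fd_grad <- function(get, set) {
    th <- get(net); g <- th * 0
    for (i in seq_along(th)) {
      up <- th; up[i] <- th[i] + h
      dn <- th; dn[i] <- th[i] - h
      g[i] <- (sgd_loss_grad(set(net, up), cfg, X, labels, "smooth")$loss -
                 sgd_loss_grad(set(net, dn), cfg, X, labels, "smooth")$loss) /
        (2 * h)
    }
    g
  }
  relerr <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-6))
  gW1 <- fd_grad(function(n) n$W[[1]],
                 function(n, v) { n$W[[1]][] <- v; n })
  expect_gt(max(abs(gW1)), 0)  # the check is not vacuous
  expect_lt(relerr(lg$W[[1]], gW1), 1e-4)
  gWo <- fd_grad(function(n) n$W_out,
                 function(n, v) { n$W_out[] <- v; n })
  expect_lt(relerr(lg$W_out, gWo), 1e-4)
  geta <- fd_grad(function(n) n$eta[[1]],
                  function(n, v) { n$eta[[1]] <- v; n })
  expect_lt(relerr(lg$eta[[1]], geta), 1e-4)
})

test_that("forward symmetry: zero weights give uniform scores and
           duplicated samples identical ones", {
  cfg <- sgd_config(n_in = 4, n_classes = 3, layer_sizes = 10, steps = 8,
                    seed = 1)
  net <- hetsnn:::sgd_init(cfg)
  net$W[[1]][] <- 0; net$W_out[] <- 0
  X <- lapply(1:8, function(t) matrix(0, 2, 4))
  sc <- sgd_forward(net, cfg, X)$scores
  expect_true(all(sc == 0))
  # duplicates in a batch receive identical scores
  net2 <- hetsnn:::sgd_init(cfg)
  set.seed(3)
  Xd <- lapply(1:8, function(t) {
    m <- matrix(rpois(3 * 4, 1), 3, 4); m[3, ] <- m[1, ]; m
  })
  sc2 <- sgd_forward(net2, cfg, Xd)$scores
  expect_equal(sc2[1, ], sc2[3, ])
})

test_that("partial reset raises the spike count under strong drive", {
  # single unit, strong constant drive; theta = 0.9 retains most of the
  # overshoot (large at dt = 1 ms) so the unit returns to threshold sooner
  count_spikes <- function(theta) {
    cfg <- sgd_config(n_in = 1, n_classes = 2, layer_sizes = 1, steps = 60,
                      dt = 1, seed = 1)
    net <- hetsnn:::sgd_init(cfg)
    net$W[[1]][] <- 4000
    net$theta[[1]] <- theta
    X <- lapply(1:60, function(t) matrix(1, 1, 1))
    fw <- sgd_forward(net, cfg, X, keep_cache = TRUE)
    sum(vapply(fw$cache, function(ct) sum(ct[[1]]$z), numeric(1)))
  }
  expect_gt(count_spikes(0.9), count_spikes(0))
})

test_that("training is deterministic given the seed and reports sane
           accuracies", {
  ds <- make_rate_task(n_classes = 2, n_channels = 16, n_samples = 60,
                       duration = 60, base_rate = 20, contrast = 120,
                       seed = 2)
  cfg <- sgd_config(n_in = 16, n_classes = 2, layer_sizes = 30, steps = 30,
                    epochs = 3, batch_size = 16, w_scale = 4000, seed = 5)
  f1 <- train_sgd(cfg, ds)
  f2 <- train_sgd(cfg, ds)
  expect_identical(f1$history, f2$history)
  expect_true(all(f1$history$train_accuracy >= 0 &
                    f1$history$train_accuracy <= 100))
  expect_equal(nrow(f1$history), 3)
  pred <- predict(f1, ds, idx = f1$idx_test)
  expect_equal(100 * mean(pred == ds$labels[f1$idx_test]),
               f1$final_test_accuracy)
  expect_error(sgd_config(n_in = 4, n_classes = 2, layer_sizes = integer(0)),
               "hidden layer")
  expect_error(sgd_config(n_in = 4, n_classes = 2, steps = 1), "steps")
})
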