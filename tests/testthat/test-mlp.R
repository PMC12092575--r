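test_that("symmetric cross-entropy matches hand-evaluated values", {
  expect_equal(sce_loss(c(0.5, 0.5), 1, alpha = 1, beta = 0), log(2))
  expect_equal(sce_loss(c(0, 1), 1, alpha = 3, beta = 7), 0)
  expect_equal(sce_loss(c(1, 0), 0, alpha = 2, beta = 5), 0)
  # CE = -ln(0.1), RCE = -0.9 * (-4) = 3.6
  expect_equal(sce_loss(c(0.9, 0.1), 1, alpha = 1, beta = 1, log_clamp = -4),
               -log(0.1) + 3.6, tolerance = 1e-12)
  expect_error(sce_loss(c(0.7, 0.5), 1), class = "odynr_validation_error")
})

test_that("beta = 0 reduces exactly to an independently coded cross-entropy", {
  withr::with_seed(2, {
    for (i in 1:100) {
      p1 <- runif(1, 1e-6, 1 - 1e-6)
      y <- rbinom(1, 1, 0.5)
      independent_ce <- -log(c(1 - p1, p1)[y + 1])
      expect_equal(sce_loss(c(1 - p1, p1), y, alpha = 1, beta = 0),
                   independent_ce, tolerance = 1e-12)
    }
  })
})

test_that("SCE logit gradient matches finite differences", {
  withr::with_seed(7, {
    z <- rnorm(2)
    y <- 1L
    loss_of <- function(z) {
      p <- exp(z - max(z)); p <- p / sum(p)
      sce_loss(p, y, alpha = 1, beta = 1, log_clamp = -4)
    }
    P <- matrix(exp(z - max(z)) / sum(exp(z - max(z))), 1)
    g <- odynr:::sce_logit_grad(P, y, 1, 1, -4)
    eps <- 1e-6
    for (c_ in 1:2) {
      zp <- z; zp[c_] <- zp[c_] + eps
      zm <- z; zm[c_] <- zm[c_] - eps
      expect_equal(g[1, c_], (loss_of(zp) - loss_of(zm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  })
})

test_that("full network gradients match finite differences", {
  spec <- mlp_spec(input = 6, hidden = 4, dropout = 0)
  params <- odynr:::mlp_init(spec, 1)
  withr::with_seed(3, {
    X <- matrix(rnorm(5 * 6), 5, 6)
    y <- c(0, 1, 1, 0, 1)
  })
  loss_total <- function(params) {
    fw <- odynr:::mlp_forward(params, X, spec)
    mean(sce_loss(fw$P, y, 1, 1, -4))
  }
  fw <- odynr:::mlp_forward(params, X, spec)
  dZ <- odynr:::sce_logit_grad(fw$P, y, 1, 1, -4)
  grads <- odynr:::mlp_backward(params, fw, X, dZ, spec)
  eps <- 1e-6
  for (nm in c("W1", "b2")) {
    idx <- if (nm == "W1") 7L else 1L  # single linear index into the array
    pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
    pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
    fd <- (loss_total(pp) - loss_total(pm)) / (2 * eps)
    expect_equal(grads[[nm]][idx], fd, tolerance = 1e-4)
  }
})

test_that("zero-weight networks score 0.5; scores stay in (0,1)", {
  spec <- mlp_spec(input = 168)
  params <- list(W1 = matrix(0, 168, 64), b1 = numeric(64),
                 W2 = matrix(0, 64, 2), b2 = numeric(2))
  model <- structure(list(params = params, spec = spec,
                          scaler = list(mean = numeric(168),
                                        sd = rep(1, 168))),
                     class = "odyn_mlp")
  X <- matrix(rnorm(10 * 168), 10, 168)
  expect_equal(predict_patches(model, X), rep(0.5, 10))

  model2 <- model
  model2$params <- odynr:::mlp_init(spec, 4)
  s <- predict_patches(model2, X)
  expect_true(all(s > 0 & s < 1))
  expect_error(predict_patches(model2, X[, 1:100]),
               class = "odynr_validation_error")
})

test_that("prediction is equivariant to a consistent feature permutation", {
  spec <- mlp_spec(input = 20, hidden = 8)
  params <- odynr:::mlp_init(spec, 5)
  withr::with_seed(6, {
    X <- matrix(rnorm(7 * 20), 7, 20)
    perm <- sample(20)
  })
  model <- structure(list(params = params, spec = spec,
                          scaler = list(mean = numeric(20), sd = rep(1, 20))),
                     class = "odyn_mlp")
  model_p <- model
  model_p$params$W1 <- params$W1[perm, ]
  expect_equal(predict_patches(model, X),
               predict_patches(model_p, X[, perm, drop = FALSE]))
})

test_that("slide aggregation averages the top half (ceiling rule)", {
  expect_equal(aggregate_slide(c(0.9, 0.8, 0.2, 0.1)), 0.85)
  expect_equal(aggregate_slide(0.4), 0.4)
  expect_equal(aggregate_slide(c(0.9, 0.5, 0.1)), 0.7)  # top ceil(3/2) = 2
  expect_error(aggregate_slide(numeric(0)), class = "odynr_validation_error")
  # monotone: raising any patch score never lowers the slide score
  withr::with_seed(8, {
    for (i in 1:30) {
      s <- runif(sample(1:9, 1))
      j <- sample(length(s), 1)
      s2 <- s; s2[j] <- min(1, s2[j] + runif(1))
      expect_gte(aggregate_slide(s2), aggregate_slide(s))
    }
  })
})

test_that("IDaRS training separates separable slides and is deterministic", {
  toy <- toy_features(n_slides = 14, n_patches = 8, delta = 3, seed = 31)
  cfg <- train_config(k = 2, r = 3, epochs = 20, batch_size = 32, seed = 9)
  m1 <- suppressMessages(idars_train(toy$features, toy$labels, cfg))
  m2 <- suppressMessages(idars_train(toy$features, toy$labels, cfg))
  expect_identical(m1$params, m2$params)  # same seed -> identical parameters
  s <- score_slides(m1, toy$features)
  expect_gte(auroc(s$odyn_score, toy$labels[s$slide_id]), 0.95)
  expect_lte(m1$history$train_loss[20], m1$history$train_loss[1])
})

test_that("with k = 0 the ranking is never consulted (uniform sampling)", {
  toy <- toy_features(n_slides = 6, n_patches = 10, delta = 2, seed = 17)
  cfg0 <- train_config(k = 0, r = 4, epochs = 5, batch_size = 16, seed = 3)
  m0a <- suppressMessages(idars_train(toy$features, toy$labels, cfg0))
  m0b <- suppressMessages(idars_train(toy$features, toy$labels, cfg0))
  expect_identical(m0a$history$train_loss, m0b$history$train_loss)
  # when every slide has <= k + r patches, selection is the full pool and
  # k plays no role: trajectories coincide with the uniform sampler
  cfg_all0 <- train_config(k = 0, r = 10, epochs = 5, batch_size = 16, seed = 3)
  cfg_all5 <- train_config(k = 5, r = 10, epochs = 5, batch_size = 16, seed = 3)
  ma <- suppressMessages(idars_train(toy$features, toy$labels, cfg_all0))
  mb <- suppressMessages(idars_train(toy$features, toy$labels, cfg_all5))
  expect_identical(ma$history$train_loss, mb$history$train_loss)
  expect_identical(ma$params, mb$params)
})
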