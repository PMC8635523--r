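test_that("the AlexNet registry entry matches its published layer stack", {
  arch <- build_architecture("alexnet_paper")
  kinds <- vapply(arch, `[[`, "", "kind")
  expect_equal(sum(kinds == "conv"), 5)
  expect_equal(sum(kinds == "dense"), 3)
  l1 <- arch[[1]]
  expect_equal(l1$filters, 96L)
  expect_equal(l1$kernel, c(11L, 11L))
  expect_equal(l1$stride, c(4L, 4L))
  expect_identical(l1$padding, "valid")
  l3 <- arch[[3]]  # second conv: same kernel as CL1, stride 2
  expect_equal(l3$filters, 256L)
  expect_equal(l3$kernel, c(11L, 11L))
  expect_equal(l3$stride, c(2L, 2L))
  expect_identical(arch[[length(arch)]]$activation, "softmax")
  expect_error(build_architecture("resnet50_full"), "registered")
})

test_that("shape arithmetic reproduces the canonical AlexNet dimensions", {
  arch <- build_architecture("alexnet_paper")
  sh <- output_shape(arch, c(227, 227, 3))
  expect_equal(unlist(sh[sh$layer == 1, c("height", "width", "channels")]),
               c(height = 55, width = 55, channels = 96))
  expect_equal(unlist(sh[sh$layer == 2, c("height", "width", "channels")]),
               c(height = 27, width = 27, channels = 96))
  flat <- sh[sh$kind == "flatten", "channels"]
  expect_equal(flat, 1024)  # 2 x 2 x 256
  expect_gt(flat, 0)
})

test_that("declared shapes agree with the backend's actual tensors", {
  cases <- list(c("alexnet_paper", 227), c("alexnet_paper", 144),
                c("lenet5", 32), c("lenet5", 96), c("vgg_small", 96),
                c("vgg_small", 64))
  for (cs in cases) {
    arch <- build_architecture(cs[1])
    size <- c(as.integer(cs[2]), as.integer(cs[2]), 3L)
    expect_equal(backend_shapes(arch, size), output_shape(arch, size),
                 info = paste(cs, collapse = "@"))
  }
})

test_that("impossible geometries are rejected with the offending layer", {
  arch <- build_architecture("alexnet_paper")
  expect_error(output_shape(arch, c(96, 96, 3)), "layer 4")
  expect_error(backend_shapes(arch, c(96, 96, 3)), "layer")
})

test_that("a separable toy problem is fit to perfect training accuracy", {
  set.seed(31)
  mk <- function(side, id) {
    px <- array(runif(256, 0, 0.2), c(16, 16, 1))
    if (side == "a") px[, 1:8, ] <- px[, 1:8, ] + 0.8
    else px[, 9:16, ] <- px[, 9:16, ] + 0.8
    spectro_image(pmin(px, 1), label = if (side == "a") "wheeze" else "rhonchi",
                  source_id = id)
  }
  imgs <- c(lapply(1:4, function(i) mk("a", paste0("a", i))),
            lapply(1:4, function(i) mk("b", paste0("b", i))))
  s <- image_set(imgs, c("wheeze", "rhonchi"))
  split <- split_dataset(s, 0.5, seed = 1)
  layers <- structure(list(anaspec:::conv_layer(4, 3, 1, "same"),
                           anaspec:::pool_layer(2, 2),
                           anaspec:::.layer("flatten"),
                           anaspec:::dense_layer(8),
                           anaspec:::dense_layer(2, "softmax")),
                      class = "cnn_layers")
  cfg <- cnn_config(input_size = c(16, 16, 1), n_classes = 2, epochs = 200,
                    seed = 1)
  m <- train_cnn(split, cfg, layers)
  expect_equal(nrow(m$history), 200)           # history length == epochs
  expect_equal(m$history$train_accuracy[200], 1.0)
  expect_true(all(m$history$train_loss >= 0))
  expect_true(all(m$history$train_accuracy >= 0 &
                    m$history$train_accuracy <= 1))
  # every training image is predicted with its own label
  p <- predict(m, split$train)
  expect_identical(p$labels, set_labels(split$train))
  # probabilities sum to 1 and prediction is deterministic
  expect_equal(rowSums(p$probabilities), rep(1, 4), tolerance = 1e-6)
  p2 <- predict(m, split$train)
  expect_identical(p$probabilities, p2$probabilities)
  # learning actually happened: late-epoch accuracy dominates early
  expect_gte(median(tail(m$history$train_accuracy, 20)),
             median(head(m$history$train_accuracy, 20)))
})

test_that("training is reproducible for a fixed seed", {
  set.seed(32)
  imgs <- lapply(1:8, function(i) {
    spectro_image(array(runif(64), c(8, 8, 1)),
                  label = c("wheeze", "rhonchi")[1 + i %% 2],
                  source_id = paste0("i", i))
  })
  s <- image_set(imgs, c("wheeze", "rhonchi"))
  split <- split_dataset(s, 0.5, seed = 2)
  layers <- structure(list(anaspec:::.layer("flatten"),
                           anaspec:::dense_layer(4),
                           anaspec:::dense_layer(2, "softmax")),
                      class = "cnn_layers")
  cfg <- cnn_config(input_size = c(8, 8, 1), n_classes = 2, epochs = 30,
                    seed = 7)
  m1 <- train_cnn(split, cfg, layers)
  m2 <- train_cnn(split, cfg, layers)
  expect_identical(m1$history, m2$history)
})

test_that("training rejects a split missing a class", {
  imgs <- c(lapply(1:4, function(i) flat_image(0.2, label = "wheeze",
                                               id = paste0("w", i))),
            lapply(1:2, function(i) flat_image(0.8, label = "rhonchi",
                                               id = paste0("r", i))))
  s <- image_set(imgs, c("wheeze", "rhonchi"))
  split <- split_dataset(s, 0.7, seed = 1)
  split$train <- image_set(split$train$images[
    set_labels(split$train) == "wheeze"], c("wheeze", "rhonchi"))
  cfg <- cnn_config(input_size = c(8, 8, 1), n_classes = 2, epochs = 2)
  expect_error(train_cnn(split, cfg,
                         structure(list(anaspec:::.layer("flatten"),
                                        anaspec:::dense_layer(2, "softmax")),
                                   class = "cnn_layers")),
               "absent")
})

test_that("models save and load with their JSON sidecar", {
  set.seed(33)
  imgs <- lapply(1:4, function(i) {
    spectro_image(array(runif(64), c(8, 8, 1)),
                  label = c("wheeze", "rhonchi")[1 + i %% 2],
                  source_id = paste0("i", i))
  })
  s <- image_set(imgs, c("wheeze", "rhonchi"))
  split <- split_dataset(s, 0.5, seed = 1)
  layers <- structure(list(anaspec:::.layer("flatten"),
                           anaspec:::dense_layer(2, "softmax")),
                      class = "cnn_layers")
  m <- train_cnn(split, cnn_config(input_size = c(8, 8, 1), n_classes = 2,
                                   epochs = 3, seed = 1), layers)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(unlist(side$class_vocabulary), c("wheeze", "rhonchi"))
  m2 <- load_model(f)
  expect_identical(predict(m2, split$test)$probabilities,
                   predict(m, split$test)$probabilities)
})

test_that("history CSV export round-trips", {
  h <- data.frame(epoch = 1:3, train_accuracy = c(0.3, 0.6, 0.9),
                  train_loss = c(2, 1, 0.5), val_accuracy = c(0.2, 0.5, 0.8),
                  val_loss = c(2.2, 1.2, 0.7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(h, f)
  expect_equal(read.csv(f), h)
  p <- plot_history(h)
  expect_s3_class(p, "ggplot")
})
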