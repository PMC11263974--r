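test_that("training reduces the reconstruction loss substantially", {
  spec <- tiny_molecule()
  stack <- sample_iid_dataset(spec, 400, 0.1, seed = 111)
  cfg <- model_config(
    K = 2, epochs = 15, hidden_enc = 64, hidden_dec = 64,
    seed = 112, batch_size = 64
  )
  model <- train(stack, cfg, "vae")
  h <- model$history
  expect_equal(h$epoch, seq_len(15))
  expect_lt(h$recon[nrow(h)], 0.5 * h$recon[1])
  expect_true(all(is.finite(h$total)))
})

test_that("training is bit-reproducible from the seed", {
  spec <- tiny_molecule()
  stack <- sample_iid_dataset(spec, 100, 0.1, seed = 113)
  cfg <- model_config(
    K = 2, epochs = 3, hidden_enc = 16, hidden_dec = 16,
    seed = 114, batch_size = 32
  )
  m1 <- train(stack, cfg, "vae")
  m2 <- train(stack, cfg, "vae")
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("alpha = 0 PoseVAE reduces exactly to the VAE", {
  spec <- tiny_molecule()
  stack <- sample_iid_dataset(spec, 120, 0.1, seed = 115)
  cfg <- model_config(
    K = 2, epochs = 3, hidden_enc = 16, hidden_dec = 16,
    seed = 116, batch_size = 32, alpha_pose = 0
  )
  m_vae <- train(stack, cfg, "vae")
  m_pose <- train(stack, cfg, "posevae")
  expect_identical(m_vae$params, m_pose$params)
  expect_identical(m_vae$history[c("total", "recon", "kl")],
                   m_pose$history[c("total", "recon", "kl")])
})

test_that("gamma = 0 SlowVAE reduces exactly to the temporal VAE", {
  spec <- tiny_molecule()
  stack <- sample_temporal_dataset(spec, temporal_params(1, 1, 60), 0.1, seed = 117)
  cfg <- model_config(
    K = 2, epochs = 3, hidden_enc = 16, hidden_dec = 16,
    seed = 118, batch_size = 32, gamma = 0
  )
  m_vae <- train(stack, cfg, "vae")
  m_slow <- train(stack, cfg, "slowvae")
  expect_identical(m_vae$params, m_slow$params)
  expect_identical(m_vae$history$recon, m_slow$history$recon)
})

test_that("variant and stack modes must match", {
  spec <- tiny_molecule()
  iid <- sample_iid_dataset(spec, 30, 0.1, seed = 119)
  temp <- sample_temporal_dataset(spec, temporal_params(1, 1, 15), 0.1, seed = 120)
  cfg <- model_config(K = 2, epochs = 1, hidden_enc = 8, hidden_dec = 8, seed = 1)
  expect_error(train(iid, cfg, "slowvae"), "temporal")
  expect_error(train(temp, cfg, "posevae"), "temporal")
})

test_that("the PoseVAE penalty shows up in the loss history", {
  spec <- tiny_molecule()
  stack <- sample_iid_dataset(spec, 120, 0.1, seed = 121)
  cfg <- model_config(
    K = 2, epochs = 2, hidden_enc = 16, hidden_dec = 16,
    seed = 122, batch_size = 32, alpha_pose = 2
  )
  m <- train(stack, cfg, "posevae")
  expect_true(all(m$history$pose_loss > 0))
  m2 <- train(stack, cfg, "vae")
  expect_true(all(m2$history$pose_loss == 0))
})
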