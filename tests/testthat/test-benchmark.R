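# Tiny end-to-end configurations: enough particles/epochs to exercise every
# code path, far below the scientific scale.
tiny_bench <- function(...) {
  benchmark_config(
    n_particles = 96, n_pairs = 48, epochs = 2, eval_n = 96,
    spec = tiny_molecule(), ...
  )
}

test_that("aggregate_seeds matches a hand-computed fixture", {
  mk_rows <- function(variant, values) {
    data.frame(variant = variant, seed = 1:5, metric = "MCC", value = values)
  }
  per_seed <- rbind(
    mk_rows("vae", c(0.50, 0.62, 0.40, 0.55, 0.47)),
    mk_rows("posevae", c(0.58, 0.60, 0.52, 0.70, 0.66))
  )
  rep <- asNamespace("conformscape")$new_comparison_report(
    "pose", "vae", "posevae", per_seed,
    c(MCC = TRUE), list(), 1:5
  )
  agg <- aggregate_seeds(rep)
  expect_equal(agg$medians$baseline, 0.50)
  expect_equal(agg$medians$treated, 0.60)
  # treated wins 4 of 5 paired seeds; exact two-sided binomial:
  # p = 2 * [C(5,4) + C(5,5)] / 2^5 = 12/32 = 0.375
  expect_equal(agg$sign_tests$wins, 4)
  expect_equal(agg$sign_tests$losses, 1)
  expect_equal(agg$sign_tests$p_value, 0.375, tolerance = 1e-12)
  # single-report passthrough keeps every row
  expect_equal(nrow(agg$long), 10)
  # shuffled input order yields identical output
  shuffled <- rep
  shuffled$per_seed <- per_seed[sample(nrow(per_seed)), ]
  expect_equal(aggregate_seeds(shuffled), agg)
})

test_that("the pose experiment with alpha = 0 yields exact ties", {
  rep <- run_pose_experiment(tiny_bench(alpha_pose = 0), seeds = 1:2)
  expect_equal(rep$win_count, 0)
  expect_equal(rep$medians$baseline, rep$medians$treated, tolerance = 0)
  # medians are recomputable from the stored per-seed scores
  for (i in seq_len(nrow(rep$medians))) {
    m <- rep$medians$metric[i]
    sub <- rep$per_seed[rep$per_seed$metric == m & rep$per_seed$variant == "posevae", ]
    expect_equal(stats::median(sub$value), rep$medians$treated[i])
  }
})

test_that("the temporal experiment with gamma = 0 yields exact ties", {
  rep <- run_temporal_experiment(tiny_bench(gamma = 0), seeds = 1)
  expect_equal(rep$win_count, 0)
  expect_equal(rep$medians$baseline, rep$medians$treated, tolerance = 0)
  expect_setequal(
    rep$medians$metric,
    c("MCC", "MIG", "SAP", "DCI_D", "Modularity", "BetaVAE", "FactorVAE")
  )
})

test_that("experiments are deterministic given config and seeds", {
  r1 <- run_pose_experiment(tiny_bench(), seeds = 3)
  r2 <- run_pose_experiment(tiny_bench(), seeds = 3)
  expect_identical(r1$per_seed, r2$per_seed)
  expect_identical(r1$win_count, r2$win_count)
})

test_that("comparison reports serialize to JSON plus a long CSV", {
  rep <- run_pose_experiment(tiny_bench(alpha_pose = 0), seeds = 1)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cmp.json")
  write_comparison_report(rep, path)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "cmp_long.csv")))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$win_count, rep$win_count)
  long <- utils::read.csv(file.path(dir, "cmp_long.csv"))
  expect_equal(nrow(long), nrow(rep$per_seed))
})
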