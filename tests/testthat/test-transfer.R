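# small trained model on the toy dataset, reused across blocks
toy_model <- function() {
  fixture("toy_model", function() {
    ds <- toy_dataset(n = 400)
    train_stiffness_model(
      ds, spec = mlp_spec(hidden = rep(10, 12)),
      config = train_config(epochs = 600, milestones = c(400, 550),
                            batch_size = 64, seed = 9))
  })
}

# the toy dataset with a deterministic feature shift (domain change)
shifted_toy <- function(factor = 1.6) {
  ds <- tibble::as_tibble(toy_dataset(n = 400, seed = 43))
  for (v in c("eps_core", "eps_cap", "eps_theta")) ds[[v]] <- ds[[v]] * factor
  ds$eps_core_sq <- ds$eps_core^2
  ds$eps_cap_sq <- ds$eps_cap^2
  ds$eps_theta_sq <- ds$eps_theta^2
  ds
}

test_that("stratified realistic split is disjoint, exhaustive, and spans ranges", {
  ds <- tibble::as_tibble(toy_dataset(n = 500))
  halves <- split_realistic(ds, 0.5, seed = 2)
  idx <- attr(halves, "indices")
  expect_length(intersect(idx$finetune, idx$evaluation), 0)
  expect_setequal(c(idx$finetune, idx$evaluation), seq_len(nrow(ds)))
  # both halves cover the cap and core-modulus ranges
  expect_lt(abs(diff(range(halves$finetune$cap_thk)) -
                  diff(range(halves$evaluation$cap_thk))), 60)
  expect_gt(max(halves$finetune$E_core) / min(halves$finetune$E_core), 10)
  expect_gt(max(halves$evaluation$E_core) / min(halves$evaluation$E_core), 10)
})

test_that("freezing keeps all but the last four layers bit-identical", {
  model <- toy_model()
  ft <- freeze_and_finetune(model, shifted_toy(),
                            finetune_config(epochs = 40, seed = 3))
  L <- length(model$params$W)
  frozen <- seq_len(L - 4)
  for (l in frozen) {
    expect_identical(ft$model$params$W[[l]], model$params$W[[l]])
    expect_identical(ft$model$params$b[[l]], model$params$b[[l]])
  }
  changed <- vapply((L - 3):L, function(l)
    !isTRUE(all.equal(ft$model$params$W[[l]], model$params$W[[l]])), logical(1))
  expect_true(all(changed))
  expect_equal(ft$model$finetuned_layers, (L - 3):L)
})

test_that("trainable parameter count equals the last four layers", {
  model <- toy_model()
  sizes <- model$spec$layer_sizes
  L <- length(sizes) - 1
  n_tail <- sum(vapply((L - 3):L, function(l)
    sizes[l] * sizes[l + 1] + sizes[l + 1], numeric(1)))
  # parameters that changed during fine-tuning are at most the tail count
  ft <- freeze_and_finetune(model, shifted_toy(),
                            finetune_config(epochs = 40, seed = 3))
  n_changed <- sum(vapply(seq_len(L), function(l)
    sum(ft$model$params$W[[l]] != model$params$W[[l]]) +
      sum(ft$model$params$b[[l]] != model$params$b[[l]]), numeric(1)))
  expect_lte(n_changed, n_tail)
  # most tail parameters move (some stay at zero behind dead ReLUs)
  expect_gt(n_changed, 0.25 * n_tail)
})

test_that("fine-tuning with zero trainable layers is a no-op", {
  model <- toy_model()
  ft <- freeze_and_finetune(model, shifted_toy(),
                            finetune_config(n_trainable = 0, epochs = 10, seed = 3))
  expect_identical(ft$model$params, model$params)
})

test_that("fine-tuning improves accuracy on a domain-shifted family", {
  model <- toy_model()
  shifted <- shifted_toy()
  ft <- freeze_and_finetune(model, shifted,
                            finetune_config(epochs = 800, seed = 3))
  before <- evaluate(model, ft$evaluation)
  after <- evaluate(ft$model, ft$evaluation)
  expect_lt(mean(after$summary$mean), mean(before$summary$mean))
  # evaluation half untouched by fine-tuning rows
  expect_length(intersect(ft$indices$finetune, ft$indices$evaluation), 0)
})

test_that("case-study report carries all three cases and serializes", {
  model <- toy_model()
  ds <- toy_dataset(n = 400)
  cs <- run_case_study(model, ds, shifted_toy(),
                       finetune_config(epochs = 150, seed = 3))
  expect_equal(cs$summary$case,
               c("case1_train", "case1_test", "case2_realistic", "case3_finetuned"))
  expect_true(all(is.finite(cs$summary$err_E_core)))
  path <- withr::local_tempfile(fileext = ".json")
  write_case_study(cs, path)
  back <- read_case_study(path)
  expect_equal(back$summary$err_E_core, cs$summary$err_E_core, tolerance = 1e-9)
})
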