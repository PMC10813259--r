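# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small synthetic population + shape model (shared by SSM/sampling tests)
fixture_shape_model <- function() {
  .memo("shape_model", function() {
    pop <- synthetic_attachment_population(
      population_config(n_subjects = 100, seed = 11))
    fit_shape_model(pop, n_modes = 4)
  })
}

# template mesh at the population mean geometry
fixture_mean_mesh <- function(n_lines = 36L) {
  .memo(paste0("mesh", n_lines), function() {
    pair <- reconstruct_attachments(fixture_shape_model(), numeric(0))
    build_capsule_mesh(pair$acetabular, pair$femoral,
                       head_sphere = list(center = c(0, 0, 0), radius = 22),
                       n_lines = n_lines)
  })
}

fixture_mean_params <- function() {
  d <- default_distributions()
  capsule_parameters(d$mean[1:6], d$mean[7:12])
}

# small trial dataset for surrogate/validation unit tests
fixture_small_trials <- function() {
  .memo("small_trials", function() {
    generate_trial_dataset(80, fixture_shape_model(), seed = 21)
  })
}

# full-scale probabilistic dataset (500 trials) for the closed-loop
# acceptance checks; expensive, so built once and reused
fixture_full_trials <- function() {
  .memo("full_trials", function() {
    generate_trial_dataset(500, fixture_shape_model(), seed = 5)
  })
}

# the baseline 450/50 closed-loop experiment on the full dataset
fixture_baseline_loop <- function() {
  .memo("baseline_loop", function() {
    sp <- split_trials(fixture_full_trials(), n_validation = 50, seed = 2)
    model <- capsule_surrogate(sp$train, set = training_set_spec(1))
    list(split = sp, model = model,
         report = closed_loop_validate(model, sp$validation))
  })
}
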