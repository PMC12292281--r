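# Shared fixtures. Expensive artefacts (trained agents, trained mappers) are
# built once per test run and cached here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a small, fast, uncalibrated model for structural tests
tiny_model <- function(dt = 1 / 12) {
  stage_model(rate_constants(0.5, 0.3, 0.2),
              actuated = rate_constants(0.1, 0.1, 0.1), dt = dt)
}

default_env <- function() {
  cached("default_env", function() wound_env(default_stage_model()))
}

# the study-condition agents: tracking and sparse arms, seeds 0..4,
# full 2000-episode budget (shared by the acceptance criteria)
study_agents <- function(reward) {
  cached(paste0("agents_", reward), function() {
    env <- default_env()
    lapply(0:4, function(s) {
      train_agent(env, a2c_config(episodes = 2000L, seed = s), reward = reward)
    })
  })
}

# a quickly trained agent for structural closed-loop tests
quick_agent <- function() {
  cached("quick_agent", function() {
    train_agent(default_env(), a2c_config(episodes = 300L, seed = 0L))
  })
}

# small noiseless cohort for mapper unit tests (14 consecutive pairs)
tiny_cohort <- function() {
  cached("tiny_cohort", function() {
    generate_cohort(2, 2, 12, params = render_params(size = 32, noise_sd = 0),
                    seed = 3, test_fraction = 0.45)
  })
}

tiny_mapper_config <- function(...) {
  mapper_config(size = 32, epochs = 6, warmup = 2, seed = 0, ...)
}

random_stage_vector <- function() {
  z <- stats::rexp(4)
  as_stage_vector(z / sum(z))
}
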