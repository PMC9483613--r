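# Shared fixtures, built once per test run and cached. Everything is
# generated in code from seeded simulators; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

fx_design <- function() fixture("design", default_design)

# one moderate spiral recording + matching line scan, reused across tests
fx_config <- function() fixture("config", function()
  spiral_sim_config(cv = 20, apd80 = 180, seed = 11))

fx_stack <- function() fixture("stack", function()
  simulate_spiral_recording(fx_design(), fx_config()))

fx_linescan <- function() fixture("linescan", function()
  simulate_linescan(fx_design(), fx_config(), c(0.1, 0.3), c(5.2, 5.4)))

fx_profile_norm <- function() fixture("profile_norm", function()
  filter_and_normalize(extract_path_profile(fx_stack(), fx_design(),
                                            extraction_width = 5)))

# a small noiseless recording for exact kinematic checks
fx_stack_clean <- function() fixture("stack_clean", function()
  simulate_spiral_recording(
    fx_design(),
    spiral_sim_config(cv = 20, apd80 = 150, seed = 4, noise_sd = 0,
                      bleach_rate = 0, n_frames = 90L)))

expect_within <- function(object, expected, tol, label = NULL) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%s: |%.6g - %.6g| <= %.3g",
                              label %||% "value", object, expected, tol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
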