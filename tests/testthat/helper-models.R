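# Shared fixtures built in code. Models are cached per session so several
# test files can reuse one (deterministically seeded) training run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 120 px scenes: same calibration as the 300 px default, smaller field of
# view (0.135 mm2), so unit tests stay fast.
tiny_spec <- function(...) scene_spec(image_size = 120L, ...)

tiny_config <- function() ssd_config(input_size = 120L)

tiny_scenes <- function(n, seed) {
  generate_scenes(n, density_range = c(93, 166), spec = tiny_spec(),
                  seed = seed)
}

# A small but genuinely trained detector on 120 px scenes.
tiny_model <- function() {
  memo("tiny_model", {
    train_detector(tiny_scenes(16, seed = 501), epochs = 12, seed = 1,
                   lr = 2e-3, config = tiny_config())
  })
}

tiny_test_scenes <- function() memo("tiny_test", tiny_scenes(8, seed = 502))

tiny_area <- function() stomadet:::scene_area_mm2(tiny_spec())
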