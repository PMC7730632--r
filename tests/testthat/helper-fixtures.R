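# Shared fixtures.  Everything is generated in code; the cache avoids
# re-rendering the same scene across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small scene for fast pipeline tests
small_scene <- function() cached("small_scene", torso_scene(160L, 192L))

# a constant-depth sequence: every pixel `depth`, n frames at `fps`
flat_sequence <- function(depth = 1500L, n = 3L, h = 40L, w = 30L,
                          fps = 30) {
  depth_sequence(array(as.integer(depth), c(h, w, n)),
                 (seq_len(n) - 1) / fps)
}

# noiseless quiet-breathing recording on the small scene
small_recording <- function() {
  cached("small_recording", {
    prog <- breathing_program("normal", rr_bpm = 15, duration_s = 24)
    render_sequence(small_scene(), prog, noise_none(), fps = 15)
  })
}

# pure sinusoidal displacement signal
sine_signal <- function(A = 3, f = 0.2, dur = 60, rate = 30) {
  t <- seq(0, dur, by = 1 / rate)
  resp_signal(t, A * sin(2 * pi * f * t), rate)
}

expect_respdepth_error <- function(expr, class) {
  expect_error(expr, class = paste0("respdepth_", class, "_error"))
}
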