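# Dense-grid maximizer: slow, assumption-free oracle for 1-D concave maxima.
grid_argmax <- function(f, lo, hi, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(vapply(grid, f, numeric(1)))]
}

# Central finite difference, for sign checks on comparative statics.
fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

both_agents <- c("elderly", "government")
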