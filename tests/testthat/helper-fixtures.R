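# Brute-force rasterization oracle (independent of the package's grid code):
# a pixel belongs to the disk iff its centre does.
oracle_disk_mask <- function(r, n, cx = n / 2, cy = n / 2) {
  m <- matrix(FALSE, n, n)
  for (row in seq_len(n)) {
    for (col in seq_len(n)) {
      m[row, col] <- (col - 0.5 - cx)^2 + (row - 0.5 - cy)^2 <= r^2
    }
  }
  m
}

# Compact fixture dataset in a fresh temp dir; small frames keep the suite
# fast while leaving room for the cup ring at every tested week.
tiny_dataset <- function(dir, n_per = 3, weeks = c(0, 18), seed = 42,
                         width = 128, radius = 30, ring = 10,
                         growth = 1.0) {
  generate_dataset(
    dir, n_per, weeks, seed = seed, growth_factor_per_week = growth,
    base_spec = synthetic_spec(width = width, height = width,
                               tissue_radius_px = radius,
                               cup_ring_width_px = ring))
}

# Random valid box in a w x h frame with a minimum side length.
random_box <- function(w = 200, h = 150, min_side = 2) {
  repeat {
    x <- sort(runif(2, 0, w)); y <- sort(runif(2, 0, h))
    if (diff(x) >= min_side && diff(y) >= min_side)
      return(bounding_box(x[1], y[1], x[2], y[2], w, h))
  }
}

benchmark_table <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "coralmorph"),
                  stringsAsFactors = FALSE)
}
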