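# Fixtures are generated in code; nothing is stored on disk.

# template as a 2k vector, centered and unit-sized
template_vec <- function() {
  wingmorph:::config_vector(wingmorph:::center_scale(wing_template()))
}

# apply a similarity transform (rotation angle, scale, shift) to a k x 2 config
similarity_transform <- function(m, angle = 0, scale = 1, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  sweep(scale * m %*% rot, 2L, -shift)
}

# n noisy copies of the wing template as a landmark_dataset
noisy_wing_dataset <- function(n, sd = 0.01, seed = 1, populations = NULL) {
  set.seed(seed)
  tpl <- wing_template()
  coords <- t(vapply(seq_len(n), function(i) {
    m <- tpl + matrix(rnorm(38, sd = sd), ncol = 2L)
    m <- similarity_transform(m, angle = runif(1, 0, 2 * pi),
                              scale = runif(1, 0.8, 1.2),
                              shift = runif(2, -1, 1))
    wingmorph:::config_vector(m)
  }, numeric(38)))
  meta <- data.frame(
    specimen_id = sprintf("sp%03d", seq_len(n)),
    colony_id = sprintf("col%02d", 1 + (seq_len(n) - 1) %/% 4),
    site_id = "s1", region = "r1",
    latitude = seq(17, 19, length.out = n),
    longitude = seq(-94, -93, length.out = n),
    population = if (is.null(populations)) "p1" else populations,
    stringsAsFactors = FALSE
  )
  landmark_dataset(coords, meta)
}

# metadata-only frame of points along a quasi-linear transect
transect_meta <- function(n, seed = 1) {
  set.seed(seed)
  t <- sort(runif(n))
  data.frame(
    specimen_id = sprintf("w%03d", seq_len(n)),
    latitude = -35 + 10 * t + rnorm(n, sd = 0.05),
    longitude = -62 + 4 * t + rnorm(n, sd = 0.05),
    stringsAsFactors = FALSE
  )
}

# two-class Gaussian scores with a given mean shift
two_class_scores <- function(n_per = 20, m = 3, shift = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * m), ncol = m),
             matrix(rnorm(n_per * m), ncol = m) + shift / sqrt(m))
  list(x = x, labels = rep(c("a", "b"), each = n_per))
}
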