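# shared fixtures: small noiseless studies are expensive enough that the
# suite builds each configuration once and memoises it per session

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# noiseless, drift-free default phantom study with all five B1 levels
clean_study <- function() fixture("clean_study", function() {
  g <- make_phantom(phantom_spec(seed = 11))
  st <- simulate_study(g, protocol(noise_sd = 0, drift_slope = 0),
                       seed = 11)
  list(geom = g, study = st, preproc = preprocess_study(st))
})

# log-spaced high-B1 offset grid used throughout
log_grid <- function(n_per_side = 15) {
  h <- exp(seq(log(3), log(300), length.out = n_per_side))
  sort(c(-h, h))
}

# brute-force 8-neighbour erosion oracle
erode_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i == 1 || i == nr || j == 1 || j == nc) next
    out[i, j] <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1)])
  }
  out
}
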