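# Shared fixtures, built once per test run and memoised across files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a 6-plant single-plot field: fast, exercises every stage
tiny_layout <- function() field_layout(n_plots = 1, rows_per_plot = 2, hills_per_row = 3)

tiny_sim <- function() fixture("tiny_sim", function()
  generate_field(tiny_layout(), growth_params(), synthetic_truth(), seed = 101))

tiny_scene <- function() fixture("tiny_scene", function()
  derive_scene_maps(tiny_sim()$scene))

tiny_records <- function() fixture("tiny_records", function() {
  lab <- segment_plants(get_map(tiny_scene(), "0524", "ndvi"))
  plant_records(lab, expected = nominal_positions(tiny_layout()))
})

# the full 210-plant study preset (used by the acceptance tests)
default_sim <- function() fixture("default_sim", function()
  generate_field(field_layout(), growth_params(), synthetic_truth(),
                 seed = stage_seed(1L, "simulate")))

default_scene <- function() fixture("default_scene", function()
  derive_scene_maps(default_sim()$scene))

default_records <- function() fixture("default_records", function() {
  lab <- segment_plants(get_map(default_scene(), "0524", "ndvi"))
  plant_records(lab, expected = nominal_positions(field_layout()))
})

default_features <- function() fixture("default_features", function()
  assemble(default_scene(), default_records()))

default_yields <- function() fixture("default_yields", function() {
  sim <- default_sim()
  sim$yields[match(default_records()$plant_id, sim$yields$plant_id), ]
})

# crude box smoothing, enough to make spatially coherent test masks
gauss_smooth_for_test <- function(m, passes = 4) {
  for (i in seq_len(passes)) {
    up <- rbind(m[-1, ], m[nrow(m), ]); dn <- rbind(m[1, ], m[-nrow(m), ])
    le <- cbind(m[, -1], m[, ncol(m)]); ri <- cbind(m[, 1], m[, -ncol(m)])
    m <- (m + up + dn + le + ri) / 5
  }
  (m - mean(m)) / stats::sd(m)
}

# simple regression design for the selection tests
make_design <- function(n, p, seed, beta = NULL, noise = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("V%02d", seq_len(p))
  if (is.null(beta)) beta <- rep(0, p)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y)
}
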