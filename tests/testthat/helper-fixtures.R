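# Shared fixtures: hand-built flow fields for kernel-level tests, and a
# lazy cache so the expensive coupled scenario runs are executed once and
# shared across test files.

# a flow_field with spatially uniform velocity (um/s) on a domain
uniform_flow <- function(domain, u = c(0, 0, 0), Q = NULL) {
  d <- domain$shape
  mk <- function(v) { a <- array(v, d); a[domain$wall_mask] <- 0; a }
  structure(list(ux = mk(u[1]), uy = mk(u[2]), uz = mk(u[3]),
                 pressure = array(0, d), converged = TRUE, iterations = 0L,
                 lb_scale = 1, domain_shape = d, h = domain$h_lkmc,
                 Q = Q %||% 0, bc_kind = "constant_shear_inlet"),
            class = "flow_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a population at given 1-based voxel triples
population_at <- function(domain, trips, mobile = TRUE) {
  pop <- new_population()
  trips <- matrix(trips, ncol = 3)
  n <- nrow(trips)
  pop$id <- seq_len(n)
  pop$pos0 <- (trips[, 1] - 1L) +
    domain$shape[1] * ((trips[, 2] - 1L) + domain$shape[2] * (trips[, 3] - 1L))
  pop$mobile <- rep(mobile, length.out = n)
  pop$created_t <- numeric(n)
  pop$next_id <- n + 1L
  pop
}

pos_to_trip <- function(pos0, shape) {
  cbind(pos0 %% shape[1] + 1L,
        (pos0 %/% shape[1]) %% shape[2] + 1L,
        pos0 %/% (shape[1] * shape[2]) + 1L)
}

# lazy cache of expensive scenario runs, shared across the suite
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, maker) {
  if (!exists(name, envir = .run_cache))
    assign(name, maker(), envir = .run_cache)
  get(name, envir = .run_cache)
}

chan_run <- function(treatment = "control", seed = 1, t_end = 150) {
  cached_run(paste0("chan_", treatment, "_", seed, "_", t_end), function()
    run_simulation(scenario_presets("channel_200", treatment = treatment,
                                    seed = seed, t_end = t_end)))
}

sten_run <- function(seed = 1, t_end = 300, vwf = TRUE, tf = FALSE) {
  cached_run(paste0("sten_", seed, "_", t_end, "_", vwf, "_", tf), function() {
    cfg <- scenario_presets("stenosis_75", seed = seed, t_end = t_end,
                            vwf_enhancement_on = vwf)
    if (tf) cfg$geometry$tf_on <- TRUE
    run_simulation(cfg)
  })
}
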