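# Shared phantom fixtures, memoised per test run (generation is the
# expensive part; specs are deterministic so caching is safe).

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .phantom_cache))
    assign(key, force(expr), envir = .phantom_cache)
  get(key, envir = .phantom_cache)
}

# compact phantom for unit tests: coarser grid, smaller anatomy
small_spec <- function(...) {
  phantom_spec(acetab_radius = 16,
               acetab_centers = rbind(L = c(55, 0, 0), R = c(-55, 0, 0)),
               endplate_width = 40, endplate_depth = 30,
               endplate_midpoint = c(0, -40, 70),
               asis = rbind(L = c(75, 26, 4), R = c(-75, 26, 4)),
               pt = rbind(L = c(18, 26, -45), R = c(-18, 26, -45)),
               voxel_spacing = c(1.4, 1.4, 1.4),
               ...)
}

small_mesh_bundle <- function() cached("small_mesh", generate_phantom_mesh(small_spec()))
small_volume_bundle <- function() cached("small_volume", generate_phantom_volume(small_spec()))

default_mesh_bundle <- function() cached("default_mesh", generate_phantom_mesh(phantom_spec()))
default_volume_bundle <- function() cached("default_volume", generate_phantom_volume(phantom_spec()))

truth_landmark_list <- function(truth) {
  apply(truth$landmarks, 1, identity, simplify = FALSE)
}

# pipeline config matched to the small phantom's resolution
small_config <- function(...) {
  pi_config(n_min = 800, n_max = 4000, ...)
}

identity_frame <- function() {
  pelvic_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}
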