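# Shared fixtures, memoized across test files (built in code, no stored data).

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small, noise-free phantom for structural tests; named overrides allowed
tiny_config <- function(...) {
  args <- modifyList(list(dim = c(12, 72, 72), noise_sd = 0, shot_scale = 0,
                          border_gain = 1, motor_pools = character(),
                          axon_tract = FALSE),
                     list(...))
  do.call(phantom_config, args)
}

tiny_phantom <- function() {
  get_fixture("tiny_phantom",
              function() generate_template_phantom(tiny_config(), seed = 42))
}

# full-size noise-free phantom (shared by deposit / template / registration tests)
clean_phantom <- function() {
  get_fixture("clean_phantom", function()
    generate_template_phantom(
      phantom_config(noise_sd = 0, shot_scale = 0, border_gain = 1), seed = 1))
}

# noisy full-size phantom used by the registration recovery checks
noisy_phantom <- function() {
  get_fixture("noisy_phantom", function()
    generate_template_phantom(phantom_config(noise_sd = 2, shot_scale = 0.01),
                              seed = 1))
}

# shared end-to-end study (used by classifier / quantify / acceptance checks)
shared_study <- function() {
  get_fixture("shared_study", function() run_phantom_study(n_per_group = 3, seed = 11))
}

# random annotation over a small ad-hoc ontology
random_annotation <- function(dim = c(4, 8, 8), seed = 99) {
  ont <- build_region_ontology(levels = c("C4", "C5"), laminae_per_level = 1:10,
                               white_tracts = "white matter")
  labs <- with_seed_test(seed, array(sample(c(0L, ont$regions$id), prod(dim),
                                            replace = TRUE), dim))
  annotation_volume(labs, voxel_size = c(40, 10, 10), ontology = ont)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

flip_x <- function(a) a[, , dim(a)[3]:1, drop = FALSE]

# strip everything but dim (for exact array comparisons)
plain_arr <- function(a) array(as.vector(unclass(a)), dim(a))
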