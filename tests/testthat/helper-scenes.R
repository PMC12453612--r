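# small deterministic worlds used across tests

small_params <- function(...) {
  scene_params(quadrat_width = 20, quadrat_height = 12, noise_sd = 0, ...)
}

# a scene with one object of each class at known positions (no noise)
one_of_each_scene <- function(params = small_params()) {
  flowers <- point_set(5, 5, kind = "flower")
  mounds <- point_set(15, 8, kind = "mound", colony_id = 1L)
  mounds$radius <- 0.10
  buttercups <- point_set(10, 3, kind = "buttercup")
  list(scene = render_scene(flowers, mounds, params,
                            buttercups = buttercups),
       flowers = flowers, mounds = mounds, buttercups = buttercups,
       params = params)
}

brute_force_nn <- function(flowers, mounds) {
  apply(as.matrix(flowers[, c("x", "y")]), 1, function(p)
    sqrt(min((p[1] - mounds$x)^2 + (p[2] - mounds$y)^2)))
}
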