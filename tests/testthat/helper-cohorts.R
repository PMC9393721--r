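# Shared small cohort specifications for tests. Small image grids keep the
# suite fast; the generator contract is identical at any size.

tiny_spec <- function(n = 4L, texture = 0, alff = 0, seed = 1L,
                      shape = c(16L, 12L, 10L), n_volumes = 210L) {
  cohort_spec(
    n_per_group = c(case = n, NC = n),
    image_shape = shape,
    roi_spec = list(left  = list(center = c(5, 6, 5), radii = c(3, 3, 3)),
                    right = list(center = c(12, 6, 5), radii = c(3, 3, 3))),
    n_volumes = n_volumes,
    texture_effect = texture, alff_effect = alff,
    seed = seed)
}

study_spec <- function(n = 20L, texture = 0, alff = 0, seed = 1L) {
  cohort_spec(n_per_group = c(case = n, NC = n),
              texture_effect = texture, alff_effect = alff, seed = seed)
}
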