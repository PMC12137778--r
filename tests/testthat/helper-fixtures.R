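# Shared fixtures: small tissues, protocols and phantoms built in code.

fix_single_pool <- function(t1 = 500, t2 = 100)
  tissue_params(t1_free = t1, t2_free = t2, bound_fraction = 0,
                label = "single_pool")

fix_wm <- function()
  tissue_params(t1_free = 350, t2_free = 90, bound_fraction = 0.13,
                exchange_rate = 35, t1_bound = 350, t2_bound = 11,
                label = "wm_like")

fix_protocol <- function(flip = 60, ...)
  sequence_protocol(flip_angle = flip, ...)

# random but physically consistent EPG state (fm[1] must equal fp[1])
fix_random_state <- function(tissue, n_states = 40, seed = 1, scale = 0.3) {
  st <- epg_init(tissue, n_states)
  set.seed(seed)
  st$fp <- complex(real = rnorm(n_states, 0, scale),
                   imaginary = rnorm(n_states, 0, scale))
  st$fm <- complex(real = rnorm(n_states, 0, scale),
                   imaginary = rnorm(n_states, 0, scale))
  st$fm[1] <- st$fp[1]
  st$z <- complex(real = rnorm(n_states, 0, scale))
  st$zb <- complex(real = rnorm(n_states, 0, scale / 3))
  st
}

# small two-vial MT phantom for fast end-to-end runs
fix_small_phantom <- function() {
  water <- tissue_params(3000, 2000, label = "water")
  cond <- tissue_params(600, 120, 0.12, 30, 600, 12, label = "cond")
  comps <- list(
    phantom_compartment("water", water, "cylinder",
                        center = c(-10, 0, 0), radius = 6, height = 12),
    phantom_compartment("cond", cond, "cylinder",
                        center = c(10, 0, 0), radius = 6, height = 12))
  build_vial_phantom(phantom_definition(comps, fov = c(48, 48, 20),
                                        voxel = c(2, 2, 5)))
}
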