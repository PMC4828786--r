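# Shared fixtures: built in code, no stored data.

table2 <- balloon_ogden_coefficients()
default_design <- balloon_design()

# a generic stable two-term Ogden material for synthetic round-trips
soft_ogden <- ogden_model(mu = c(40, 200), alpha = c(1.3, 5.2), poisson = 0.45)

# long cylindrical balloon whose mid-section approximates an infinite
# cylinder (heads ~5 % of total length), for closed-form oracle checks
long_cyl_design <- balloon_design(diameter = 23, cyl_length = 76,
                                  total_length = 80, thickness = 0.09,
                                  shaft_radius = 3)

# phantom configurations used across tests
phantom_22 <- cylinder_phantom(22, 1.2, 75, end_band = 5)
phantom_compliance <- cylinder_phantom(20, 0.8, 60, end_band = 0)
t50_material <- linear_elastic_model(13.19, poisson = 0.25)

# mid-element index helper: element whose midpoint is closest to the
# axial centre of a state
mid_element <- function(state) {
  zm <- (state$z[-1] + state$z[-length(state$z)]) / 2
  which.min(abs(zm - (min(state$z) + max(state$z)) / 2))
}
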