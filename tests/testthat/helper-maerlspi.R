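# Shared fixtures built in code.

# noiseless color model: classification must be exact
cm0 <- color_model(channel_sd = 0)

# a small scene builder used across files
small_scene <- function(composition = c(0.5, 0.3, 0.2),
                        interface = interface_flat(50),
                        color_model = cm0, seed = 7,
                        width = 100, height = 300, scale = 0.02) {
  generate_spi_image(width_px = width, height_px = height,
                     scale_cm_per_px = scale, interface = interface,
                     composition = composition, color_model = color_model,
                     seed = seed)
}

# one RGB pixel image
pixel_image <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))

# a tiny campaign spec for pipeline tests
tiny_spec <- function(seed = 5, noise = TRUE) {
  gradient_spec(
    n_stations = 6, images_per_station = 5,
    pressure_values = c(0, 0.05, 0.8, 1.2, 2.8, 3.2),
    noise_sd = if (noise) list(ratio = 0.35, penetration = 1.2,
                               rugosity = 0.35, interstice = 0.02,
                               perimeter = 40, solidity = 0.03)
    else list(ratio = 0, penetration = 0, rugosity = 0, interstice = 0,
              perimeter = 0, solidity = 0),
    thalli_stations = 3, cores_per_station = 2, thalli_per_core = 2,
    seed = seed)
}
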