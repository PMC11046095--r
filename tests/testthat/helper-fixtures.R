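# Shared fixtures, built once per test run and cached. Everything is
# generated in code; seeds are fixed so the suite is deterministic.

the_fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(the_fixtures[[name]])) the_fixtures[[name]] <- builder()
  the_fixtures[[name]]
}

# noise-free, hair-free default-protocol scan and its processed form
quiet_scan <- function() fixture("quiet_scan", function() {
  generate_scan(build_phantom_scene(),
                scan_protocol(noise_sd = 0, dark_sd = 0),
                hair = NULL, seed = 7)
})

quiet_processed <- function() fixture("quiet_processed", function() {
  process_scan(quiet_scan())
})

# default-noise scan with a hair layer
hairy_scan <- function() fixture("hairy_scan", function() {
  protocol <- scan_protocol()
  hair <- sample_hair_field(protocol, seed = 5)
  generate_scan(build_phantom_scene(), protocol, hair = hair, seed = 11)
})

hairy_processed <- function() fixture("hairy_processed", function() {
  process_scan(hairy_scan())
})

# shared Monte Carlo path ensemble (default geometry and scattering)
mc_paths <- function() fixture("mc_paths", function() {
  simulate_paths(slab_geometry(), scatter_model(), n_photons = 2e5, seed = 42)
})

# moderate-size shared-path sweep for derivative/extremum properties
mc_small_sweep <- function() fixture("mc_small_sweep", function() {
  mc_sweep(n_photons = 2e5, seed = 3, n_boot = 30)
})
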