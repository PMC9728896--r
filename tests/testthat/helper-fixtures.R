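# Shared simulation fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small single-deme equilibrium simulation (fast, reused widely)
fix_single_deme <- function() {
  fixture("single_deme", function() {
    simulate_wf(sim_config(seq_length = 1e5, mu = 1e-5, rec = 1e-5,
                           demes = c(pop = 50), seed = 42))
  })
}

# small two-deme simulation with migration
fix_two_deme <- function() {
  fixture("two_deme", function() {
    simulate_wf(island_pair_config(Nm = 1, N = 50, seq_length = 1e5,
                                   mu = 1e-5, rec = 1e-5, seed = 43))
  })
}
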