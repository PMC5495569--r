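# Shared fixture builders: everything is generated in code at test time.

pip_plan <- function(...) {
  make_session_plan("recording", utils::modifyList(list(alignment = "pip"),
                                                   list(...)))
}

# One-session habituation-style plan for cheap single-unit fixtures.
mini_plan <- function(n_cs = 3, alignment = "tone") {
  p <- make_session_plan("recording", list(alignment = alignment))
  p$sessions <- p$sessions[p$sessions$label == "Hab", ]
  p$sessions$n_cs <- n_cs
  p
}

# Simulate one unit of a phenotype and classify it; used by recovery tests.
classify_planted <- function(seed, phenotype, plan = NULL, modulation = 10) {
  plan <- plan %||% pip_plan()
  ev <- generate_events(plan, substream_seed(seed, "sched"))
  spec <- make_neuron_spec("u", phenotype, plan, modulation = modulation)
  sim <- simulate_unit(spec, plan, seed, events = ev, n_snippets = 4)
  classify_neuron(build_profile(sim$spikes, ev, plan, unit_id = "u"))$label
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical biphasic waveform used as a template fixture.
spike_template_fixture <- function(n = 32) {
  t <- seq_len(n)
  -120 * exp(-(t - 9)^2 / 8) + 45 * exp(-(t - 17)^2 / 30)
}
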