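# Shared fixture builders (all generated in code; no stored data).

# Pulse train of identical beats at a fixed rate, rendered with the package
# generator at negligible noise.
make_pulse_train <- function(hr_bpm = 72, duration_s = 60, fs = 500,
                             amp = 1, seed = 1) {
  protocol <- protocol_spec(baseline_s = duration_s, occlusion_s = 1,
                            hyperemia_s = duration_s)
  params <- archetype_params(hr_bpm = hr_bpm, hr_cv = 0, base_amp = amp,
                             gain = 1, complexity = 0, fluct_cv = 0,
                             snr_db = 80)
  sim <- simulate_amplitude_series(params, seed = seed, protocol = protocol)
  rw <- render_waveform(sim, params, fs_hz = fs, seed = seed,
                        protocol = protocol)
  list(recording = rw$recording, series = sim, protocol = protocol,
       params = params)
}

default_group_sim <- function(group = 1, seed = 42, ...) {
  simulate_recording(group, seed = seed, ...)
}
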