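# Default analysis configuration: synthetic cohort mode.
mode: synthetic
seed: 1
cohort:
  recording_duration: 150      # seconds per participant
  sample_rate: 22050
  burst_base: 0.06
spectrogram:
  window_length: 25            # ms
  hop: 2                       # ms (temporal-modulation Nyquist 250 Hz)
  window_shape: gaussian
  amplitude_scale: log
  log_floor: 80                # dB below per-file maximum
  max_frequency: 8000          # Hz
contour:
  energy_fraction: 0.999
  wt_max: 100                  # Hz
  wf_max: 20                   # cycles/kHz
  chunk_duration: 1            # s
  chunk_overlap: 0.5
bands:
  sr: [0, 10]
  ft: [10, 50]
  poa: [50, 100]
detector:
  pause_ms: 300
  frame: 10
  threshold_db: 15
stats:
  alpha: 0.05
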