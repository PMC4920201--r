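{
  "seed": 1,
  "bin_size": 1000,
  "read_depth": 1,
  "noise": "poisson",
  "library_size": 1000000,
  "blocks": [
    {
      "prefix": "constant",
      "n": 3,
      "pattern": "constant",
      "length": 12000,
      "baseline_rate": 0.5,
      "fold": 3,
      "onset_time": 0,
      "off_time": 30,
      "rate_kb_min": 2,
      "strand": "+"
    },
    {
      "prefix": "sustained_up",
      "n": 3,
      "pattern": "sustained_up",
      "length": 12000,
      "baseline_rate": 0.5,
      "fold": 3,
      "onset_time": 0,
      "off_time": 30,
      "rate_kb_min": 2,
      "strand": "+"
    },
    {
      "prefix": "sustained_down",
      "n": 3,
      "pattern": "sustained_down",
      "length": 12000,
      "baseline_rate": 0.5,
      "fold": 3,
      "onset_time": 0,
      "off_time": 30,
      "rate_kb_min": 2,
      "strand": "+"
    },
    {
      "prefix": "transient_up",
      "n": 3,
      "pattern": "transient_up",
      "length": 12000,
      "baseline_rate": 0.5,
      "fold": 3,
      "onset_time": 0,
      "off_time": 30,
      "rate_kb_min": 2,
      "strand": "+"
    },
    {
      "prefix": "transient_down",
      "n": 3,
      "pattern": "transient_down",
      "length": 12000,
      "baseline_rate": 0.5,
      "fold": 3,
      "onset_time": 0,
      "off_time": 30,
      "rate_kb_min": 2,
      "strand": "+"
    },
    {
      "prefix": "delayed_up",
      "n": 3,
      "pattern": "delayed_up",
      "length": 12000,
      "baseline_rate": 0.5,
      "fold": 3,
      "onset_time": 30,
      "off_time": 30,
      "rate_kb_min": 2,
      "strand": "+"
    },
    {
      "prefix": "delayed_down",
      "n": 3,
      "pattern": "delayed_down",
      "length": 12000,
      "baseline_rate": 0.5,
      "fold": 3,
      "onset_time": 30,
      "off_time": 30,
      "rate_kb_min": 2,
      "strand": "+"
    },
    {
      "prefix": "reversal",
      "n": 3,
      "pattern": "reversal",
      "length": 12000,
      "baseline_rate": 0.5,
      "fold": 3,
      "onset_time": 0,
      "off_time": 60,
      "rate_kb_min": 2,
      "strand": "-"
    },
    {
      "prefix": "wave_up",
      "n": 3,
      "pattern": "sustained_up",
      "length": 300000,
      "baseline_rate": 0,
      "change_times": 0,
      "epoch_rates": 2,
      "rate_kb_min": 2,
      "gap": 50000
    },
    {
      "prefix": "wave_down",
      "n": 3,
      "pattern": "sustained_down",
      "length": 300000,
      "baseline_rate": 2,
      "change_times": 0,
      "epoch_rates": 0,
      "rate_kb_min": 2,
      "gap": 50000
    }
  ]
}
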