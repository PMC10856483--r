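timestamp: 2026-09-21T23:14:56+0000
subcommand: report
seed: 1
config_hash: 0445588cf96725704d849dc5d1f3e56a
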