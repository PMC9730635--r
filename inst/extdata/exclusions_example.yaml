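
# Months removed from all index and inference stages (data inconsistencies)
exclude: [2017-06, 2019-12]
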