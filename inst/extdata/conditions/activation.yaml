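name: activation
vessel: {total_mL: 500, liquid_mL: 165}
pressure: {value: 1.8, unit: bar}
temperature_C: 25
gas: {H2: 51, CO: 22, CO2: 27}
intermediates: {}
initial_pH: 6.5
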