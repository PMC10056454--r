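name: series1_syngas
vessel: {total_mL: 300, liquid_mL: 100}
pressure: {value: 1.8, unit: atm}
temperature_C: 37
gas: {H2: 70, CO: 10, CO2: 20}
intermediates: {acetic acid: 39, ethanol: 93}
initial_pH: 6.5
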