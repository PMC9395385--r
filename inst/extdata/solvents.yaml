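# Handbook properties of the co-solvent pair. Antoine constants follow the
# log10(P/mmHg) = A - B/(C + T/degC) convention; van Laar constants are for
# the ethanol(1)-water(2) binary at ambient conditions.
activity_model: van_laar
van_laar:
  a12: 1.6798
  a21: 0.9227
components:
  ethanol:
    boiling_point: 78.37    # degC
    flash_point: 13.0       # degC, closed cup
    antoine: [8.20417, 1642.89, 230.300]
    hansen_delta: 26.52     # MPa^0.5
    tlv_stel: 1000.0        # ppm
    nfpa_reactivity: 0
    lel: 3.3                # vol %
    uel: 19.0               # vol %
    density: 0.789          # g/ml at 20 degC
    molar_mass: 46.07       # g/mol
    flammable: true
  water:
    boiling_point: 100.0
    flash_point: null
    antoine: [8.07131, 1730.63, 233.426]
    hansen_delta: 47.81
    tlv_stel: null
    nfpa_reactivity: 0
    lel: null
    uel: null
    density: 0.99820
    molar_mass: 18.015
    flammable: false
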