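# Molar extinction coefficients of human hemoglobin in the near infrared,
# compiled from the standard tabulated values (units: cm^-1 / (mol/L)).
# Columns: wavelength_nm  eps_hbo2  eps_hb
750	518.0	1405.24
760	586.0	1548.52
770	650.0	1311.88
780	710.0	1075.44
790	764.0	893.20
800	816.0	761.84
810	864.0	717.08
820	916.0	693.76
830	974.0	693.04
840	1022.0	693.44
850	1058.0	691.32
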