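# Core Hox-monomer binding 5-mers (fingerprint panel); label = display colour
TTTAT	red
TTAAT	darkblue
TTGAT	darkgreen
TGGAT	yellow
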