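# Exd-Hox dimer binding 8-mers (fingerprint panel); label = display colour
TGATTTAT	red
TGATTTAC	magenta
TGATTGAT	darkgreen
TGATTAAT	darkblue
TGATAAAT	cyan
TGATGGAT	yellow
TGACAAAT	orange
TGACTAAT	purple
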