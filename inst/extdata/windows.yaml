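# Default elution-peak integration windows (min) for the five sugars on
# the polyamine HILIC column.  Maltose and trehalose windows overlap, as
# their elution peaks do.
Fru: [35.3, 38.0]
Glu: [38.0, 40.7]
Suc: [40.7, 43.3]
Mal: [44.7, 47.3]
Tre: [46.0, 49.0]
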