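poverty_tracts.csv: five published housing-affordability / poverty / employment
percentage indicators with their 90% margins of error for four adjacent Cook
County (Chicago) census tracts, used in the worked examples. The households
column is illustrative filler required by the table schema; it plays no role
in the uncertainty arithmetic the examples exercise.
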