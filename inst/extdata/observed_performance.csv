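measure,actual
Initial Preparation,11
Contract Negotiation,54.9
Budget Negotiation,46.3
PI Approval,4.8
DSR Approval,2.5
Sponsor Approval,5.5
Entire Process,76.6
Number in,147
Number out,78
Still in process,52
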