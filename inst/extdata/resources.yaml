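# Example accelerator resource configuration (bytes, bytes/cycle, cycles).
# All values are model parameters, not measured silicon.
input_mem: 65536
param_mem: 65536
output_mem: 65536
pe_multipliers: 2048
load_bw: 64
wb_bw: 64
cf_cycles: 8
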