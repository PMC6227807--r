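convention: none
n_stages: 3
ordering: pre,commit,post
stage1.label: pre
stage1.n_cells: 30
stage1.dropout: 0.10000000000000001
stage1.n_substates: 1
stage1.substate1.weight: 1
stage1.substate1.on_probability: 0.94999999999999996,0.94999999999999996,0.94999999999999996,0.94999999999999996,0.94999999999999996,0.050000000000000003,0.050000000000000003,0.050000000000000003,0.050000000000000003,0.050000000000000003
stage2.label: commit
stage2.n_cells: 30
stage2.dropout: 0.10000000000000001
stage2.n_substates: 2
stage2.substate1.weight: 0.5
stage2.substate1.on_probability: 0.94999999999999996,0.94999999999999996,0.94999999999999996,0.94999999999999996,0.94999999999999996,0.050000000000000003,0.050000000000000003,0.050000000000000003,0.050000000000000003,0.050000000000000003
stage2.substate2.weight: 0.5
stage2.substate2.on_probability: 0.050000000000000003,0.050000000000000003,0.050000000000000003,0.050000000000000003,0.050000000000000003,0.94999999999999996,0.94999999999999996,0.94999999999999996,0.94999999999999996,0.94999999999999996
stage3.label: post
stage3.n_cells: 30
stage3.dropout: 0.10000000000000001
stage3.n_substates: 1
stage3.substate1.weight: 1
stage3.substate1.on_probability: 0.050000000000000003,0.050000000000000003,0.050000000000000003,0.050000000000000003,0.050000000000000003,0.94999999999999996,0.94999999999999996,0.94999999999999996,0.94999999999999996,0.94999999999999996
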