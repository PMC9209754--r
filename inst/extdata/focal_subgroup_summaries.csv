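group,subgroup,mean,n
2QL,with,58.6,3
2QL,without,51.6,4
3QL,with,71.4,6
3QL,without,61.5,4
4QL,with,72.5,4
4QL,without,68.0,3
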