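subject,subject_type,mean,se,n,scale
HJX74,control,29.2,,3,raw_percent
1QL,group,48.1,,11,raw_percent
2QL,group,54.6,,7,raw_percent
3QL,group,67.4,,10,raw_percent
4QL,group,70.6,,7,raw_percent
5QL,group,77.1,,5,raw_percent
6QL,group,88.8,,2,raw_percent
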