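"intensity","opacity"
15,16.3
27.1,25.5
39.2,34.79
51.3,44.16
63.4,53.64
75.5,63.22
87.6,72.93
99.7,82.75
111.8,92.72
123.9,102.82
136.1,113.17
148.2,123.59
160.3,134.17
172.4,144.94
184.5,155.89
196.6,167.03
208.7,178.38
220.8,189.94
232.9,201.71
245,213.72
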