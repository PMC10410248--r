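GM001	synthetic lactate to propionate module
K00016,K01026
K01847
K05606,K01848,K01849
K11264
===
GM002	synthetic threonine degradation module
K01754
K00060,K00639
//
K01620
K00132
K13821
===
GM003	synthetic mucin degradation module
K01186,K01206
K12373
K01205
===
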