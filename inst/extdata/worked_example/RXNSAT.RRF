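4278||||CUI||AT00000001||SPL_SET_ID|MTHSPL|3a6f1b22-8c4d-4e9a-9f10-5b7d2c8e4a01|N||
4278||||CUI||AT00000002||SPL_SET_ID|MTHSPL|9d4c7e55-1f2a-4b83-a6c9-0e8f3d5b7a12|N||
46||||CUI||AT00000003||SPL_SET_ID|MTHSPL|0f2053f1-fd94-4a4a-b803-bca391d9e032|N||
47||||CUI||AT00000004||SPL_SET_ID|MTHSPL|0f2053f1-fd94-4a4a-b803-bca391d9e032|N||
48||||CUI||AT00000005||SPL_SET_ID|MTHSPL|0f2053f1-fd94-4a4a-b803-bca391d9e032|N||
44||||CUI||AT00000006||SPL_SET_ID|MTHSPL|b1e8d3c6-4a2f-4d97-8e5b-6c0a9f1d2e83|N||
45||||CUI||AT00000007||SPL_SET_ID|MTHSPL|b1e8d3c6-4a2f-4d97-8e5b-6c0a9f1d2e83|N||
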