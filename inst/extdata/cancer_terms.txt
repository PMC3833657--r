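# common cancer-related terms for the longest-match tagger
prostate cancer
prostatic carcinoma
breast cancer
breast carcinoma
ovarian cancer
ovarian carcinoma
carcinoma
cancer
tumor
neoplasm
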