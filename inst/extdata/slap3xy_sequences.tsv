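role	clone	length_bp
X	13d11E	115665
Y	7a8D	72683
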