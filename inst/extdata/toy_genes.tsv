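name	start	end	essential
X	1	9	TRUE
Y	3	11	FALSE
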