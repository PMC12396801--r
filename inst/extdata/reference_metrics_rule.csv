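metric,IRRELEVANT,CLIN_SIG,SEVERE,macro
accuracy,0.81,0.86,0.74,0.80
precision,0.80,0.94,0.50,0.75
recall,0.95,0.77,0.03,0.58
f1,0.87,0.84,0.06,0.59
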